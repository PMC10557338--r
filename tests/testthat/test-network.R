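# Build a worked-example network: n_single single meals + n_double doubles,
# with typed-locus counts chosen so that `n_complete` profiles are complete.
toy_network <- function(n_single = 34, n_double = 4, n_complete = 23) {
  panel <- panel_subset(apply_exclusions(load_panel("bloodmeal"),
                                         field_exclusions()), "human")
  mixtures <- list()
  made <- 0
  mk_prof <- function(id) {
    made <<- made + 1
    field_profile(id, if (made <= n_complete) 13 else 5, panel)
  }
  for (i in seq_len(n_single)) {
    mid <- sprintf("M%02d", i)
    p <- mk_prof(paste0(mid, ".major"))
    mixtures[[mid]] <- structure(
      list(sample_id = mid, min_contributors = 1L, major_profile = p,
           minor_profiles = list(), masked_loci = character(0),
           unresolved_major = FALSE, assignments = profile_table(list(p))),
      class = "mixture_report")
  }
  for (i in seq_len(n_double)) {
    mid <- sprintf("M%02d", n_single + i)
    p1 <- mk_prof(paste0(mid, ".major"))
    p2 <- mk_prof(paste0(mid, ".minor1"))
    mixtures[[mid]] <- structure(
      list(sample_id = mid, min_contributors = 2L, major_profile = p1,
           minor_profiles = list(p2), masked_loci = character(0),
           unresolved_major = FALSE,
           assignments = profile_table(list(p1, p2))),
      class = "mixture_report")
  }
  build_network(mixtures, panel = panel)
}

test_that("34 single + 4 double meals give 42 profile nodes and edges", {
  net <- toy_network()
  expect_equal(nrow(net$profiles), 42)
  expect_equal(nrow(net$edges), 42)
  expect_equal(nrow(net$mosquitoes), 38)
  expect_equal(sum(net$mosquitoes$n_contributors), nrow(net$edges))
})

test_that("the field summary reproduces the stated percentages", {
  s <- network_summary(toy_network(), n_collected = 61)
  expect_equal(s$pct_with_human_dna, 62)       # 38/61
  expect_equal(s$pct_single, 89)               # 34/38
  expect_equal(s$pct_double, 11)               # 4/38
  expect_equal(s$n_profiles_total, 42)
  expect_equal(s$n_complete_or_nearly, 23)
  expect_equal(s$pct_complete_or_nearly, 55)   # 23/42
  expect_equal(s$n_profiles_total,
               s$n_single_meal + 2 * s$n_double_meal + 3 * s$n_triple_meal)
})

test_that("degenerate networks: empty input and a triple feeding", {
  net0 <- build_network(list())
  expect_equal(nrow(net0$edges), 0)
  s0 <- network_summary(net0, n_collected = 10)
  expect_equal(s0$pct_with_human_dna, 0)
  expect_equal(s0$n_profiles_total, 0)

  panel <- panel_subset(apply_exclusions(load_panel("bloodmeal"),
                                         field_exclusions()), "human")
  p <- lapply(1:3, function(i)
    field_profile(sprintf("T1.c%d", i), 13, panel))
  m <- structure(list(sample_id = "T1", min_contributors = 3L,
                      major_profile = p[[1]], minor_profiles = p[2:3],
                      masked_loci = character(0), unresolved_major = FALSE,
                      assignments = profile_table(p)),
                 class = "mixture_report")
  net3 <- build_network(list(m), panel = panel)
  expect_equal(nrow(net3$edges), 3)
  expect_equal(network_summary(net3, 1)$n_triple_meal, 1)
  expect_error(build_network(list(m, m)), "duplicate mosquito ids")
})

test_that("percent rounding is half away from zero", {
  net <- toy_network(n_single = 1, n_double = 0, n_complete = 1)
  # 1/8 = 12.5% -> 13
  expect_equal(network_summary(net, n_collected = 8)$pct_with_human_dna, 13)
  # 1/3 = 33.33 -> 33
  expect_equal(network_summary(net, n_collected = 3)$pct_with_human_dna, 33)
})

test_that("generated field studies give bipartite networks with the edge identity", {
  cfg <- generator_config(seed = 44)
  fs <- gen_field_study(cfg, n_mosquitoes = 14, n_references = 10,
                        n_with_human = 10, n_double = 3)
  res <- run_pipeline(fs$peaks, fs$references, fs$panel, n_collected = 14,
                      sessions = fs$sessions)
  net <- res$network
  expect_true(igraph::is_bipartite(net$graph))
  expect_equal(nrow(net$edges), sum(net$mosquitoes$n_contributors))
  expect_equal(nrow(net$edges), nrow(net$profiles))
  # every edge joins a mosquito to one of its own profile nodes
  expect_true(all(net$profiles$mosquito_id ==
                    net$edges$mosquito_id[match(net$profiles$id,
                                                net$edges$profile_id)]))
})
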