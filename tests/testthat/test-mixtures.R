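# Two disjoint-allele contributors on the autosomal human loci, plus helpers
# to feed them through the blood-meal generator.
autosomal_panel <- function() {
  p <- panel_subset(load_panel("bloodmeal"), "human")
  apply_exclusions(p, "Amelogenin")
}

disjoint_pair <- function(hom_a = character(0)) {
  panel <- autosomal_panel()
  ga <- list(); gb <- list()
  for (loc in panel$locus) {
    ga[[loc]] <- if (loc %in% hom_a) c("0", "0") else c("0", "1")
    gb[[loc]] <- c("3", "4")
  }
  list(a = str_profile("HOST_A", ga), b = str_profile("HOST_B", gb),
       panel = panel)
}

test_that("minimum contributor count is ceil(max alleles / 2)", {
  p1 <- str_profile("s", list(A = c("1", "2"), B = c("3", "3")))
  expect_equal(min_contributors(p1), 1L)
  p2 <- str_profile("s", list(A = c("1", "2", "3")))
  expect_equal(min_contributors(p2), 2L)
  p3 <- str_profile("s", list(A = as.character(1:5)))
  expect_equal(min_contributors(p3), 3L)
  # Amelogenin capped at two alleles
  amel <- str_profile("s", list(Amelogenin = c("X", "Y"), A = c("1", "2")))
  expect_equal(min_contributors(amel), 1L)
  expect_error(min_contributors(str_profile("s", list())), "no typed loci")
})

test_that("single-source profiles deconvolve to themselves", {
  p <- str_profile("solo", list(A = c("1", "2"), B = "4"),
                   heights = list(A = c(1200, 500), B = 2600))
  rep1 <- deconvolve(p)
  expect_equal(rep1$min_contributors, 1L)
  expect_equal(rep1$major_profile$calls, p$calls)
  expect_equal(length(rep1$minor_profiles), 0)
  expect_equal(length(rep1$masked_loci), 0)
  expect_false(rep1$unresolved_major)
})

test_that("a 3:1 disjoint mixture yields the major contributor's genotype", {
  pair <- disjoint_pair(hom_a = c("TH01", "TPOX"))
  cfg <- generator_config(seed = 21, height_sigma = 0, base_dropout = 0,
                          detection_threshold = 0)
  bm <- gen_bloodmeal(list(pair$a, pair$b), pair$panel, cfg,
                      time_h = 0, proportions = c(0.75, 0.25),
                      sample_id = "MIX1")
  binned <- bin_peaks(bm$peaks, pair$panel)
  prof <- calls_to_profile(binned$calls, pair$panel)
  expect_true(prof$mixture_candidate)
  expect_equal(min_contributors(prof), 2L)

  rep1 <- deconvolve(prof, major_ratio = 2)
  expect_equal(length(rep1$masked_loci), 0)
  expect_false(rep1$unresolved_major)
  for (loc in pair$panel$locus) {
    expect_equal(sort(unique(rep1$major_profile$calls[[loc]]$allele)),
                 sort(unique(pair$a$calls[[loc]]$allele)), label = loc)
  }
  # the minor partial profile holds the 1-part contributor's alleles
  minor <- rep1$minor_profiles[[1]]
  for (loc in typed_loci(minor))
    expect_true(all(minor$calls[[loc]]$allele %in%
                      pair$b$calls[[loc]]$allele))
})

test_that("equal-proportion mixtures defer: most loci masked", {
  pair <- disjoint_pair()
  cfg <- generator_config(seed = 22, height_sigma = 0.05, base_dropout = 0,
                          detection_threshold = 0)
  bm <- gen_bloodmeal(list(pair$a, pair$b), pair$panel, cfg,
                      time_h = 0, proportions = c(0.5, 0.5),
                      sample_id = "MIX_EQ")
  prof <- calls_to_profile(bin_peaks(bm$peaks, pair$panel)$calls, pair$panel)
  rep1 <- deconvolve(prof, major_ratio = 2)
  expect_gt(length(rep1$masked_loci), prof$n_typed_loci / 2)
  expect_true(rep1$unresolved_major)
})

test_that("every input allele lands in exactly one of major/minor/masked", {
  pair <- disjoint_pair()
  cfg <- generator_config(seed = 23, base_dropout = 0, detection_threshold = 0)
  for (props in list(c(0.75, 0.25), c(0.6, 0.4), c(0.5, 0.5))) {
    bm <- gen_bloodmeal(list(pair$a, pair$b), pair$panel, cfg, time_h = 0,
                        proportions = props, sample_id = "MIXP",
                        counter = round(100 * props[1]))
    prof <- calls_to_profile(bin_peaks(bm$peaks, pair$panel)$calls, pair$panel)
    rep1 <- deconvolve(prof)
    asg <- rep1$assignments
    inp <- profile_table(list(prof))
    expect_equal(nrow(asg), nrow(inp))
    expect_setequal(paste(asg$locus, asg$allele),
                    paste(inp$locus, inp$allele))
    expect_true(all(asg$assignment %in% c("major", "minor_1", "masked")))
  }
})

test_that("contributor-count estimate never exceeds the true count", {
  panel <- autosomal_panel()
  cfg <- generator_config(seed = 24, base_dropout = 0, detection_threshold = 0)
  freqs <- gen_allele_freqs(panel, cfg)
  pop <- gen_population(freqs, 9, cfg)
  for (trial in 1:3) {
    k <- trial  # 1, 2, 3 contributors
    contribs <- pop[seq((trial - 1) * 3 + 1, length.out = k)]
    bm <- gen_bloodmeal(contribs, panel, cfg, time_h = 0,
                        proportions = rep(1 / k, k), sample_id = "T",
                        counter = trial)
    prof <- calls_to_profile(bin_peaks(bm$peaks, panel)$calls, panel)
    expect_lte(min_contributors(prof), k)
  }
})

test_that("greater imbalance unmasks more loci (monotone trend)", {
  pair <- disjoint_pair()
  cfg <- generator_config(seed = 25, height_sigma = 0.1, base_dropout = 0,
                          detection_threshold = 0)
  masked_at <- vapply(c(0.50, 0.62, 0.75, 0.88), function(p1) {
    bm <- gen_bloodmeal(list(pair$a, pair$b), pair$panel, cfg, time_h = 0,
                        proportions = c(p1, 1 - p1), sample_id = "G",
                        counter = round(p1 * 100))
    prof <- calls_to_profile(bin_peaks(bm$peaks, pair$panel)$calls,
                             pair$panel)
    length(deconvolve(prof)$masked_loci)
  }, numeric(1))
  expect_lt(masked_at[4], masked_at[1])
  expect_true(all(diff(masked_at) <= 2))  # allow small seed jitter, no jumps up
})
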