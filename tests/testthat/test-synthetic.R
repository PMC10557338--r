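test_that("allele frequencies are legal, normalized and reproducible", {
  panel <- panel_subset(load_panel("bloodmeal"), "human")
  cfg <- generator_config(seed = 61)
  f1 <- gen_allele_freqs(panel, cfg)
  f2 <- gen_allele_freqs(panel, cfg)
  expect_identical(f1, f2)
  for (loc in names(f1)) expect_equal(sum(f1[[loc]]), 1)
  expect_setequal(names(f1$Amelogenin), c("X", "Y"))
  expect_equal(unname(f1$Amelogenin["Y"]), cfg$male_fraction / 2)
  # labels within range capacity
  th01 <- panel[panel$locus == "TH01", ]
  cap <- (th01$size_max - th01$size_min) %/% th01$repeat_unit_len + 1
  expect_true(all(as.integer(names(f1$TH01)) < cap))
  expect_error(gen_allele_freqs(panel, generator_config(seed = 1, n_alleles = 500)),
               "capacity|holds")
  # uniform model
  fu <- gen_allele_freqs(panel, generator_config(seed = 1, n_alleles = 4,
                                                 freq_model = "uniform"))
  expect_equal(unname(fu$TH01), rep(0.25, 4))
})

test_that("HWE populations show the expected heterozygosity", {
  panel <- as_panel(data.frame(
    locus = "L1", organism = "human", repeat_motif = "[AGAT]n",
    repeat_unit_len = 4L, size_min = 100L, size_max = 140L, multiplex = 1L,
    dye = "6-FAM", sex_marker = FALSE, stringsAsFactors = FALSE))
  cfg <- generator_config(seed = 62, n_alleles = 2, freq_model = "uniform")
  freqs <- gen_allele_freqs(panel, cfg)
  pop <- gen_population(freqs, 500, cfg)
  het <- mean(vapply(pop, function(p)
    length(unique(p$calls$L1$allele)) == 2, logical(1)))
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 500))
  expect_equal(length(gen_population(freqs, 0, cfg)), 0)
  # fixed allele -> all homozygous
  fixed <- list(L1 = c(`3` = 1.0))
  mono <- gen_population(fixed, 10, cfg)
  expect_true(all(vapply(mono, function(p)
    all(p$calls$L1$allele == "3"), logical(1))))
})

test_that("families obey Mendelian transmission", {
  panel <- panel_subset(load_panel("bloodmeal"), "human")
  cfg <- generator_config(seed = 63)
  freqs <- gen_allele_freqs(panel, cfg)
  # every child shares an allele with each parent at every autosomal locus
  fam <- gen_family(freqs, 3, cfg, id_prefix = "F1")
  mother <- fam$F1_mother; father <- fam$F1_father
  for (k in 1:3) {
    child <- fam[[paste0("F1_child", k)]]
    for (loc in setdiff(names(freqs), "Amelogenin")) {
      expect_true(length(intersect(child$calls[[loc]]$allele,
                                   mother$calls[[loc]]$allele)) >= 1)
      expect_true(length(intersect(child$calls[[loc]]$allele,
                                   father$calls[[loc]]$allele)) >= 1)
    }
    expect_true("X" %in% child$calls$Amelogenin$allele)
  }
})

test_that("blood meals are deterministic and ledgered allele by allele", {
  panel <- panel_subset(load_panel("bloodmeal"), "human")
  cfg <- generator_config(seed = 65)
  freqs <- gen_allele_freqs(panel, cfg)
  pop <- gen_population(freqs, 2, cfg)
  args <- list(pop, panel, cfg, time_h = 24, preservation = "ethanol",
               proportions = c(0.7, 0.3), sample_id = "B", counter = 9)
  b1 <- do.call(gen_bloodmeal, args)
  b2 <- do.call(gen_bloodmeal, args)
  expect_identical(b1, b2)
  # every peak traces to >= 1 surviving ledger row at the same size
  led <- b1$ledger[!b1$ledger$dropped_out & !b1$ledger$below_threshold, ]
  expect_setequal(b1$peaks$size_bp, unique(led$size_bp))
  expect_error(gen_bloodmeal(pop, panel, cfg, proportions = c(0.9, 0.3)),
               "sum to 1")
})

test_that("noise-free expected heights follow the closed-form product", {
  panel <- panel_subset(load_panel("bloodmeal"), "human")
  cfg <- generator_config(seed = 66, height_sigma = 0, base_dropout = 0,
                          detection_threshold = 0)
  geno <- stats::setNames(rep(list(c("0", "1")), 13),
                          head(panel$locus[panel$locus != "Amelogenin"], 13))
  geno[[1]] <- c("2", "2")  # one homozygous locus
  p <- str_profile("one", geno)
  bm <- gen_bloodmeal(list(p), panel, cfg, time_h = 30,
                      preservation = "lysis_buffer", sample_id = "NF")
  dig <- 1 / (1 + exp(0.15 * (30 - 55)))
  het_expected <- 300 * 1 * 2.2 * dig
  led <- bm$ledger
  expect_equal(unique(led$noisy_height[led$zygosity == "het"]), het_expected)
  expect_equal(unique(led$noisy_height[led$zygosity == "hom"]),
               2 * het_expected)
  expect_equal(led$noisy_height, led$expected_height)
  expect_equal(nrow(bm$peaks), 1 + 12 * 2)
})

test_that("homozygote doubling shows one peak of twice the het height", {
  panel <- toy_panel()
  cfg <- generator_config(seed = 67, height_sigma = 0, base_dropout = 0,
                          detection_threshold = 0)
  p <- str_profile("s", list(LA = c("1", "1"), LB = c("2", "5")))
  bm <- gen_bloodmeal(list(p), panel, cfg, time_h = 0, sample_id = "S")
  pk <- bm$peaks
  h_hom <- pk$height[pk$dye == "6-FAM"]
  h_het <- pk$height[pk$dye == "HEX"]
  expect_equal(length(h_hom), 1)
  expect_equal(length(h_het), 2)
  expect_equal(h_hom, 2 * h_het[1])
})

test_that("a detection threshold above all peaks empties the table", {
  panel <- toy_panel()
  cfg <- generator_config(seed = 68, detection_threshold = 1e9)
  p <- str_profile("s", list(LA = c("1", "2")))
  bm <- gen_bloodmeal(list(p), panel, cfg, sample_id = "S")
  expect_equal(nrow(bm$peaks), 0)
  expect_true(all(bm$ledger$dropped_out | bm$ledger$below_threshold))
})

test_that("long amplicons drop out preferentially", {
  panel <- panel_subset(load_panel("bloodmeal"), "human")
  cfg <- generator_config(seed = 69)
  freqs <- gen_allele_freqs(panel, cfg)
  pop <- gen_population(freqs, 120, cfg)
  drops <- integer(0); locus <- character(0)
  for (i in seq_along(pop)) {
    bm <- gen_bloodmeal(pop[i], panel, cfg, time_h = 0, sample_id = "L",
                        counter = i)
    drops <- c(drops, bm$ledger$dropped_out)
    locus <- c(locus, bm$ledger$locus)
  }
  rate <- tapply(drops, locus, mean)
  expect_gt(rate["PentaD"] + rate["PentaE"], 2 * rate["TH01"])
  expect_gt(mean(rate[c("PentaD", "PentaE", "FGA")]),
            mean(rate[c("TH01", "D3S1358", "D5S818")]))
})

test_that("lysis buffer beats ethanol in standardized PH in every batch", {
  panel <- panel_subset(load_panel("bloodmeal"), "human")
  for (seed in c(71, 72, 73, 74, 75)) {
    cfg <- generator_config(seed = seed)
    freqs <- gen_allele_freqs(panel, cfg)
    pop <- gen_population(freqs, 10, cfg)
    m_ph <- numeric(10)
    method <- rep(c("lysis_buffer", "ethanol"), each = 5)
    for (i in 1:10) {
      bm <- gen_bloodmeal(pop[i], panel, cfg, time_h = 0,
                          preservation = method[i], sample_id = "P",
                          counter = i)
      prof <- calls_to_profile(bin_peaks(bm$peaks, panel)$calls, panel)
      m_ph[i] <- mean_ph(prof)
    }
    std <- standardize_ph(m_ph)
    expect_gt(mean(std[method == "lysis_buffer"]),
              mean(std[method == "ethanol"]))
  }
})

test_that("drop_alleles thins profiles at the requested rate", {
  p <- rand_profile("d", loci = paste0("L", 1:50), n_alleles = 9)
  set.seed(70)
  q0 <- drop_alleles(p, 0)
  expect_equal(q0$calls, p$calls)
  q1 <- drop_alleles(p, 1)
  expect_equal(q1$n_typed_loci, 0)
  qs <- replicate(30, sum(lengths(lapply(drop_alleles(p, 0.2)$calls,
                                         function(df) df$allele))))
  expect_equal(mean(qs) / 100, 0.8, tolerance = 0.05)
})
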