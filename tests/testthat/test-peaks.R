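test_that("peaks bin to the unique locus sharing channel and size range", {
  panel <- load_panel("bloodmeal")
  peaks <- data.frame(
    sample_id = "S1",
    multiplex = c(3, 1, 1, 3),
    dye = c("TAMRA", "JOE", "JOE", "TAMRA"),
    size_bp = c(107.0, 400.0, 95.0, 112.2),
    height = c(2000, 1500, 900, 1100), stringsAsFactors = FALSE)
  out <- bin_peaks(peaks, panel)
  expect_equal(nrow(out$calls) + nrow(out$rejected), nrow(peaks))

  amel <- out$calls[out$calls$size_bp == 107.0, ]
  expect_equal(amel$locus, "Amelogenin")
  expect_equal(amel$allele, "X")
  expect_equal(out$calls$allele[out$calls$size_bp == 112.2], "Y")
  expect_equal(out$calls$locus[out$calls$size_bp == 400.0], "PentaD")
  expect_equal(out$rejected$reason, "no locus in range")
  expect_equal(out$rejected$size_bp, 95.0)
})

test_that("allele labels are repeat offsets from the range start", {
  panel <- toy_panel()
  peaks <- data.frame(sample_id = "S1", multiplex = 1,
                      dye = "6-FAM", size_bp = c(100, 108.3, 140.4),
                      height = 1000, stringsAsFactors = FALSE)
  out <- bin_peaks(peaks, panel)
  expect_equal(out$calls$allele, c("0", "2", "10"))
})

test_that("peaks in a panel conflict are flagged ambiguous, never assigned", {
  panel <- load_panel("bloodmeal")
  # inside the Alb-tri-21 / Aealbmic7 overlap (MPX1, ATTO565, 194-206 bp)
  peaks <- data.frame(sample_id = "S1", multiplex = 1, dye = "ATTO565",
                      size_bp = 200, height = 500, stringsAsFactors = FALSE)
  out <- bin_peaks(peaks, panel)
  expect_equal(nrow(out$calls), 0)
  expect_match(out$rejected$reason, "ambiguous")
  expect_match(out$rejected$reason, "Alb-tri-21")
})

test_that("binning conserves peaks on random input", {
  panel <- load_panel("bloodmeal")
  set.seed(42)
  peaks <- data.frame(
    sample_id = "S1",
    multiplex = sample(1:3, 300, replace = TRUE),
    dye = sample(unique(panel$dye), 300, replace = TRUE),
    size_bp = runif(300, 80, 500),
    height = runif(300, 50, 4000), stringsAsFactors = FALSE)
  out <- bin_peaks(peaks, panel)
  expect_equal(nrow(out$calls) + nrow(out$rejected), 300)
  # every call is inside its locus's widened interval
  for (i in seq_len(nrow(out$calls))) {
    row <- panel[panel$locus == out$calls$locus[i], ]
    expect_gte(out$calls$size_bp[i], row$size_min - 0.5)
    expect_lte(out$calls$size_bp[i], row$size_max + 0.5)
  }
})

test_that("profiles assemble from calls with mixture flagging", {
  panel <- panel_subset(apply_exclusions(load_panel("bloodmeal"),
                                         field_exclusions()), "human")
  p13 <- field_profile("full13", 13, panel)
  expect_equal(p13$n_typed_loci, 13)
  expect_false(p13$mixture_candidate)

  calls <- data.frame(sample_id = "mix", locus = "TH01",
                      allele = c("1", "3", "5"), height = c(900, 600, 300),
                      size_bp = NA_real_, stringsAsFactors = FALSE)
  pm <- calls_to_profile(calls, panel)
  expect_true(pm$mixture_candidate)

  empty <- calls_to_profile(calls[0, ], panel)
  expect_equal(empty$n_typed_loci, 0)

  bad <- calls; bad$locus <- "PentaD"  # excluded from this panel
  expect_error(calls_to_profile(bad, panel), "absent from panel")
})

test_that("homozygote single peaks split into halves, conserving signal", {
  p <- str_profile("s", list(A = "7", B = c("2", "4")),
                   heights = list(A = 3000, B = c(1200, 900)))
  h <- per_allele_heights(p)
  expect_equal(unname(h$A), c(1500, 1500))
  expect_equal(names(h$A), c("7", "7"))
  expect_equal(sum(h$A), 3000)             # 2 x H/2 = H
  expect_equal(unname(h$B), c(1200, 900))  # heterozygote unchanged
  expect_equal(length(h), 2)               # untyped loci absent

  mix <- str_profile("m", list(A = c("1", "2", "3")),
                     heights = list(A = c(900, 600, 300)))
  expect_error(per_allele_heights(mix), "deconvolve")
})

test_that("mean PH averages observed peaks without homozygote splitting", {
  p <- str_profile("s", list(A = c("1", "2"), B = "3"),
                   heights = list(A = c(100, 200), B = 300))
  expect_equal(mean_ph(p), 200)
  expect_equal(mean_ph(str_profile("s", list(A = "1"),
                                   heights = list(A = 500))), 500)
  expect_error(mean_ph(str_profile("s", list(A = "1"))), "no detected")
})

test_that("Sneath-Sokal ranging maps batch extremes to 0 and 1", {
  expect_equal(standardize_ph(c(100, 200, 300)), c(0, 0.5, 1))
  expect_equal(standardize_ph(c(0, 1)), c(0, 1))
  expect_warning(z <- standardize_ph(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  # affine invariance: standardize(a x + b) == standardize(x), a > 0
  set.seed(1)
  x <- rnorm(20)
  expect_equal(standardize_ph(3.7 * x + 11), standardize_ph(x))
  # monotone
  expect_true(all(diff(standardize_ph(sort(x))) >= 0))
})

test_that("completeness classes follow the >= 11 of 13 field rule", {
  panel <- panel_subset(apply_exclusions(load_panel("bloodmeal"),
                                         field_exclusions()), "human")
  expect_equal(completeness(field_profile("a", 13, panel), panel), "complete")
  expect_equal(completeness(field_profile("b", 11, panel), panel),
               "nearly_complete")
  expect_equal(completeness(field_profile("c", 10, panel), panel), "incomplete")
  # monotone in the number of typed loci
  classes <- vapply(1:13, function(n)
    completeness(field_profile("x", n, panel), panel), character(1))
  ranks <- c(incomplete = 1, nearly_complete = 2, complete = 3)
  expect_true(all(diff(ranks[classes]) >= 0))
})

test_that("profile tables round-trip through CSV", {
  panel <- toy_panel()
  p <- str_profile("s1", list(LA = c("1", "2"), LB = "4"),
                   heights = list(LA = c(1000, 800), LB = 1500))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(list(p), path)
  back <- read_profiles(path, panel)
  expect_equal(names(back), "s1")
  expect_equal(back$s1$calls$LA$allele, p$calls$LA$allele)
  expect_equal(back$s1$calls$LB$height, 1500)
})
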