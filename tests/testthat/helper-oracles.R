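# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Nei's D_A: explicit per-allele loop over the union of alleles,
# including zero-frequency terms. Kept independent of nei_da()'s vectorized
# shared-allele path.
nei_da_oracle <- function(a, b) {
  shared <- intersect(typed_loci(a), typed_loci(b))
  if (length(shared) == 0) return(NA_real_)
  total <- 0
  for (loc in shared) {
    fa <- table(a$calls[[loc]]$allele)
    fa <- as.numeric(fa) / sum(fa); names(fa) <- names(table(a$calls[[loc]]$allele))
    fb <- table(b$calls[[loc]]$allele)
    fb <- as.numeric(fb) / sum(fb); names(fb) <- names(table(b$calls[[loc]]$allele))
    s <- 0
    for (al in union(names(fa), names(fb))) {
      xa <- if (al %in% names(fa)) fa[[al]] else 0
      xb <- if (al %in% names(fb)) fb[[al]] else 0
      s <- s + sqrt(xa * xb)
    }
    total <- total + s
  }
  1 - total / length(shared)
}

# Random diploid profile over `loci`, alleles drawn from labels 1..n_alleles.
rand_profile <- function(id, loci = paste0("L", 1:10), n_alleles = 6,
                         missing_rate = 0) {
  geno <- list()
  for (loc in loci) {
    if (missing_rate > 0 && runif(1) < missing_rate) next
    geno[[loc]] <- as.character(sample.int(n_alleles, 2, replace = TRUE))
  }
  str_profile(id, geno)
}

# Tiny two-locus test panel (same multiplex, different dyes).
toy_panel <- function() {
  as_panel(data.frame(
    locus = c("LA", "LB"), organism = "human",
    repeat_motif = "[AGAT]n", repeat_unit_len = 4L,
    size_min = c(100L, 200L), size_max = c(140L, 240L),
    multiplex = 1L, dye = c("6-FAM", "HEX"), sex_marker = FALSE,
    stringsAsFactors = FALSE))
}

# Profile with heights at `n_loci` loci of the post-exclusion human panel.
field_profile <- function(id, n_loci, panel = NULL) {
  if (is.null(panel))
    panel <- panel_subset(apply_exclusions(load_panel("bloodmeal"),
                                           field_exclusions()), "human")
  loci <- panel$locus[seq_len(n_loci)]
  geno <- stats::setNames(
    lapply(seq_along(loci), function(i) c("1", "2")), loci)
  hts <- stats::setNames(lapply(loci, function(x) c(800, 700)), loci)
  str_profile(id, geno, hts)
}
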