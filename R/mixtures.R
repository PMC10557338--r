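#' @title Multiple-feeding detection and mixture deconvolution
#' @name mixtures
#' @description
#' The number of different people in one blood meal is read off the number of
#' alleles detected at the human STR loci (a diploid contributes at most two
#' per locus), and individual profiles are separated by relative peak heights,
#' a proxy for each host's DNA template amount.
NULL

#' Minimum number of contributors to a profile
#'
#' `ceil(max over loci of distinct alleles / 2)`; sex-marker loci are capped
#' at two alleles (X/Y carries no extra contributor information).
#'
#' @param profile An `str_profile` typed at >= 1 locus.
#' @param sex_locus Sex-marker locus name(s).
#' @return Integer >= 1.
#' @export
min_contributors <- function(profile, sex_locus = "Amelogenin") {
  loci <- typed_loci(profile)
  if (length(loci) == 0) stop("min_contributors(): profile has no typed loci")
  counts <- vapply(loci, function(loc) {
    n <- length(unique(profile$calls[[loc]]$allele))
    if (loc %in% sex_locus) min(n, 2L) else n
  }, integer(1))
  max(1L, as.integer(ceiling(max(counts) / 2)))
}

# Pick the next contributor's allele rows from height-sorted locus calls.
# Returns indices, or NULL when relative heights cannot separate a
# contributor (masking).
.peel_contributor <- function(h, ratio) {
  n <- length(h)
  if (n == 1) return(1L)
  if (h[1] >= ratio * h[2]) return(1L)          # homozygous contributor
  if (n == 2) return(1:2)
  if (h[2] >= ratio * h[3]) return(1:2)
  NULL
}

#' Deconvolve a mixed blood-meal profile by relative peak heights
#'
#' Single-source profiles (no locus with more than two alleles) are returned
#' unchanged as the major profile. For candidate mixtures, alleles at each
#' locus are ranked by height and contributors are peeled from the top: the
#' top allele alone is taken as a homozygous genotype when it stands at least
#' `major_ratio` times above the next allele, the top two are taken as a
#' heterozygous genotype when they jointly clear the third by the same
#' margin, and loci where the ranking is too flat to separate the major
#' contributor are recorded as masked (the masking effect of taller alleles
#' in the same position) and left unassigned. Remaining alleles are peeled
#' again into minor *partial* profiles; no attempt is made to phase minor
#' alleles into full genotypes across loci. When the major genotype is
#' resolved at fewer than `consistency` of the typed loci the report is
#' flagged `unresolved_major`.
#'
#' @param profile An `str_profile` with peak heights.
#' @param major_ratio Height ratio a contributor's alleles must hold over the
#'   next-ranked allele (default 2, mirroring the homozygote doubling rule).
#' @param consistency Minimum fraction of typed loci at which the major
#'   genotype must be resolved (default 0.75).
#' @param sex_locus Sex-marker locus name(s).
#' @return A `mixture_report`: list with `sample_id`, `min_contributors`,
#'   `major_profile`, `minor_profiles`, `masked_loci`, `unresolved_major` and
#'   an `assignments` table (`sample_id, locus, allele, height, assignment`).
#' @export
deconvolve <- function(profile, major_ratio = 2, consistency = 0.75,
                       sex_locus = "Amelogenin") {
  has_heights <- any(vapply(profile$calls,
                            function(df) any(!is.na(df$height)), logical(1)))
  if (profile$n_typed_loci > 0 && !has_heights)
    stop("deconvolve(): profile ", profile$sample_id, " carries no peak heights")
  k <- if (profile$n_typed_loci > 0) min_contributors(profile, sex_locus) else 1L

  if (k == 1L) {
    asg <- profile_table(list(profile))
    asg$assignment <- if (nrow(asg)) "major" else character(0)
    major <- new_profile(paste0(profile$sample_id, ".major"), profile$calls,
                         sex_locus = sex_locus)
    return(structure(list(sample_id = profile$sample_id, min_contributors = 1L,
                          major_profile = major, minor_profiles = list(),
                          masked_loci = character(0), unresolved_major = FALSE,
                          assignments = asg),
                     class = "mixture_report"))
  }

  major_calls <- list()
  minor_calls <- replicate(k - 1, list(), simplify = FALSE)
  masked <- character(0)
  rows <- list()
  for (loc in typed_loci(profile)) {
    df <- profile$calls[[loc]]
    df <- df[order(-df$height, df$allele), , drop = FALSE]
    asg <- rep("masked", nrow(df))
    sel <- .peel_contributor(df$height, major_ratio)
    if (is.null(sel)) {
      masked <- c(masked, loc)
    } else {
      asg[sel] <- "major"
      major_calls[[loc]] <- df[sel, , drop = FALSE]
      rest <- df[-sel, , drop = FALSE]
      m <- 1
      while (nrow(rest) > 0 && m <= k - 1) {
        sel_m <- .peel_contributor(rest$height, major_ratio)
        # an inseparable remainder is pooled into this minor rank: minors are
        # partial by construction and never phased into full genotypes
        if (is.null(sel_m) || m == k - 1) sel_m <- seq_len(nrow(rest))
        minor_calls[[m]][[loc]] <- rest[sel_m, , drop = FALSE]
        asg[match(rownames(rest)[sel_m], rownames(df))] <- paste0("minor_", m)
        rest <- rest[-sel_m, , drop = FALSE]
        m <- m + 1
      }
    }
    rows[[loc]] <- data.frame(sample_id = profile$sample_id, locus = loc,
                              allele = df$allele, height = df$height,
                              assignment = asg, stringsAsFactors = FALSE)
  }

  major <- new_profile(paste0(profile$sample_id, ".major"), major_calls,
                       sex_locus = sex_locus)
  minors <- list()
  for (m in seq_len(k - 1)) {
    if (length(minor_calls[[m]]) > 0)
      minors[[length(minors) + 1]] <-
        new_profile(paste0(profile$sample_id, ".minor", m), minor_calls[[m]],
                    sex_locus = sex_locus)
  }
  resolved_frac <- 1 - length(masked) / profile$n_typed_loci
  asg_table <- do.call(rbind, rows)
  rownames(asg_table) <- NULL
  structure(list(sample_id = profile$sample_id,
                 min_contributors = k,
                 major_profile = major,
                 minor_profiles = minors,
                 masked_loci = masked,
                 unresolved_major = resolved_frac < consistency,
                 assignments = asg_table),
            class = "mixture_report")
}

#' @export
print.mixture_report <- function(x, ...) {
  cat(sprintf("<mixture_report %s: >=%d contributor(s), %d masked locus(i)%s>\n",
              x$sample_id, x$min_contributors, length(x$masked_loci),
              if (isTRUE(x$unresolved_major)) ", major unresolved" else ""))
  invisible(x)
}

#' Flatten mixture reports to the assignment table
#'
#' @param reports List of `mixture_report`.
#' @return Data frame `sample_id, min_contributors, locus, allele, height,
#'   assignment`.
#' @export
mixture_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (nrow(r$assignments) == 0) return(NULL)
    cbind(r$assignments[, "sample_id", drop = FALSE],
          min_contributors = r$min_contributors,
          r$assignments[, c("locus", "allele", "height", "assignment")])
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(sample_id = character(), min_contributors = integer(),
                      locus = character(), allele = character(),
                      height = numeric(), assignment = character())
  rownames(out) <- NULL
  out
}
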