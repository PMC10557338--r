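#' @title Reference matching under the D_A threshold rule
#' @name matching
#' @description
#' Blood-meal-derived human profiles are compared against a saliva reference
#' database with Nei's D_A under pairwise deletion; only pairs with
#' `D_A < threshold` (default 0.15, strict) are considered possible matches.
NULL

#' Match query profiles against a reference database
#'
#' For each query, D_A is computed against every reference (pairwise-deletion
#' policy, so amplification failures do not bar comparison). Candidates are
#' the references with `d_a < threshold` and at least `min_shared` jointly
#' typed loci, sorted by ascending distance. The decision is `matched` when
#' exactly one candidate passes, `ambiguous` when several do (never
#' auto-resolved to the smallest distance), `unmatched` when none does, and
#' `incomparable` when the query shares fewer than `min_shared` loci with
#' every reference — sparse profiles cannot produce spurious certainty.
#'
#' @param queries List of `str_profile` (unique ids).
#' @param references Non-empty list of `str_profile` (unique ids).
#' @param threshold Strict D_A cut-off in `(0, 1]` (default 0.15).
#' @param min_shared Minimum jointly typed loci (default 6).
#' @param exclude Loci excluded from the distance (passed to [nei_da()]).
#' @return List of match reports (class `str_match`), one per query, each
#'   with `query_id`, `candidates` (data frame `reference_id, d_a,
#'   shared_loci`) and `decision`.
#' @export
match_profiles <- function(queries, references, threshold = 0.15,
                           min_shared = 6, exclude = NULL) {
  if (length(references) == 0) stop("match_profiles(): empty reference set")
  stopifnot(threshold > 0, threshold <= 1)
  ref_ids <- vapply(references, function(p) p$sample_id, character(1))
  if (anyDuplicated(ref_ids)) stop("duplicate reference ids")
  if (is.list(queries) && inherits(queries, "str_profile")) queries <- list(queries)
  reports <- lapply(queries, function(q) {
    d <- numeric(length(references))
    sh <- integer(length(references))
    for (j in seq_along(references)) {
      v <- nei_da(q, references[[j]], exclude = exclude)
      d[j] <- as.numeric(v)
      sh[j] <- attr(v, "shared_loci")
    }
    comparable <- which(sh >= min_shared & !is.na(d))
    if (length(comparable) == 0) {
      decision <- "incomparable"
      cand <- data.frame(reference_id = character(), d_a = numeric(),
                         shared_loci = integer(), stringsAsFactors = FALSE)
    } else {
      pass <- comparable[d[comparable] < threshold]
      pass <- pass[order(d[pass])]
      cand <- data.frame(reference_id = ref_ids[pass], d_a = d[pass],
                         shared_loci = sh[pass], stringsAsFactors = FALSE)
      decision <- if (nrow(cand) == 1) "matched"
                  else if (nrow(cand) > 1) "ambiguous"
                  else "unmatched"
    }
    structure(list(query_id = q$sample_id, candidates = cand,
                   decision = decision), class = "str_match")
  })
  names(reports) <- vapply(queries, function(p) p$sample_id, character(1))
  reports
}

#' Flatten match reports to a table
#'
#' One row per query-candidate pair (queries without candidates keep one row
#' with `NA` reference), in the CSV layout
#' `query_id, reference_id, d_a, shared_loci, decision`.
#'
#' @param reports List of `str_match` from [match_profiles()].
#' @return Data frame.
#' @export
match_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (nrow(r$candidates) == 0) {
      data.frame(query_id = r$query_id, reference_id = NA_character_,
                 d_a = NA_real_, shared_loci = NA_integer_,
                 decision = r$decision, stringsAsFactors = FALSE)
    } else {
      cbind(query_id = r$query_id, r$candidates,
            decision = r$decision, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best matched reference per query
#'
#' @param reports List of `str_match`.
#' @return Named character vector: query id -> reference id for queries with
#'   decision `matched`, `NA` otherwise.
#' @export
matched_references <- function(reports) {
  out <- vapply(reports, function(r) {
    if (r$decision == "matched") r$candidates$reference_id[1] else NA_character_
  }, character(1))
  names(out) <- vapply(reports, function(r) r$query_id, character(1))
  out
}

#' Calibrate the matching rule on synthetic genotypes
#'
#' Simulates the field matching task under controlled conditions: a reference
#' database of `n_references` individuals drawn in Hardy-Weinberg equilibrium
#' on the post-exclusion 13-locus human panel, and `n_trials` query profiles,
#' each a reference's genotype with independent per-allele dropout at rate
#' `dropout`. For every trial the query is matched against the full database
#' and two rates are recorded: how often the true source is the nearest
#' candidate, and how often any *unrelated* reference crosses the D_A
#' threshold.
#'
#' @param seed Integer seed (generator and trial streams derive from it).
#' @param n_trials Number of query trials (default 500).
#' @param n_references Database size (default 40).
#' @param dropout Per-allele dropout rate for queries (default 0.15).
#' @param n_alleles Alleles per locus in the generator (default 6).
#' @param threshold,min_shared Matching parameters (defaults 0.15 / 6).
#' @return List with `top1_rate`, `false_pass_rate`, `n_trials`, and the
#'   per-trial logical vectors `top1` and `false_pass`.
#' @export
match_calibration <- function(seed, n_trials = 500, n_references = 40,
                              dropout = 0.15, n_alleles = 6,
                              threshold = 0.15, min_shared = 6) {
  panel <- panel_subset(apply_exclusions(load_panel("bloodmeal"),
                                         field_exclusions()), "human")
  config <- generator_config(seed = seed, n_alleles = n_alleles)
  freqs <- gen_allele_freqs(panel, config)
  refs <- gen_population(freqs, n_references, config, id_prefix = "REF")
  top1 <- logical(n_trials)
  false_pass <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(derive_seed(seed, 50000 + t))
    src <- sample.int(n_references, 1)
    query <- drop_alleles(refs[[src]], dropout)
    query$sample_id <- paste0("Q", t)
    rep1 <- match_profiles(list(query), refs, threshold = threshold,
                           min_shared = min_shared)[[1]]
    src_id <- refs[[src]]$sample_id
    top1[t] <- nrow(rep1$candidates) > 0 &&
      rep1$candidates$reference_id[1] == src_id
    false_pass[t] <- any(rep1$candidates$reference_id != src_id)
  }
  list(top1_rate = mean(top1), false_pass_rate = mean(false_pass),
       n_trials = n_trials, top1 = top1, false_pass = false_pass)
}
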