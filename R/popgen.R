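#' @title Genetic distances and ordination
#' @name popgen
#' @description
#' Nei's D_A genetic distance between individual multilocus STR profiles,
#' pairwise distance matrices, principal coordinates analysis (PCoA), and the
#' one-way ANOVA / Tukey comparisons used in the preservation and digestion
#' experiments.
NULL

#' Within-individual allele frequencies at one locus
#'
#' A diploid individual's "frequency vector" at a locus: 1.0 for a homozygous
#' allele, 0.5/0.5 for a heterozygote. A mixed call with more than two alleles
#' is converted proportionally (count / total copies).
#'
#' @param profile An `str_profile`.
#' @param locus Locus name.
#' @return Named numeric vector of frequencies summing to 1, or `NULL` when
#'   the locus is untyped (missing data, not zero frequencies).
#' @export
profile_freqs <- function(profile, locus) {
  df <- profile$calls[[locus]]
  if (is.null(df) || nrow(df) == 0) return(NULL)
  tab <- table(df$allele)
  f <- as.numeric(tab) / sum(tab)
  names(f) <- names(tab)
  f
}

#' Nei's D_A distance between two profiles
#'
#' `D_A = 1 - (1/L) * sum over loci of sum over alleles of sqrt(x_a * y_a)`,
#' where `x` and `y` are the two profiles' within-individual allele
#' frequencies and `L` counts the loci entering the average. Under the default
#' `"shared"` policy (pairwise deletion) only loci typed in *both* profiles
#' are used, so partial blood-meal profiles remain comparable to full
#' references despite amplification failures; `"all"` averages over loci typed
#' in either profile, counting a locus missing on one side as zero similarity.
#'
#' @param a,b `str_profile` objects.
#' @param policy `"shared"` (default) or `"all"`.
#' @param exclude Locus names to drop (e.g. `"Amelogenin"` for autosomal-only
#'   distances).
#' @return D_A in `[0, 1]`, with attribute `shared_loci` (number of loci typed
#'   in both profiles after exclusions). `NA` when no locus is shared.
#' @examples
#' p1 <- str_profile("a", list(L1 = c("1", "1")))
#' p2 <- str_profile("b", list(L1 = c("1", "2")))
#' nei_da(p1, p2)   # 1 - sqrt(0.5) ~= 0.2929
#' @export
nei_da <- function(a, b, policy = c("shared", "all"), exclude = NULL) {
  policy <- match.arg(policy)
  loci_a <- setdiff(typed_loci(a), exclude)
  loci_b <- setdiff(typed_loci(b), exclude)
  shared <- intersect(loci_a, loci_b)
  loci <- if (policy == "shared") shared else union(loci_a, loci_b)
  if (length(shared) == 0) {
    return(structure(NA_real_, shared_loci = 0L))
  }
  sims <- vapply(loci, function(loc) {
    fa <- profile_freqs(a, loc)
    fb <- profile_freqs(b, loc)
    if (is.null(fa) || is.null(fb)) return(0)
    common <- intersect(names(fa), names(fb))
    if (length(common) == 0) return(0)
    sum(sqrt(fa[common] * fb[common]))
  }, numeric(1))
  d <- 1 - mean(sims)
  d <- min(max(d, 0), 1)
  structure(d, shared_loci = length(shared))
}

#' Pairwise Nei's D_A distance matrix
#'
#' @param profiles List of `str_profile` with unique sample ids.
#' @param policy,exclude Passed to [nei_da()].
#' @return An `str_dist`: list with `ids`, symmetric matrix `d` (zero
#'   diagonal; `NA` for incomparable pairs) and integer matrix `shared` of
#'   jointly typed locus counts.
#' @export
distance_matrix <- function(profiles, policy = "shared", exclude = NULL) {
  stopifnot(length(profiles) >= 2)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids in profiles")
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sh <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- nei_da(profiles[[i]], profiles[[j]], policy = policy, exclude = exclude)
      d[i, j] <- d[j, i] <- as.numeric(v)
      sh[i, j] <- sh[j, i] <- attr(v, "shared_loci")
    }
  }
  structure(list(ids = ids, d = d, shared = sh), class = "str_dist")
}

#' @export
as.matrix.str_dist <- function(x, ...) x$d

#' Write a distance matrix as square CSV (id header row and column)
#' @param dm An `str_dist`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.csv(dm$d, path, row.names = TRUE)
  invisible(path)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric PCoA (Gower double-centering of `-D^2/2` followed by
#' eigendecomposition, via [ape::pcoa()]): coordinates are eigenvectors scaled
#' by the square root of their eigenvalues, axes ordered by decreasing
#' eigenvalue, and axes whose eigenvalue falls below `eig_tol` times the
#' largest are dropped. Negative eigenvalues (non-Euclidean input) are
#' reported, never embedded.
#'
#' @param d An `str_dist`, `dist`, or symmetric numeric matrix without
#'   missing values.
#' @param eig_tol Relative eigenvalue retention floor (default 1e-10).
#' @return List with `ids`, `coordinates` (samples x axes), `eigenvalues`,
#'   `proportion_explained` (relative to the positive eigenvalue total) and
#'   `negative_eigenvalues`.
#' @export
run_pcoa <- function(d, eig_tol = 1e-10) {
  if (inherits(d, "str_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("run_pcoa(): distance matrix must be symmetric")
  if (anyNA(d))
    stop("run_pcoa(): matrix contains missing pairs; impute or subset first")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(d)))
  res <- ape::pcoa(stats::as.dist(d))
  eig <- res$values$Eigenvalues
  pos <- which(eig > eig_tol * max(eig, 0))
  coords <- res$vectors[, seq_len(min(length(pos), ncol(res$vectors))), drop = FALSE]
  eigs <- eig[pos]
  colnames(coords) <- paste0("PCo", seq_along(eigs))
  rownames(coords) <- ids
  list(ids = ids,
       coordinates = coords,
       eigenvalues = eigs,
       proportion_explained = eigs / sum(eig[eig > 0]),
       negative_eigenvalues = eig[eig < 0])
}

#' One-way ANOVA with optional Tukey HSD
#'
#' Classical between/within decomposition via [stats::aov()]; pairwise Tukey
#' honestly-significant-difference comparisons (studentized range, family
#' level `conf_level`) when `tukey = TRUE` and every group has at least two
#' values.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param tukey Compute Tukey HSD pairwise table?
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return List with `F`, `df_between`, `df_within`, `p`, and `tukey` (data
#'   frame `pair, diff, lwr, upr, p_adj`, or `NULL`).
#' @export
anova_oneway <- function(groups, tukey = TRUE, conf_level = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("anova_oneway(): every group needs >= 1 value")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  out <- list(F = tab[["F value"]][1],
              df_between = tab[["Df"]][1],
              df_within = tab[["Df"]][2],
              p = tab[["Pr(>F)"]][1],
              tukey = NULL)
  if (tukey && all(sizes >= 2)) {
    tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
    out$tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                            lwr = tk[, "lwr"], upr = tk[, "upr"],
                            p_adj = tk[, "p adj"], row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  out
}
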