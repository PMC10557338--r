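#' @title Digestion-time decay of host DNA
#' @name digestion
#' @description
#' Host-DNA detectability and standardized peak height fall with post-feeding
#' time following a descending sigmoid. The package fits the three-parameter
#' descending logistic `v(t) = A / (1 + exp(k * (t - t50)))` (upper asymptote
#' `A`, midpoint `t50` in hours, slope `k` per hour, floor fixed at 0) and
#' inverts it to estimate time since feeding from an observed value.
NULL

#' Construct a sigmoid decay model
#'
#' @param A Upper asymptote (standardized PH units or allele count), > 0.
#' @param t50 Midpoint, hours.
#' @param k Slope per hour, > 0 for decay.
#' @param rss Residual sum of squares of a fit (optional).
#' @param converged Convergence flag (optional).
#' @return Object of class `sigmoid_model`.
#' @export
sigmoid_model <- function(A, t50, k, rss = NA_real_, converged = TRUE) {
  stopifnot(A > 0)
  structure(list(A = A, t50 = t50, k = k, rss = rss, converged = converged),
            class = "sigmoid_model")
}

#' @export
print.sigmoid_model <- function(x, ...) {
  cat(sprintf("<sigmoid_model A=%.4g t50=%.4g h k=%.4g /h%s>\n",
              x$A, x$t50, x$k,
              if (!isTRUE(x$converged)) " (NOT converged)" else ""))
  invisible(x)
}

#' Predict from a sigmoid decay model
#'
#' @param object A `sigmoid_model`.
#' @param t Times in hours.
#' @param ... Unused.
#' @return `A / (1 + exp(k * (t - t50)))`.
#' @export
predict.sigmoid_model <- function(object, t, ...) {
  object$A / (1 + exp(object$k * (t - object$t50)))
}

#' Fit the descending sigmoid by least squares
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nlsLM()]) of
#' `v(t) = A / (1 + exp(k * (t - t50)))`, initialised at `A = max(values)`,
#' `t50` at the time whose value lies nearest `A/2`, `k = 0.1`/h, with bounds
#' `A > 0`, `k >= 0`. Degenerate inputs (constant values) and non-convergence
#' are flagged in the returned model, never silently defaulted.
#'
#' @param times Observation times, hours (>= 4 points).
#' @param values Observed values (same length).
#' @return A `sigmoid_model` with `rss` and `converged`.
#' @export
fit_sigmoid <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 4)
  if (stats::sd(values) == 0) {
    return(sigmoid_model(A = max(max(values), .Machine$double.eps),
                         t50 = mean(times), k = .Machine$double.eps,
                         rss = 0, converged = FALSE))
  }
  A0 <- max(values)
  t50_0 <- times[which.min(abs(values - A0 / 2))]
  df <- data.frame(t = times, v = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ A / (1 + exp(k * (t - t50))), data = df,
                      start = list(A = A0, t50 = t50_0, k = 0.1),
                      lower = c(A = 1e-12, t50 = -Inf, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(sigmoid_model(A = A0, t50 = t50_0, k = .Machine$double.eps,
                         rss = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  sigmoid_model(A = cf[["A"]], t50 = cf[["t50"]], k = cf[["k"]],
                rss = sum(stats::residuals(fit)^2),
                converged = cf[["k"]] > 1e-10)
}

#' Invert a sigmoid model: time at which a value is reached
#'
#' Exact functional inverse of [predict.sigmoid_model()] on `(0, A)`:
#' `t = t50 + log(A / value - 1) / k`.
#'
#' @param model A `sigmoid_model`.
#' @param value Observed value, strictly between 0 and `A`.
#' @return Estimated post-feeding time in hours.
#' @export
invert_time <- function(model, value) {
  if (any(value <= 0 | value >= model$A))
    stop("invert_time(): value must lie strictly inside (0, A)")
  model$t50 + log(model$A / value - 1) / model$k
}

#' Detectability summary per post-feeding time point
#'
#' For each time point: the mean number of detected alleles (homozygous
#' single-peak loci count as two allele copies) and the mean and standard
#' deviation of per-sample mean peak heights standardized across the whole
#' batch (Sneath-Sokal ranging, the default scope for the digestion
#' comparison). Samples with no detected alleles contribute 0 alleles and 0
#' standardized PH.
#'
#' @param profiles List of `str_profile`.
#' @param times Numeric vector of post-feeding times (hours), parallel to
#'   `profiles`.
#' @param panel Panel whose loci are counted.
#' @return Data frame `time_h, mean_alleles, mean_std_ph, sd_std_ph, n`.
#' @export
detectability_table <- function(profiles, times, panel) {
  stopifnot(length(profiles) == length(times))
  n_alleles <- vapply(profiles, function(p) {
    loci <- intersect(typed_loci(p), panel$locus)
    if (length(loci) == 0) return(0)
    sum(vapply(loci, function(loc) {
      df <- p$calls[[loc]]
      if (nrow(df) == 1) 2L else nrow(df)   # homozygote single peak = 2 copies
    }, integer(1)))
  }, numeric(1))
  raw_ph <- vapply(profiles, function(p) {
    h <- unlist(lapply(p$calls, function(df) df$height), use.names = FALSE)
    h <- h[!is.na(h)]
    if (length(h) == 0) 0 else mean(h)
  }, numeric(1))
  std_ph <- standardize_ph(raw_ph)
  out <- do.call(rbind, lapply(sort(unique(times)), function(tt) {
    idx <- which(times == tt)
    data.frame(time_h = tt,
               mean_alleles = mean(n_alleles[idx]),
               mean_std_ph = mean(std_ph[idx]),
               sd_std_ph = if (length(idx) > 1) stats::sd(std_ph[idx]) else NA_real_,
               n = length(idx))
  }))
  rownames(out) <- NULL
  out
}
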