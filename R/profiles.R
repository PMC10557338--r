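#' @title Allele calls and multilocus profiles
#' @name profiles
#' @description
#' A `str_profile` is one individual's (or one blood meal's) multilocus
#' genotype: for each typed locus, the allele labels observed there together
#' with their electropherogram peak heights (RFU). Homozygotes appear as a
#' single peak; by the standard convention that peak carries roughly twice the
#' height of a heterozygote's single-allele peak.
NULL

#' Construct a profile from genotype data
#'
#' @param sample_id Sample identifier.
#' @param genotypes Named list: locus -> character vector of allele labels
#'   (one entry per allele copy; a homozygote may be given as one label or the
#'   same label twice).
#' @param heights Optional named list parallel to `genotypes` with peak
#'   heights (RFU), one per *distinct peak*; `NA` heights are allowed for
#'   reference profiles that carry no intensity information.
#' @param sex_locus Name(s) of sex-marker loci (no mixture flagging there).
#' @return An object of class `str_profile`.
#' @export
str_profile <- function(sample_id, genotypes, heights = NULL,
                        sex_locus = "Amelogenin") {
  stopifnot(is.list(genotypes),
            length(genotypes) == 0 || !is.null(names(genotypes)))
  calls <- list()
  for (loc in names(genotypes)) {
    al <- as.character(genotypes[[loc]])
    if (length(al) == 0) next
    if (is.null(heights) || is.null(heights[[loc]])) {
      df <- data.frame(allele = al, height = NA_real_, size_bp = NA_real_,
                       stringsAsFactors = FALSE)
    } else {
      h <- as.numeric(heights[[loc]])
      if (length(h) != length(al))
        stop("heights for locus ", loc, " do not match its alleles")
      df <- data.frame(allele = al, height = h, size_bp = NA_real_,
                       stringsAsFactors = FALSE)
      df <- df[order(-df$height, df$allele), , drop = FALSE]
    }
    rownames(df) <- NULL
    calls[[loc]] <- df
  }
  new_profile(sample_id, calls, sex_locus = sex_locus)
}

new_profile <- function(sample_id, calls, sex_locus = "Amelogenin") {
  non_sex <- setdiff(names(calls), sex_locus)
  n_distinct <- vapply(calls[non_sex],
                       function(df) length(unique(df$allele)), integer(1))
  structure(
    list(sample_id = as.character(sample_id),
         calls = calls,
         n_typed_loci = length(calls),
         mixture_candidate = length(n_distinct) > 0 && any(n_distinct > 2)),
    class = "str_profile")
}

#' @export
print.str_profile <- function(x, ...) {
  cat(sprintf("<str_profile %s: %d typed loci%s>\n", x$sample_id,
              x$n_typed_loci,
              if (isTRUE(x$mixture_candidate)) ", candidate mixture" else ""))
  invisible(x)
}

#' Loci typed in a profile
#' @param profile An `str_profile`.
#' @return Character vector of locus names with at least one call.
#' @export
typed_loci <- function(profile) names(profile$calls)

#' Bin sized electropherogram peaks into allele calls
#'
#' Each peak is assigned to the unique panel locus that shares its multiplex
#' and dye and whose tolerance-widened size range
#' `[size_min - tol_bp, size_max + tol_bp]` contains the fragment size. Allele
#' labels are integer repeat offsets from the range start,
#' `round((size_bp - size_min) / repeat_unit_len)`; sex-marker loci are
#' labelled by amplicon ("X" at the short fragment, "Y" at the long one, the
#' X/Y indel of Amelogenin at 106/112 bp). Peaks matching no locus, or more
#' than one (a panel conflict), are returned in a `rejected` table with the
#' reason; nothing is assigned silently.
#'
#' @param peaks Data frame with columns `sample_id, multiplex, dye, size_bp,
#'   height`.
#' @param panel An `str_panel`.
#' @param tol_bp Binning tolerance in bp (default 0.5, conventional capillary
#'   electrophoresis resolution).
#' @return List with `calls` (`sample_id, locus, allele, size_bp, height`) and
#'   `rejected` (the unassignable peaks plus a `reason` column).
#' @export
bin_peaks <- function(peaks, panel, tol_bp = 0.5) {
  stopifnot(tol_bp >= 0)
  need <- c("sample_id", "multiplex", "dye", "size_bp", "height")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols) > 0)
    stop("peak table is missing column(s): ", paste(missing_cols, collapse = ", "))
  calls <- data.frame(sample_id = character(), locus = character(),
                      allele = character(), size_bp = numeric(),
                      height = numeric(), stringsAsFactors = FALSE)
  rejected <- cbind(peaks[0, need], data.frame(reason = character()))
  if (nrow(peaks) == 0) return(list(calls = calls, rejected = rejected))

  call_rows <- vector("list", nrow(peaks))
  rej_rows <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    hit <- which(panel$multiplex == pk$multiplex & panel$dye == pk$dye &
                   pk$size_bp >= panel$size_min - tol_bp &
                   pk$size_bp <= panel$size_max + tol_bp)
    if (length(hit) == 0) {
      rej_rows[[i]] <- cbind(pk[need], data.frame(
        reason = "no locus in range", stringsAsFactors = FALSE))
      next
    }
    if (length(hit) > 1) {
      rej_rows[[i]] <- cbind(pk[need], data.frame(
        reason = paste0("ambiguous: ", paste(panel$locus[hit], collapse = ",")),
        stringsAsFactors = FALSE))
      next
    }
    loc <- panel[hit, ]
    if (isTRUE(loc$sex_marker)) {
      # nearest amplicon wins: the short fragment is X, the long one Y
      allele <- if (abs(pk$size_bp - loc$size_min) <=
                      abs(pk$size_bp - loc$size_max)) "X" else "Y"
    } else {
      allele <- as.character(max(0L, as.integer(
        round((pk$size_bp - loc$size_min) / loc$repeat_unit_len))))
    }
    call_rows[[i]] <- data.frame(sample_id = pk$sample_id, locus = loc$locus,
                                 allele = allele, size_bp = pk$size_bp,
                                 height = pk$height, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, c(list(calls), Filter(Negate(is.null), call_rows)))
  rejected <- do.call(rbind, c(list(rejected), Filter(Negate(is.null), rej_rows)))
  rownames(calls) <- rownames(rejected) <- NULL
  list(calls = calls, rejected = rejected)
}

#' Assemble one sample's allele calls into a profile
#'
#' Groups calls by locus (tallest peak first). A profile showing more than two
#' distinct alleles at any non-sex locus is flagged as a candidate mixture
#' (multiple feeding); `n_typed_loci` counts panel loci with at least one
#' call.
#'
#' @param calls Call table (from [bin_peaks()]) for a single sample.
#' @param panel An `str_panel`; calls at loci absent from it are an error.
#' @return An `str_profile`.
#' @export
calls_to_profile <- function(calls, panel) {
  if (nrow(calls) == 0) return(new_profile("(empty)", list(), sex_loci(panel)))
  ids <- unique(calls$sample_id)
  if (length(ids) != 1)
    stop("calls_to_profile() expects a single sample, got: ",
         paste(ids, collapse = ", "))
  bad <- setdiff(unique(calls$locus), panel$locus)
  if (length(bad) > 0)
    stop("calls reference loci absent from panel: ", paste(bad, collapse = ", "))
  call_list <- list()
  for (loc in panel$locus) {
    df <- calls[calls$locus == loc, c("allele", "height", "size_bp"), drop = FALSE]
    if (nrow(df) == 0) next
    df <- df[order(-df$height, df$allele), , drop = FALSE]
    rownames(df) <- NULL
    call_list[[loc]] <- df
  }
  new_profile(ids, call_list, sex_locus = sex_loci(panel))
}

#' Split a call table into per-sample profiles
#'
#' @param calls Call table possibly covering many samples.
#' @param panel An `str_panel`.
#' @return Named list of `str_profile`, one per sample id.
#' @export
profiles_from_calls <- function(calls, panel) {
  if (nrow(calls) == 0) return(list())
  out <- lapply(split(calls, calls$sample_id), calls_to_profile, panel = panel)
  out[order(names(out))]
}

#' Per-allele peak heights with the homozygote rule
#'
#' Heterozygous loci keep their observed peak heights. A homozygote presents a
#' single peak of about twice a heterozygote's single-allele height, so a
#' single-peak locus is expanded to two per-allele heights of half the
#' observed peak each. Total locus signal is conserved.
#'
#' @param profile An `str_profile` with at most 2 alleles per locus (run after
#'   deconvolution for mixtures).
#' @return Named list: locus -> numeric vector of per-allele heights (names
#'   are allele labels).
#' @export
per_allele_heights <- function(profile) {
  out <- list()
  for (loc in names(profile$calls)) {
    df <- profile$calls[[loc]]
    if (nrow(df) > 2)
      stop("per_allele_heights(): locus ", loc,
           " has >2 peaks; deconvolve the mixture first")
    if (nrow(df) == 1) {
      h <- rep(df$height / 2, 2)
      names(h) <- rep(df$allele, 2)
    } else {
      h <- df$height
      names(h) <- df$allele
    }
    out[[loc]] <- h
  }
  out
}

#' Mean peak height across detected alleles
#'
#' The sum of the peak heights of the alleles detected in a sample divided by
#' the number of alleles detected (observed peaks, without homozygote
#' splitting).
#'
#' @param profile An `str_profile` with height information.
#' @return Mean peak height in RFU.
#' @export
mean_ph <- function(profile) {
  h <- unlist(lapply(profile$calls, function(df) df$height), use.names = FALSE)
  h <- h[!is.na(h)]
  if (length(h) == 0)
    stop("mean_ph(): no detected alleles with heights in sample ",
         profile$sample_id)
  mean(h)
}

#' Range-standardize peak-height statistics
#'
#' Sneath-Sokal "ranging": `(x - min) / (max - min)` over the batch being
#' compared, mapping the batch minimum to 0 and maximum to 1. A constant batch
#' maps to all zeros with a warning.
#'
#' @param values Numeric vector of per-sample statistics from one batch.
#' @return Standardized values in `[0, 1]`.
#' @export
standardize_ph <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) == 0) return(numeric(0))
  rng <- range(values, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("standardize_ph(): constant batch, all values mapped to 0")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / diff(rng)
}

#' Classify profile completeness
#'
#' `complete` when every panel locus is typed, `nearly_complete` when at least
#' `nearly` loci are typed (the >= 11 of 13 field rule), `incomplete`
#' otherwise.
#'
#' @param profile An `str_profile`.
#' @param panel The panel the profile is scored against (typically the
#'   post-exclusion 13-human-locus panel).
#' @param nearly Minimum typed loci for `nearly_complete` (default 11).
#' @return One of `"complete"`, `"nearly_complete"`, `"incomplete"`.
#' @export
completeness <- function(profile, panel, nearly = 11) {
  n <- sum(panel$locus %in% typed_loci(profile))
  if (n == nrow(panel)) "complete"
  else if (n >= nearly) "nearly_complete"
  else "incomplete"
}

#' Write profiles to a long-format CSV
#'
#' One row per allele call: `sample_id, locus, allele, height`.
#'
#' @param profiles List of `str_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profile_table(profiles), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten profiles to a call table
#' @param profiles List of `str_profile`.
#' @return Data frame `sample_id, locus, allele, height`.
#' @export
profile_table <- function(profiles) {
  rows <- list()
  for (p in profiles) {
    for (loc in names(p$calls)) {
      df <- p$calls[[loc]]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = p$sample_id, locus = loc, allele = df$allele,
        height = df$height, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sample_id = character(), locus = character(),
                      allele = character(), height = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read profiles from a long-format CSV
#'
#' @param path CSV with columns `sample_id, locus, allele` and optionally
#'   `height`.
#' @param panel An `str_panel` used to validate loci and flag mixtures.
#' @return Named list of `str_profile`.
#' @export
read_profiles <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(allele = "character"))
  if (!"height" %in% names(df)) df$height <- NA_real_
  df$size_bp <- NA_real_
  profiles_from_calls(df[, c("sample_id", "locus", "allele", "height", "size_bp")],
                      panel)
}
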