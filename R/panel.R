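#' @title STR panel model
#' @name panel
#' @description
#' A panel is the machine-readable description of the combined human-mosquito
#' STR marker set: one row per locus with its organism, repeat motif, repeat
#' unit length, allele size range in base pairs, amplification multiplex and
#' fluorescent dye. Two layouts ship with the package: `"bloodmeal"` (all 35
#' loci, 16 human + 19 *Aedes albopictus*, spread over three multiplexes, the
#' dye set used on blood-fed mosquitoes) and `"swab"` (the 16 human loci in a
#' single multiplex, the dye set used on buccal-swab references).
NULL

.panel_columns <- c("locus", "organism", "repeat_motif", "repeat_unit_len",
                    "size_min", "size_max", "multiplex", "dye", "sex_marker")

#' Load an STR panel definition
#'
#' Reads a panel from a packaged fixture (`"bloodmeal"` or `"swab"`) or from a
#' CSV/JSON file with columns `locus, organism, repeat_motif, repeat_unit_len,
#' size_min, size_max, multiplex, dye, sex_marker`. The result is validated:
#' locus names must be unique, size ranges ordered, repeat unit lengths
#' positive (sex markers such as Amelogenin may instead rely on their explicit
#' X/Y amplicon sizes).
#'
#' @param source `"bloodmeal"`, `"swab"`, or a path to a panel CSV/JSON file.
#' @return A `str_panel`: a data frame of loci with a `context` attribute.
#' @examples
#' panel <- load_panel("bloodmeal")
#' nrow(panel)                       # 35
#' table(panel$organism)             # 16 human, 19 mosquito
#' @export
load_panel <- function(source = "bloodmeal") {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% c("bloodmeal", "swab")) {
    path <- system.file("extdata", paste0("panel_", source, ".csv"),
                        package = "bloodmealSTR", mustWork = TRUE)
    context <- source
  } else {
    path <- source
    context <- "custom"
    if (!file.exists(path)) stop("panel source not found: ", path)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_panel(df, context = context)
}

#' Construct and validate a panel from a data frame
#'
#' @param df Data frame with the panel columns (see [load_panel()]).
#' @param context Label for the dye layout, e.g. `"bloodmeal"` or `"swab"`.
#' @return A validated `str_panel`.
#' @export
as_panel <- function(df, context = "custom") {
  missing_cols <- setdiff(.panel_columns, names(df))
  if (length(missing_cols) > 0)
    stop("panel table is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, .panel_columns, drop = FALSE]
  if (nrow(df) > 0) {
    df$locus <- as.character(df$locus)
    df$organism <- as.character(df$organism)
    df$dye <- as.character(df$dye)
    df$sex_marker <- as.logical(df$sex_marker)
    for (col in c("repeat_unit_len", "size_min", "size_max", "multiplex"))
      df[[col]] <- as.integer(df[[col]])
    .check_panel_rows(df)
  }
  rownames(df) <- NULL
  structure(df, context = context, class = c("str_panel", "data.frame"))
}

.check_panel_rows <- function(df) {
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    fail <- function(field, msg)
      stop(sprintf("panel row %d (locus '%s'), field '%s': %s",
                   i, row$locus, field, msg), call. = FALSE)
    if (is.na(row$locus) || !nzchar(row$locus)) fail("locus", "empty name")
    if (!row$organism %in% c("human", "mosquito"))
      fail("organism", "must be 'human' or 'mosquito'")
    if (is.na(row$size_min) || is.na(row$size_max) || row$size_min >= row$size_max)
      fail("size_min/size_max", "need size_min < size_max")
    if (!isTRUE(row$sex_marker) && (is.na(row$repeat_unit_len) || row$repeat_unit_len < 1))
      fail("repeat_unit_len", "must be >= 1 bp for non-sex loci")
  }
  dup <- unique(df$locus[duplicated(df$locus)])
  if (length(dup) > 0)
    stop("duplicate locus name(s) in panel: ", paste(dup, collapse = ", "))
  invisible(df)
}

#' Write a panel definition to CSV
#'
#' @param panel An `str_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect size-range conflicts within a panel
#'
#' Two loci conflict when they share a multiplex and a dye and their closed
#' allele size ranges `[size_min, size_max]` intersect: a sized fragment in the
#' overlap cannot be assigned unambiguously. On the packaged blood-meal layout
#' this reports the two overlaps present in the published marker table
#' (Alb-tri-21/Aealbmic7 and Alb-tri-6/D21S11); the swab layout is
#' conflict-free.
#'
#' @param panel An `str_panel`.
#' @return Data frame with one row per unordered conflicting pair:
#'   `locus_a, locus_b, multiplex, dye, overlap_lo, overlap_hi` (empty when
#'   there is no conflict).
#' @export
validate_panel <- function(panel) {
  out <- data.frame(locus_a = character(), locus_b = character(),
                    multiplex = integer(), dye = character(),
                    overlap_lo = integer(), overlap_hi = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(panel) < 2) return(out)
  groups <- split(seq_len(nrow(panel)), paste(panel$multiplex, panel$dye, sep = "/"))
  for (idx in groups) {
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1), length(idx))) {
        ia <- idx[a]; ib <- idx[b]
        lo <- max(panel$size_min[ia], panel$size_min[ib])
        hi <- min(panel$size_max[ia], panel$size_max[ib])
        if (lo <= hi) {
          out <- rbind(out, data.frame(
            locus_a = panel$locus[ia], locus_b = panel$locus[ib],
            multiplex = panel$multiplex[ia], dye = panel$dye[ia],
            overlap_lo = lo, overlap_hi = hi, stringsAsFactors = FALSE))
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Remove loci from a panel by name
#'
#' Applies a named exclusion list (e.g. the field exclusions PentaD, vWA and
#' D5S818, dropped after the field trial for amplification failure and
#' cross-locus size overlap) and returns a new panel; the input is unchanged.
#'
#' @param panel An `str_panel`.
#' @param excluded Character vector of locus names to remove (may be empty).
#' @return The panel without the excluded loci.
#' @examples
#' field <- apply_exclusions(load_panel("bloodmeal"), field_exclusions())
#' nrow(field)                               # 32
#' sum(field$organism == "human")            # 13
#' @export
apply_exclusions <- function(panel, excluded) {
  excluded <- as.character(excluded)
  unknown <- setdiff(excluded, panel$locus)
  if (length(unknown) > 0)
    stop("exclusion names not in panel: ", paste(unknown, collapse = ", "))
  out <- panel[!panel$locus %in% excluded, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, context = attr(panel, "context"),
            class = c("str_panel", "data.frame"))
}

#' Field-trial locus exclusions
#'
#' The three human loci dropped for field analyses: PentaD (long 376-449 bp
#' amplicons that fail on degraded template) and vWA/D5S818 (allele size
#' overlap with other markers under field scoring). Kept as configuration, not
#' recomputed from the printed ranges.
#'
#' @return Character vector of locus names.
#' @export
field_exclusions <- function() c("PentaD", "vWA", "D5S818")

#' Subset a panel by organism
#'
#' @param panel An `str_panel`.
#' @param organism `"human"` or `"mosquito"`.
#' @return The panel restricted to that organism's loci.
#' @export
panel_subset <- function(panel, organism) {
  stopifnot(organism %in% c("human", "mosquito"))
  out <- panel[panel$organism == organism, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, context = attr(panel, "context"),
            class = c("str_panel", "data.frame"))
}

# Names of sex-determining loci in a panel (Amelogenin in the shipped layouts).
sex_loci <- function(panel) panel$locus[panel$sex_marker]
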