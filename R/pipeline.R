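#' @title End-to-end blood-meal profiling pipeline
#' @name pipeline
#' @description
#' Binds the modules into the full workflow: peak binning on the combined
#' panel, per-mosquito human profiles, multiple-feeding detection and
#' deconvolution, reference matching under the D_A threshold, biting-network
#' assembly and the field summary. Deterministic given inputs and
#' configuration.
NULL

#' Pipeline configuration
#'
#' @param tol_bp Peak binning tolerance, bp (default 0.5).
#' @param exclude Locus names removed before analysis (default the field
#'   exclusions PentaD, vWA, D5S818).
#' @param da_threshold Strict Nei's D_A match threshold (default 0.15).
#' @param min_shared Minimum jointly typed loci for a comparison (default 6).
#' @param major_ratio Deconvolution height ratio (default 2).
#' @param consistency Major-profile consistency fraction (default 0.75).
#' @param nearly Typed-locus floor for `nearly_complete` (default 11).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tol_bp = 0.5, exclude = field_exclusions(),
                            da_threshold = 0.15, min_shared = 6,
                            major_ratio = 2, consistency = 0.75, nearly = 11) {
  structure(list(tol_bp = tol_bp, exclude = exclude,
                 da_threshold = da_threshold, min_shared = min_shared,
                 major_ratio = major_ratio, consistency = consistency,
                 nearly = nearly),
            class = "pipeline_config")
}

#' Run the full blood-meal analysis pipeline
#'
#' Stages: (1) apply configured locus exclusions to the panel; (2) bin the
#' peak table into allele calls; (3) build one human profile per mosquito
#' (mosquito-locus calls are returned separately); (4) detect multiple
#' feedings and deconvolve each blood meal into a major profile plus minor
#' partial profiles; (5) match every contributor profile against the
#' reference database with the strict D_A rule; (6) assemble the bipartite
#' biting network and the field summary. Stage errors are annotated with the
#' stage name.
#'
#' @param peaks Peak table (`sample_id, multiplex, dye, size_bp, height`).
#' @param references List of reference `str_profile` (saliva database).
#' @param panel Full `str_panel` (default the packaged blood-meal layout).
#' @param n_collected Total mosquitoes collected, for the summary
#'   denominator; defaults to the number of distinct sample ids in `peaks`.
#' @param sessions Optional named vector mosquito id -> session label.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: writes profiles, matches, mixture
#'   assignments, network edges, the summary JSON and a manifest.
#' @return List with `panel`, `calls`, `rejected`, `human_profiles`,
#'   `mosquito_calls`, `mixtures`, `query_profiles`, `matches`, `network`,
#'   `summary`.
#' @export
run_pipeline <- function(peaks, references, panel = load_panel("bloodmeal"),
                         n_collected = NULL, sessions = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  panel2 <- stage("panel", apply_exclusions(panel, config$exclude))
  human_panel <- panel_subset(panel2, "human")
  if (is.null(n_collected))
    n_collected <- length(unique(peaks$sample_id))

  binned <- stage("bin_peaks", bin_peaks(peaks, panel2, tol_bp = config$tol_bp))
  is_human <- binned$calls$locus %in% human_panel$locus
  human_calls <- binned$calls[is_human, , drop = FALSE]
  mosquito_calls <- binned$calls[!is_human, , drop = FALSE]

  human_profiles <- stage("profiles",
                          profiles_from_calls(human_calls, human_panel))
  mixtures <- stage("deconvolve", lapply(human_profiles, deconvolve,
                                         major_ratio = config$major_ratio,
                                         consistency = config$consistency))
  queries <- list()
  for (m in mixtures)
    queries <- c(queries, list(m$major_profile), m$minor_profiles)
  queries <- Filter(function(p) p$n_typed_loci > 0, queries)

  matches <- if (length(queries) > 0 && length(references) > 0)
    stage("match", match_profiles(queries, references,
                                  threshold = config$da_threshold,
                                  min_shared = config$min_shared))
  else list()
  network <- stage("network", build_network(mixtures, matches, sessions,
                                            panel = human_panel,
                                            nearly = config$nearly))
  summary <- stage("summary", network_summary(network, n_collected))

  bundle <- list(panel = panel2, calls = binned$calls,
                 rejected = binned$rejected, human_profiles = human_profiles,
                 mosquito_calls = mosquito_calls, mixtures = mixtures,
                 query_profiles = queries, matches = matches,
                 network = network, summary = summary)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, config)
  bundle
}

#' Write a pipeline result bundle to disk
#'
#' Emits `profiles.csv`, `matches.csv`, `mixtures.csv`, `network_edges.csv`,
#' `summary.json` and `manifest.json` (the exact configuration plus per-stage
#' counts) under `out_dir`.
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param config The `pipeline_config` used.
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profiles(bundle$human_profiles, file.path(out_dir, "profiles.csv"))
  utils::write.csv(match_table(bundle$matches),
                   file.path(out_dir, "matches.csv"), row.names = FALSE)
  utils::write.csv(mixture_table(bundle$mixtures),
                   file.path(out_dir, "mixtures.csv"), row.names = FALSE)
  write_network(bundle$network, file.path(out_dir, "network_edges.csv"))
  jsonlite::write_json(unclass(bundle$summary),
                       file.path(out_dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    config = unclass(config),
    counts = list(peak_calls = nrow(bundle$calls),
                  rejected_peaks = nrow(bundle$rejected),
                  human_profiles = length(bundle$human_profiles),
                  query_profiles = length(bundle$query_profiles),
                  network_edges = nrow(bundle$network$edges)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
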