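#' @title Human-mosquito biting networks
#' @name network
#' @description
#' The field result is a bipartite network: mosquito nodes on one side, human
#' profile nodes on the other, one edge per blood-meal contributor. Matched
#' profiles are annotated with their reference individual, so a profiled
#' person bitten by several mosquitoes appears as one reference shared by
#' several profile nodes.
NULL

# round half away from zero to integer percent (62%, 89%, 11%, 55% style)
pct <- function(num, den) {
  if (den == 0) return(0L)
  x <- 100 * num / den
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Assemble the biting network from mixture and match reports
#'
#' One mosquito node per mixture report, one profile node per contributor
#' (the major profile plus each minor partial profile), and one edge linking
#' the mosquito to each of its contributor profiles. Profile nodes carry
#' their completeness class against `panel` and, when a match report decided
#' `matched`, the reference individual's id.
#'
#' @param mixtures List of `mixture_report`, one per mosquito with human
#'   signal (duplicate mosquito ids are an error).
#' @param matches Optional list of `str_match` keyed by profile node id.
#' @param sessions Optional named character vector mosquito id -> sampling
#'   session label.
#' @param panel Panel for completeness scoring (typically the 13-locus
#'   post-exclusion human panel).
#' @param nearly Completeness threshold passed to [completeness()].
#' @return A `biting_network`: list with data frames `mosquitoes` (`id,
#'   session, n_contributors`), `profiles` (`id, mosquito_id, role,
#'   n_typed_loci, completeness, matched_reference`), `edges` (`mosquito_id,
#'   profile_id`) and an `igraph` bipartite `graph`.
#' @export
build_network <- function(mixtures, matches = NULL, sessions = NULL,
                          panel = NULL, nearly = 11) {
  mosq_ids <- vapply(mixtures, function(m) m$sample_id, character(1))
  if (anyDuplicated(mosq_ids))
    stop("build_network(): duplicate mosquito ids: ",
         paste(unique(mosq_ids[duplicated(mosq_ids)]), collapse = ", "))
  matched <- if (is.null(matches)) character(0) else matched_references(matches)

  prof_rows <- list()
  edge_rows <- list()
  for (m in mixtures) {
    contributors <- c(list(m$major_profile), m$minor_profiles)
    roles <- c("major", if (length(m$minor_profiles) > 0)
      paste0("minor_", seq_along(m$minor_profiles)))
    for (i in seq_along(contributors)) {
      p <- contributors[[i]]
      comp <- if (is.null(panel)) NA_character_ else completeness(p, panel, nearly)
      ref <- if (p$sample_id %in% names(matched)) matched[[p$sample_id]] else NA_character_
      prof_rows[[length(prof_rows) + 1]] <- data.frame(
        id = p$sample_id, mosquito_id = m$sample_id, role = roles[i],
        n_typed_loci = p$n_typed_loci, completeness = comp,
        matched_reference = ref, stringsAsFactors = FALSE)
      edge_rows[[length(edge_rows) + 1]] <- data.frame(
        mosquito_id = m$sample_id, profile_id = p$sample_id,
        stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, c(list(data.frame(
    id = character(), mosquito_id = character(), role = character(),
    n_typed_loci = integer(), completeness = character(),
    matched_reference = character(), stringsAsFactors = FALSE)), prof_rows))
  edges <- do.call(rbind, c(list(data.frame(
    mosquito_id = character(), profile_id = character(),
    stringsAsFactors = FALSE)), edge_rows))
  n_contrib <- vapply(mosq_ids, function(id)
    sum(edges$mosquito_id == id), integer(1))
  session_vec <- if (is.null(sessions)) rep(NA_character_, length(mosq_ids))
                 else unname(sessions[mosq_ids])
  mosquitoes <- data.frame(
    id = if (length(mosq_ids)) mosq_ids else character(0),
    session = session_vec,
    n_contributors = if (length(mosq_ids)) unname(n_contrib) else integer(0),
    stringsAsFactors = FALSE)

  vertices <- rbind(
    data.frame(name = mosquitoes$id,
               type = rep(FALSE, nrow(mosquitoes)), stringsAsFactors = FALSE),
    data.frame(name = profiles$id,
               type = rep(TRUE, nrow(profiles)), stringsAsFactors = FALSE))
  graph <- igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = vertices)
  rownames(mosquitoes) <- rownames(profiles) <- rownames(edges) <- NULL
  structure(list(mosquitoes = mosquitoes, profiles = profiles,
                 edges = edges, graph = graph),
            class = "biting_network")
}

#' @export
print.biting_network <- function(x, ...) {
  cat(sprintf("<biting_network: %d mosquitoes, %d human profiles, %d edges>\n",
              nrow(x$mosquitoes), nrow(x$profiles), nrow(x$edges)))
  invisible(x)
}

#' Field-trial summary counts and percentages
#'
#' All counts use the stated numerators and denominators: the fraction of
#' collected mosquitoes with human DNA is over `n_collected`, single/double
#' meal fractions are over mosquitoes with human DNA, and completeness is
#' over retrieved profiles. Percentages are rounded half away from zero to
#' integer percent.
#'
#' @param net A `biting_network`.
#' @param n_collected Total mosquitoes collected (>= mosquitoes in the
#'   network).
#' @return A `network_summary` list: `n_mosquitoes_collected`,
#'   `n_with_human_dna`, `pct_with_human_dna`, `n_single_meal`,
#'   `n_double_meal`, `n_triple_meal`, `pct_single`, `pct_double`,
#'   `n_profiles_total`, `n_complete_or_nearly`, `pct_complete_or_nearly`,
#'   `n_matched_profiles`, `n_matched_individuals`.
#' @export
network_summary <- function(net, n_collected) {
  n_with <- nrow(net$mosquitoes)
  stopifnot(n_collected >= n_with)
  deg <- net$mosquitoes$n_contributors
  n_single <- sum(deg == 1)
  n_double <- sum(deg == 2)
  n_triple <- sum(deg >= 3)
  n_profiles <- nrow(net$profiles)
  n_complete <- sum(net$profiles$completeness %in%
                      c("complete", "nearly_complete"), na.rm = TRUE)
  n_matched <- sum(!is.na(net$profiles$matched_reference))
  matched_ids <- unique(stats::na.omit(net$profiles$matched_reference))
  structure(list(
    n_mosquitoes_collected = as.integer(n_collected),
    n_with_human_dna = n_with,
    pct_with_human_dna = pct(n_with, n_collected),
    n_single_meal = n_single,
    n_double_meal = n_double,
    n_triple_meal = n_triple,
    pct_single = pct(n_single, n_with),
    pct_double = pct(n_double, n_with),
    n_profiles_total = n_profiles,
    n_complete_or_nearly = n_complete,
    pct_complete_or_nearly = pct(n_complete, n_profiles),
    n_matched_profiles = n_matched,
    n_matched_individuals = length(matched_ids)),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Field summary: %d/%d mosquitoes with human DNA (%d%%); ",
           "%d single / %d double / %d triple meals; %d profiles, ",
           "%d complete or nearly (%d%%); %d matched to %d individual(s)\n"),
    x$n_with_human_dna, x$n_mosquitoes_collected, x$pct_with_human_dna,
    x$n_single_meal, x$n_double_meal, x$n_triple_meal, x$n_profiles_total,
    x$n_complete_or_nearly, x$pct_complete_or_nearly,
    x$n_matched_profiles, x$n_matched_individuals))
  invisible(x)
}

#' Write the network edge list as CSV
#'
#' Layout: `mosquito_id, profile_id, matched_reference, completeness,
#' session`.
#'
#' @param net A `biting_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- merge(net$edges,
              net$profiles[, c("id", "matched_reference", "completeness")],
              by.x = "profile_id", by.y = "id", sort = FALSE)
  el <- merge(el, net$mosquitoes[, c("id", "session")],
              by.x = "mosquito_id", by.y = "id", sort = FALSE)
  el <- el[order(el$mosquito_id, el$profile_id),
           c("mosquito_id", "profile_id", "matched_reference",
             "completeness", "session")]
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}
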