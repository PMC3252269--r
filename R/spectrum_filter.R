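#' Map a taxonomic group label to its distribution-spectrum species set
#'
#' The spectrum filter partitions eukaryote genomes into six sets: protists,
#' fungi, plants, insects, non-insect arthropods and non-arthropod
#' metazoans. Recipient-insect sequences fall in the insect set; prokaryote
#' labels are an error because they are not part of the eukaryote spectrum.
#'
#' @param group Character vector of group labels (see [read_fasta()]).
#' @return Character vector of set labels.
#' @export
assign_species_set <- function(group) {
  check_groups(group)
  if (any(is_prokaryote(group))) {
    abort("Prokaryote groups have no spectrum species set.")
  }
  dplyr::case_match(
    group,
    c("recipient_insect", "other_insect") ~ "insect",
    "non_insect_arthropod" ~ "non_insect_arthropod",
    "non_arthropod_metazoan" ~ "non_arthropod_metazoan",
    "plant" ~ "plant",
    "fungus" ~ "fungus",
    "protist" ~ "protist"
  )
}

#' Taxonomic distribution-spectrum decision for one candidate
#'
#' A candidate is dropped when, in any one of the five non-insect eukaryote
#' sets, more than two distinct species each have a hit with both bit score
#' and identity strictly greater than the candidate's top bacterial hit —
#' i.e. the candidate is better explained by vertical eukaryotic homology.
#' A candidate that would be dropped but has no insect-set hit at all is
#' recovered (kept) instead, because absence from other insects leaves
#' horizontal transfer the plausible explanation. Species are counted once
#' each regardless of how many hits they contribute.
#'
#' @param euk_hits Hit tibble of the candidate against the eukaryote panel,
#'   already filtered to the stage thresholds, with columns `subject_id`,
#'   `bit_score`, `identity_pct` plus per-subject `species` and `group`
#'   (join the species map beforehand or pass `species_map`).
#' @param top_bacterial_hit One-row tibble (or list) with the top bacterial
#'   hit's `bit_score` and `identity_pct`.
#' @param species_map Optional species map to annotate `euk_hits`.
#' @param score_field Field compared as "score" (`"bit_score"` default;
#'   `"raw_score"` available for raw-score screening).
#' @return A one-row tibble: `decision` (`"retain"`, `"drop"`, `"recover"`),
#'   `triggering_set`, `n_better_species`, `n_insect_hits`.
#' @export
spectrum_decision <- function(euk_hits, top_bacterial_hit,
                              species_map = NULL,
                              score_field = c("bit_score", "raw_score")) {
  score_field <- match.arg(score_field)
  if (is.null(top_bacterial_hit) ||
      (is.data.frame(top_bacterial_hit) && nrow(top_bacterial_hit) == 0)) {
    abort("spectrum_decision requires the candidate's top bacterial hit.")
  }
  top_score <- top_bacterial_hit[[score_field]][1]
  top_ident <- top_bacterial_hit$identity_pct[1]
  hits <- euk_hits
  if (!is.null(species_map)) {
    sm <- as_species_map(species_map)
    hits <- dplyr::left_join(
      hits, dplyr::rename(sm, subject_id = "id"), by = "subject_id"
    )
  }
  if (nrow(hits) > 0 && (!("species" %in% names(hits)) ||
                         !("group" %in% names(hits)))) {
    abort("euk_hits need species and group columns (or pass species_map).")
  }
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      decision = "recover", triggering_set = NA_character_,
      n_better_species = 0L, n_insect_hits = 0L
    ))
  }
  hits$set <- assign_species_set(hits$group)
  n_insect <- sum(hits$set == "insect")
  better <- hits |>
    dplyr::filter(.data$set != "insect",
                  .data[[score_field]] > top_score,
                  .data$identity_pct > top_ident) |>
    dplyr::distinct(.data$set, .data$species) |>
    dplyr::count(.data$set, name = "n_species") |>
    dplyr::arrange(dplyr::desc(.data$n_species))
  droppable <- nrow(better) > 0 && better$n_species[1] > 2
  decision <- if (droppable && n_insect == 0) {
    "recover"
  } else if (droppable) {
    "drop"
  } else {
    "retain"
  }
  tibble::tibble(
    decision = decision,
    triggering_set = if (droppable) better$set[1] else NA_character_,
    n_better_species = if (nrow(better) > 0) better$n_species[1] else 0L,
    n_insect_hits = as.integer(n_insect)
  )
}

#' Run the spectrum filter over a set of candidates
#'
#' @param euk_hits Hit tibble (all candidates against the eukaryote panel,
#'   pre-filtered to stage thresholds) with a `query_id` column.
#' @param bacterial_hits Hit tibble against the prokaryote panel; the top
#'   hit per query (highest bit score) is used as the comparison point.
#' @param species_map Species map annotating the subjects of `euk_hits`.
#' @param score_field Passed to [spectrum_decision()].
#' @return A tibble with one row per candidate in `bacterial_hits`:
#'   `candidate_id`, `decision`, `triggering_set`, `n_better_species`,
#'   `n_insect_hits`.
#' @export
spectrum_screen <- function(euk_hits, bacterial_hits, species_map = NULL,
                            score_field = c("bit_score", "raw_score")) {
  score_field <- match.arg(score_field)
  tops <- bacterial_hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_max(.data$bit_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  purrr::map_dfr(seq_len(nrow(tops)), function(i) {
    cand <- tops$query_id[i]
    dec <- spectrum_decision(
      dplyr::filter(euk_hits, .data$query_id == cand),
      tops[i, ], species_map = species_map, score_field = score_field
    )
    dplyr::bind_cols(tibble::tibble(candidate_id = cand), dec)
  })
}
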