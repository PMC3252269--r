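#' Pipeline configuration
#'
#' Bundles every stage parameter of the detection flow: the two similarity
#' threshold stages, spectrum-filter scoring, tree parameters, triage and
#' type-grouping settings, and the global seed.
#'
#' @param blast1,blast3 [threshold_config()]s for the prokaryote screen and
#'   the broad-database confirmation.
#' @param score_field Score compared by the spectrum filter.
#' @param tree_model Distance model for gene trees.
#' @param n_bootstrap Bootstrap replicates in the refinement stage
#'   (default 1000).
#' @param min_support Support threshold for the decisive clade (default 50).
#' @param k_per_group Homologs retained per group at refinement.
#' @param homolog_max_evalue E-value ceiling for collecting tree homologs.
#' @param identity_alert Supporting-flag identity level at triage.
#' @param max_gap_bp,min_identity Type-grouping parameters.
#' @param seed Mandatory global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(blast1 = threshold_config("blast1"),
                            blast3 = threshold_config("blast3"),
                            score_field = "bit_score",
                            tree_model = "kimura",
                            n_bootstrap = 1000, min_support = 50,
                            k_per_group = 3, homolog_max_evalue = 1e-3,
                            identity_alert = 60, max_gap_bp = 50000,
                            min_identity = 40, seed) {
  if (missing(seed)) abort("pipeline_config requires an explicit seed.")
  stopifnot(inherits(blast1, "threshold_config"),
            inherits(blast3, "threshold_config"),
            n_bootstrap >= 1, min_support >= 0, min_support <= 100,
            k_per_group >= 1, homolog_max_evalue > 0)
  structure(
    list(blast1 = blast1, blast3 = blast3, score_field = score_field,
         tree_model = tree_model, n_bootstrap = n_bootstrap,
         min_support = min_support, k_per_group = k_per_group,
         homolog_max_evalue = homolog_max_evalue,
         identity_alert = identity_alert, max_gap_bp = max_gap_bp,
         min_identity = min_identity, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Assemble pipeline inputs from a synthetic simulation
#'
#' Extracts only what a real screen would have — the recipient gene set,
#' the comparison panel, annotations and the superfamily map — never the
#' truth table.
#'
#' @param sim An `hgt_simulation` from [generate_dataset()].
#' @return An input list for [run_pipeline()].
#' @export
pipeline_inputs <- function(sim) {
  stopifnot(inherits(sim, "hgt_simulation"))
  recipient <- dplyr::filter(sim$sequences,
                             .data$species == sim$recipient_species)
  panel <- dplyr::filter(sim$sequences,
                         .data$species != sim$recipient_species)
  list(
    recipient = recipient,
    panel = panel,
    annotations = sim$annotations,
    superfamily_map = sim$superfamily_map
  )
}

#' Run the full HGT-detection pipeline
#'
#' Executes the staged flow on a recipient gene set: (1) exact-alignment
#' screen against the prokaryote panel with blast-I thresholds; (2) the
#' eukaryote distribution-spectrum filter; (3) optional broad-database
#' confirmation from a second hit table with blast-III thresholds and
#' domain rescue; (4) first-pass gene trees (distances + BIONJ, midpoint
#' root) with topology classification; (5) bootstrap refinement of
#' unresolved candidates; (6) contamination triage from gene-level
#' evidence; (7) donor and transfer-depth inference and transfer-event
#' type grouping; (8) the accompanying statistics (similarity enrichment,
#' intron-free draws, GC amelioration) computed on the survivors against
#' the stage-1 background. Every input gene ends up exactly once in the
#' audit trail, as a survivor or with a removal reason.
#'
#' @param inputs A list: `recipient` (query sequence tibble), `panel`
#'   (comparison sequences with `species`/`group`), `annotations`
#'   (per-gene evidence incl. coordinates), optional precomputed hit
#'   tables `hits1` (vs prokaryotes) / `hits2` (vs eukaryotes) / `hits3`
#'   (broad database), optional `domain_annotations`, `alignments` (named
#'   per-candidate aligned blocks), `superfamily_map` (species ->
#'   superfamily), `donor_gc`.
#' @param config A [pipeline_config()].
#' @return A list of class `hgt_pipeline_result`: `calls` (per input gene:
#'   `final_call`, topology class/type, support, donor, transfer depth,
#'   type group, triage verdict), `audit`, `funnel`, `stats`, `config`.
#' @export
run_pipeline <- function(inputs, config) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("recipient", "panel", "annotations")
  miss <- setdiff(need, names(inputs))
  if (length(miss) > 0) {
    abort(paste0("Missing pipeline input(s): ", paste(miss, collapse = ", ")))
  }
  recipient <- inputs$recipient
  panel <- inputs$panel
  audit <- list()
  note <- function(ids, stage, decision, reason) {
    if (length(ids) == 0) return()
    audit[[length(audit) + 1]] <<- tibble::tibble(
      gene_id = ids, stage = stage, decision = decision, reason = reason
    )
  }
  funnel <- list(c(stage = "input", n = nrow(recipient)))
  if (nrow(recipient) == 0) {
    return(finish_pipeline(recipient, tibble::tibble(
      gene_id = character(), stage = character(), decision = character(),
      reason = character()
    ), list(), list(), config,
    tibble::tibble(stage = "input", n = 0L)))
  }

  prok <- dplyr::filter(panel, is_prokaryote(.data$group))
  euk <- dplyr::filter(panel, !is_prokaryote(.data$group))

  # -- blast-I: recipient vs prokaryote panel ------------------------------
  hits1 <- if (!is.null(inputs$hits1)) inputs$hits1 else {
    search_hits(recipient, prok, max_evalue = config$homolog_max_evalue)
  }
  qlen <- setNames(nchar(recipient$residues), recipient$id)
  hits1_pass <- apply_hit_filter(hits1, config$blast1, query_lengths = qlen)
  survivors <- intersect(recipient$id, unique(hits1_pass$query_id))
  note(setdiff(recipient$id, survivors), "blast1", "removed",
       "no qualifying prokaryote similarity")
  funnel <- c(funnel, list(c(stage = "blast1", n = length(survivors))))

  # -- blast-II: eukaryote distribution spectrum ---------------------------
  hits2 <- empty_hit_table()
  if (length(survivors) > 0) {
    cand_seq <- dplyr::filter(recipient, .data$id %in% survivors)
    hits2 <- if (!is.null(inputs$hits2)) {
      inputs$hits2
    } else {
      search_hits(cand_seq, euk, max_evalue = config$homolog_max_evalue)
    }
    hits2_pass <- apply_hit_filter(hits2, config$blast1,
                                   query_lengths = qlen)
    spect <- spectrum_screen(
      hits2_pass,
      dplyr::filter(hits1_pass, .data$query_id %in% survivors),
      species_map = panel[, c("id", "species", "group")],
      score_field = config$score_field
    )
    dropped <- spect$candidate_id[spect$decision == "drop"]
    note(dropped, "blast2", "removed",
         "better explained by eukaryote homology")
    survivors <- setdiff(survivors, dropped)
  } else {
    hits2_pass <- empty_hit_table()
    spect <- tibble::tibble(candidate_id = character())
  }
  funnel <- c(funnel, list(c(stage = "blast2", n = length(survivors))))

  # -- blast-III: broad-database confirmation (precomputed hit table) ------
  if (!is.null(inputs$hits3) && length(survivors) > 0) {
    hits3_pass <- apply_hit_filter(inputs$hits3, config$blast3,
                                   domain_annotations =
                                     inputs$domain_annotations,
                                   query_lengths = qlen)
    sm <- panel[, c("id", "group")]
    prok_ok <- hits3_pass |>
      dplyr::left_join(dplyr::rename(sm, subject_id = "id"),
                       by = "subject_id") |>
      dplyr::filter(is_prokaryote(.data$group)) |>
      dplyr::pull("query_id") |>
      unique()
    gone <- setdiff(survivors, prok_ok)
    note(gone, "blast3", "removed",
         "no prokaryote similarity in broad database")
    survivors <- intersect(survivors, prok_ok)
  }
  funnel <- c(funnel, list(c(stage = "blast3", n = length(survivors))))

  # -- trees: first pass + bootstrap refinement ----------------------------
  all_seqs <- dplyr::bind_rows(recipient, panel)
  taxa <- tibble::tibble(
    id = all_seqs$id,
    species = if ("species" %in% names(all_seqs)) all_seqs$species else
      all_seqs$id,
    group = all_seqs$group
  )
  hits_all <- dplyr::bind_rows(hits1, hits2)
  calls <- list()
  for (cand in survivors) {
    hom <- hits_all |>
      dplyr::filter(.data$query_id == cand,
                    .data$evalue <= config$homolog_max_evalue)
    hom_ids <- union(cand, hom$subject_id)
    # recipient-lineage copies of the candidate (tandem duplicates) join
    # the focal side when they hit the same subjects
    aln <- candidate_alignment(cand, hom_ids, inputs, all_seqs)
    if (is.null(aln) || nrow(aln) < 4) {
      calls[[cand]] <- too_few_call(cand)
      next
    }
    focal <- union(cand, intersect(
      rownames(aln), taxa$id[taxa$group == "recipient_insect"]
    ))
    tr <- midpoint_root(
      bionj_tree(protein_distance_matrix(aln, config$tree_model))
    )
    call <- classify_topology(tr, focal, taxa,
                              min_support = config$min_support)
    call$stage <- "tree1"
    if (call$class == "unresolved") {
      call <- refine_and_recall(
        cand, aln, taxa, focal_ids = focal,
        k_per_group = config$k_per_group,
        n_bootstrap = config$n_bootstrap,
        min_support = config$min_support,
        seed = config$seed + match(cand, survivors)
      )
      call$stage <- "tree2"
    }
    call$candidate_id <- cand
    calls[[cand]] <- call
  }
  call_tbl <- dplyr::bind_rows(calls)
  vertical_ids <- call_tbl$candidate_id[call_tbl$class == "vertical"]
  unresolved_ids <- call_tbl$candidate_id[call_tbl$class == "unresolved"]
  note(vertical_ids, "phylogeny", "removed", "vertical topology")
  note(unresolved_ids, "phylogeny", "removed", "unresolved topology")
  survivors <- setdiff(survivors, c(vertical_ids, unresolved_ids))
  funnel <- c(funnel, list(c(stage = "phylogeny", n = length(survivors))))

  # -- determination: contamination triage ---------------------------------
  ann <- dplyr::rename(tibble::as_tibble(inputs$annotations),
                       dplyr::any_of(c(gene_id = "id")))
  top_ident <- hits1_pass |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_max(.data$bit_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(gene_id = "query_id", top_hit_identity_pct =
                    "identity_pct")
  contaminant_ids <- character(0)
  triage <- NULL
  if (length(survivors) > 0) {
    ev <- ann |>
      dplyr::filter(.data$gene_id %in% survivors) |>
      dplyr::left_join(top_ident, by = "gene_id")
    triage <- triage_contamination(ev, identity_alert =
                                     config$identity_alert)
    contaminant_ids <- triage$gene_id[triage$verdict ==
                                        "suspected_contaminant"]
    note(contaminant_ids, "determination", "removed",
         "suspected genomic contamination")
    survivors <- setdiff(survivors, contaminant_ids)
  }
  funnel <- c(funnel, list(c(stage = "determination", n = length(survivors))))
  note(survivors, "final", "retained", "HGT call")

  # -- donor, transfer depth, type groups ----------------------------------
  species_of <- setNames(taxa$species, taxa$id)
  final_calls <- purrr::map_dfr(survivors, function(cand) {
    call <- calls[[cand]]
    ranking <- hits1_pass |>
      dplyr::filter(.data$query_id == cand) |>
      dplyr::arrange(dplyr::desc(.data$bit_score)) |>
      dplyr::mutate(species = unname(species_of[.data$subject_id])) |>
      dplyr::select("species", "bit_score")
    don <- infer_donor(call, ranking)
    depth <- NA_character_
    if (!is.null(inputs$superfamily_map)) {
      hom_sp <- unique(species_of[unique(c(
        cand,
        hits_all$subject_id[hits_all$query_id == cand &
                              hits_all$evalue <= config$homolog_max_evalue]
      ))])
      pres <- unique(stats::na.omit(inputs$superfamily_map[hom_sp]))
      if (length(pres) > 0) depth <- infer_transfer_depth(pres)
    }
    tibble::tibble(
      gene_id = cand, class = call$class, six_type = call$six_type,
      nesting_support = call$nesting_support, stage = call$stage,
      donor = don$donor, donor_rank = don$rank,
      donor_species = don$donor_species, transfer_depth = depth
    )
  })
  if (nrow(final_calls) > 0) {
    cand_coord <- ann |>
      dplyr::filter(.data$gene_id %in% survivors)
    seq_of <- setNames(all_seqs$residues, all_seqs$id)
    simfun <- function(a, b) {
      al <- local_align(seq_of[[a]], seq_of[[b]])
      if (nrow(al) == 0) 0 else al$identity_pct
    }
    grouped <- group_transfer_types(cand_coord, similarity_fn = simfun,
                                    max_gap_bp = config$max_gap_bp,
                                    min_identity = config$min_identity)
    final_calls <- dplyr::left_join(
      final_calls, grouped[, c("gene_id", "type_group")], by = "gene_id"
    )
  } else {
    final_calls$type_group <- character(0)
  }

  # -- statistics on survivors vs stage-1 background -----------------------
  stats_out <- list()
  background <- dplyr::filter(top_ident,
                              .data$gene_id %in% unique(hits1_pass$query_id))
  if (nrow(final_calls) > 0 && nrow(background) > 1) {
    per_type <- final_calls |>
      dplyr::left_join(top_ident, by = "gene_id") |>
      dplyr::group_by(.data$type_group) |>
      dplyr::summarise(identity = mean(.data$top_hit_identity_pct,
                                       na.rm = TRUE), .groups = "drop")
    k <- nrow(per_type)
    if (k >= 1 && k <= nrow(background)) {
      stats_out$enrichment <- similarity_enrichment_test(
        per_type$identity, background$top_hit_identity_pct, k = k,
        n_reps = 10000, seed = config$seed
      )
    }
    bg_ann <- dplyr::semi_join(ann, background, by = "gene_id")
    if ("intron_count" %in% names(bg_ann)) {
      stats_out$intron <- intron_free_test(
        n_background = nrow(bg_ann),
        n_intron_free = sum(bg_ann$intron_count == 0),
        k = k, n_reps = 10000, seed = config$seed
      )
    }
    if ("gc" %in% names(ann)) {
      per_type_gc <- final_calls |>
        dplyr::left_join(ann[, c("gene_id", "gc")], by = "gene_id") |>
        dplyr::group_by(.data$type_group) |>
        dplyr::summarise(gc = mean(.data$gc, na.rm = TRUE),
                         .groups = "drop")
      stats_out$gc <- gc_amelioration_summary(per_type_gc$gc,
                                              inputs$donor_gc)
    }
  }

  audit_tbl <- dplyr::bind_rows(audit)
  funnel_tbl <- purrr::map_dfr(funnel, function(x) {
    tibble::tibble(stage = x[["stage"]], n = as.integer(x[["n"]]))
  })
  finish_pipeline(recipient, audit_tbl, final_calls,
                  list(stats = stats_out, spectrum = spect,
                       triage = triage, topology = call_tbl),
                  config, funnel_tbl)
}

candidate_alignment <- function(cand, hom_ids, inputs, all_seqs) {
  if (!is.null(inputs$alignments) && cand %in% names(inputs$alignments)) {
    return(as_alignment_matrix(inputs$alignments[[cand]]))
  }
  seqs <- dplyr::filter(all_seqs, .data$id %in% hom_ids)
  if (nrow(seqs) < 2) return(NULL)
  if (length(unique(nchar(seqs$residues))) != 1) {
    abort(paste0(
      "Homologs of ", cand, " differ in length; supply a pre-aligned ",
      "block through inputs$alignments."
    ))
  }
  as_alignment_matrix(setNames(seqs$residues, seqs$id))
}

too_few_call <- function(cand) {
  out <- tibble::tibble(
    candidate_id = cand, class = "unresolved", six_type = NA_character_,
    nesting_support = NA_real_,
    sister_taxa = list(tibble::tibble(species = character(),
                                      group = character())),
    reason = "too_few_taxa", stage = "tree1"
  )
  class(out) <- c("topology_call", class(out))
  out
}

finish_pipeline <- function(recipient, audit_tbl, final_calls, extras,
                            config, funnel_tbl) {
  final_call <- rep("vertical", nrow(recipient))
  names(final_call) <- recipient$id
  if (nrow(audit_tbl) > 0) {
    cont <- audit_tbl$gene_id[audit_tbl$reason ==
                                "suspected genomic contamination"]
    final_call[cont] <- "contaminant"
    kept <- audit_tbl$gene_id[audit_tbl$decision == "retained"]
    final_call[kept] <- "hgt"
  }
  calls <- tibble::tibble(gene_id = recipient$id,
                          final_call = unname(final_call))
  if (is.data.frame(final_calls) && nrow(final_calls) > 0) {
    calls <- dplyr::left_join(calls, final_calls, by = "gene_id")
  }
  out <- c(list(calls = calls, audit = audit_tbl, funnel = funnel_tbl,
                config = config), extras)
  class(out) <- "hgt_pipeline_result"
  out
}

#' Validate a pipeline funnel report
#'
#' Asserts that per-stage surviving counts are monotone non-increasing and
#' that every removed candidate carries a removal reason (the audit trail
#' partitions the input).
#'
#' @param result An `hgt_pipeline_result` (or a list with `funnel`,
#'   `audit`, `calls`).
#' @return A list: `pass` (logical) and `problems` (character vector).
#' @export
funnel_check <- function(result) {
  problems <- character(0)
  fun <- result$funnel
  if (any(diff(fun$n) > 0)) {
    bad <- which(diff(fun$n) > 0)
    problems <- c(problems, paste0(
      "stage count increases at ", fun$stage[bad + 1], " (",
      fun$n[bad], " -> ", fun$n[bad + 1], ")"
    ))
  }
  audit <- result$audit
  removed <- audit[audit$decision == "removed", ]
  noreason <- removed$gene_id[is.na(removed$reason) |
                                !nzchar(removed$reason)]
  if (length(noreason) > 0) {
    problems <- c(problems, paste0(
      "candidates removed without reason: ",
      paste(noreason, collapse = ", ")
    ))
  }
  accounted <- unique(audit$gene_id)
  missing <- setdiff(result$calls$gene_id, accounted)
  if (nrow(audit) > 0 && length(missing) > 0) {
    problems <- c(problems, paste0(
      "input genes absent from the audit trail: ",
      paste(missing, collapse = ", ")
    ))
  }
  dup <- audit |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    problems <- c(problems, paste0(
      "genes with multiple audit entries: ",
      paste(dup$gene_id, collapse = ", ")
    ))
  }
  list(pass = length(problems) == 0, problems = problems)
}

#' @export
print.hgt_pipeline_result <- function(x, ...) {
  cat("HGT detection pipeline result\n")
  print(x$funnel)
  n_hgt <- sum(x$calls$final_call == "hgt")
  cat(sprintf("HGT calls: %d of %d input genes\n", n_hgt,
              nrow(x$calls)))
  invisible(x)
}
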