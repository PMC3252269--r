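#' Contamination triage from gene-level evidence
#'
#' A bacteria-like candidate is a suspected assembly contaminant when every
#' line of gene-level evidence is absent simultaneously: no EST, never
#' cloned, not anchored on a scaffold/chromosome with host neighbours, and
#' no homolog in a related genome. High identity to the top bacterial hit
#' (above `identity_alert`, default 60) is reported as a supporting flag
#' but is never decisive on its own. Unknown evidence fields are treated as
#' absent and flagged.
#'
#' @param evidence Tibble with one row per candidate: `gene_id`,
#'   `est_count`, `cloned`, `anchored`, `relative_genome_homolog`, and
#'   optionally `top_hit_identity_pct`.
#' @param identity_alert Identity level above which the supporting flag
#'   `high_identity` is raised.
#' @return The input plus `verdict` (`"genuine"` /
#'   `"suspected_contaminant"`) and a `flags` list-column.
#' @export
triage_contamination <- function(evidence, identity_alert = 60) {
  need <- c("gene_id", "est_count", "cloned", "anchored",
            "relative_genome_homolog")
  miss <- setdiff(need, names(evidence))
  if (length(miss) > 0) {
    abort(paste0("evidence lacks column(s): ", paste(miss, collapse = ", ")))
  }
  ev <- tibble::as_tibble(evidence)
  imputed <- c(
    if (anyNA(ev$est_count)) "est_count",
    if (anyNA(ev$cloned)) "cloned",
    if (anyNA(ev$anchored)) "anchored",
    if (anyNA(ev$relative_genome_homolog)) "relative_genome_homolog"
  )
  ev$est_count[is.na(ev$est_count)] <- 0L
  for (col in c("cloned", "anchored", "relative_genome_homolog")) {
    ev[[col]][is.na(ev[[col]])] <- FALSE
  }
  if (length(imputed) > 0) {
    warn(paste0("Unknown evidence treated as absent in: ",
                paste(imputed, collapse = ", ")))
  }
  no_evidence <- ev$est_count == 0 & !ev$cloned & !ev$anchored &
    !ev$relative_genome_homolog
  ident <- if ("top_hit_identity_pct" %in% names(ev)) {
    ev$top_hit_identity_pct
  } else {
    rep(NA_real_, nrow(ev))
  }
  ev$verdict <- ifelse(no_evidence, "suspected_contaminant", "genuine")
  ev$flags <- purrr::map2(no_evidence, ident, function(ne, id) {
    c(
      if (ne) "no_evidence",
      if (!is.na(id) && id > identity_alert) "high_identity"
    )
  })
  ev
}

#' Group candidate genes into transfer-event types
#'
#' Two candidates belong to the same type (descend from one transfer event,
#' possibly via post-transfer tandem duplication) iff they sit on the same
#' scaffold within `max_gap_bp`, or their pairwise identity reaches
#' `min_identity` and each is the other's reciprocal best match within the
#' candidate set (ties allowed). Types are the transitive closure of these
#' links.
#'
#' @param candidates Tibble with `gene_id` and optional `scaffold`,
#'   `start`, `end` columns.
#' @param similarity_fn Optional `function(gene_id_a, gene_id_b)` returning
#'   percent identity; when `NULL` only the coordinate rule applies.
#' @param max_gap_bp Maximum interval gap for same-scaffold linkage
#'   (default 50000).
#' @param min_identity Identity floor for homology linkage (default 40).
#' @return `candidates` plus a `type_group` column naming each group by its
#'   lexicographically first member.
#' @export
group_transfer_types <- function(candidates, similarity_fn = NULL,
                                 max_gap_bp = 50000, min_identity = 40) {
  cand <- tibble::as_tibble(candidates)
  n <- nrow(cand)
  if (n == 0) return(dplyr::mutate(cand, type_group = character(0)))
  ids <- cand$gene_id
  adj <- matrix(FALSE, n, n)
  has_coord <- all(c("scaffold", "start", "end") %in% names(cand))
  sim <- NULL
  if (!is.null(similarity_fn) && n > 1) {
    sim <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sim[i, j] <- sim[j, i] <- similarity_fn(ids[i], ids[j])
      }
    }
  }
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      linked <- FALSE
      if (has_coord && !is.na(cand$scaffold[i]) && !is.na(cand$scaffold[j]) &&
          cand$scaffold[i] == cand$scaffold[j]) {
        gap <- max(cand$start[i], cand$start[j]) -
          min(cand$end[i], cand$end[j])
        if (gap <= max_gap_bp) linked <- TRUE
      }
      if (!linked && !is.null(sim) && sim[i, j] >= min_identity) {
        # reciprocal best match within the candidate set, ties allowed
        best_i <- max(sim[i, -i])
        best_j <- max(sim[j, -j])
        if (sim[i, j] >= best_i && sim[i, j] >= best_j) linked <- TRUE
      }
      adj[i, j] <- adj[j, i] <- linked
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  rep_id <- vapply(split(ids, comp), function(m) sort(m)[1], character(1))
  cand$type_group <- unname(rep_id[as.character(comp)])
  cand
}

new_resampling_result <- function(observed, reps, n_extreme, seed,
                                  statistic, extra = list()) {
  out <- structure(
    c(list(
      observed_statistic = observed,
      null_mean = mean(reps),
      null_sd = stats::sd(reps) * sqrt((length(reps) - 1) / length(reps)),
      n_replicates = length(reps),
      n_extreme = n_extreme,
      empirical_p = n_extreme / length(reps),
      seed = seed,
      statistic = statistic,
      replicates = reps
    ), extra),
    class = "resampling_result"
  )
  out
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("Monte-Carlo resampling test (", x$statistic, ")\n", sep = "")
  cat(sprintf("  observed: %.4f\n", x$observed_statistic))
  cat(sprintf("  null mean: %.4f  null sd: %.4f  (%d replicates, seed %s)\n",
              x$null_mean, x$null_sd, x$n_replicates, format(x$seed)))
  cat(sprintf("  extreme replicates: %d  empirical p: %.4g\n",
              x$n_extreme, x$empirical_p))
  if (!is.null(x$exact_p)) cat(sprintf("  exact p: %.4g\n", x$exact_p))
  invisible(x)
}

#' Similarity-enrichment resampling test
#'
#' Tests whether the mean identity of the detected transfer-event types
#' exceeds what random draws from the screened background produce. Each
#' replicate draws `k` values without replacement from `background_values`
#' and records their mean; the empirical p-value is the fraction of
#' replicate means at or above the observed per-type mean.
#'
#' @param per_type_identities Per-type (already aggregated) identity
#'   values; the observed statistic is their mean.
#' @param background_values Background identity values (e.g. all screened
#'   genes' top-hit identities).
#' @param k Draw size per replicate (default `length(per_type_identities)`).
#' @param n_reps Number of replicates (default 10000).
#' @param seed Mandatory seed.
#' @return A `resampling_result` with `observed_statistic`, `null_mean`,
#'   `null_sd` (population form), `n_extreme`, `empirical_p`.
#' @export
similarity_enrichment_test <- function(per_type_identities,
                                       background_values,
                                       k = length(per_type_identities),
                                       n_reps = 10000, seed) {
  if (missing(seed)) abort("similarity_enrichment_test requires a seed.")
  if (k > length(background_values)) {
    abort("k exceeds the background size.")
  }
  observed <- mean(per_type_identities)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      mean(sample(background_values, k, replace = FALSE))
    }, numeric(1))
  })
  new_resampling_result(
    observed, reps, n_extreme = sum(reps >= observed), seed = seed,
    statistic = "mean identity of sampled types"
  )
}

#' Intron-free draw test
#'
#' Probability that `k` genes drawn without replacement from a background
#' of `n_background` genes (of which `n_intron_free` lack introns) are all
#' intron-free. Reports both the Monte-Carlo estimate and the exact
#' probability from the sequential product
#' \eqn{\prod_{i=0}^{k-1} (n_{if} - i) / (n_{bg} - i)} (evaluated in log
#' space).
#'
#' @param n_background Background gene count.
#' @param n_intron_free Intron-free genes in the background.
#' @param k Draw size.
#' @param n_reps Monte-Carlo replicates (default 10000).
#' @param seed Mandatory seed.
#' @return A `resampling_result` with `empirical_p`, `exact_p`,
#'   `n_extreme` (all-intron-free draws).
#' @export
intron_free_test <- function(n_background, n_intron_free, k,
                             n_reps = 10000, seed) {
  if (missing(seed)) abort("intron_free_test requires a seed.")
  if (n_intron_free < 0 || n_intron_free > n_background || k < 0 ||
      k > n_background) {
    abort("Invalid counts: need 0 <= n_intron_free <= n_background, k <= n_background.")
  }
  exact_p <- if (k == 0) 1 else if (k > n_intron_free) 0 else {
    exp(sum(log(n_intron_free - seq_len(k) + 1) -
              log(n_background - seq_len(k) + 1)))
  }
  pool <- c(rep(TRUE, n_intron_free), rep(FALSE, n_background - n_intron_free))
  successes <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      all(sample(pool, k, replace = FALSE))
    }, logical(1))
  })
  res <- new_resampling_result(
    observed = 1, reps = as.numeric(successes),
    n_extreme = sum(successes), seed = seed,
    statistic = "all-intron-free draw", extra = list(exact_p = exact_p)
  )
  res
}

#' GC-content amelioration summary
#'
#' Compares the GC spread of the transferred genes in the recipient genome
#' with that of their predicted donors. Anciently transferred genes drift
#' ("ameliorate") toward the recipient's base composition, so their GC
#' distribution is more centralized than the donors'. Standard deviations
#' use the population (divisor N) form.
#'
#' @param recipient_gc_by_type Per-type GC values of the transferred genes
#'   (fractions or percentages).
#' @param donor_gc GC values of the predicted donor sequences; may be
#'   empty, in which case no verdict is reported.
#' @return A one-row tibble: `recipient_mean`, `recipient_sd`,
#'   `donor_mean`, `donor_sd`, `centralized` (logical; `NA` without donor
#'   values).
#' @export
gc_amelioration_summary <- function(recipient_gc_by_type, donor_gc = NULL) {
  pop_sd <- function(x) {
    sqrt(mean((x - mean(x))^2))
  }
  has_donor <- !is.null(donor_gc) && length(donor_gc) > 0
  tibble::tibble(
    recipient_mean = mean(recipient_gc_by_type),
    recipient_sd = pop_sd(recipient_gc_by_type),
    donor_mean = if (has_donor) mean(donor_gc) else NA_real_,
    donor_sd = if (has_donor) pop_sd(donor_gc) else NA_real_,
    centralized = if (has_donor) {
      pop_sd(recipient_gc_by_type) < pop_sd(donor_gc)
    } else {
      NA
    }
  )
}

#' Composition fraction of a taxon in the prokaryote panel
#'
#' Percentage of the panel's species (or organisms) accounted for by one or
#' more taxa, rounded to one decimal as printed.
#'
#' @param panel The panel composition table ([load_fixture()]
#'   `"panel_composition"` or same shape).
#' @param taxon_query Taxon name(s); counts are summed over the query.
#' @param count `"species"` (default) or `"organisms"`.
#' @return A single percentage.
#' @export
#' @examples
#' composition_fractions(load_fixture("panel_composition"), "Proteobacteria")
composition_fractions <- function(panel, taxon_query,
                                  count = c("species", "organisms")) {
  count <- match.arg(count)
  rows <- panel[panel$taxon %in% taxon_query, ]
  missing <- setdiff(taxon_query, panel$taxon)
  if (length(missing) > 0) {
    abort(paste0("Unknown taxon/taxa in panel: ",
                 paste(missing, collapse = ", ")))
  }
  total <- panel[[count]][panel$level == "total"][1]
  if (is.na(total)) abort("Panel lacks a total row for this count.")
  round(100 * sum(rows[[count]], na.rm = TRUE) / total, 1)
}

#' EST-evidence counts for a candidate table
#'
#' Counts candidates with at least one EST. Cloned genes are established by
#' direct experiment rather than by transcript survey, so the reconciled
#' count excludes them; both the raw and the reconciled count are reported.
#'
#' @param candidates Tibble with `est_count` and `cloned` columns.
#' @return A one-row tibble: `raw` (any EST), `excluding_cloned`.
#' @export
est_evidence_counts <- function(candidates) {
  tibble::tibble(
    raw = sum(candidates$est_count > 0, na.rm = TRUE),
    excluding_cloned = sum(candidates$est_count > 0 & !candidates$cloned,
                           na.rm = TRUE)
  )
}

#' Per-type aggregation of a gene-level column
#'
#' Aggregates a per-gene value to transfer-event types by the within-type
#' mean; missing values are excluded from the mean (a type whose values are
#' all missing is dropped).
#'
#' @param candidates Tibble with `type_group` and the target column.
#' @param col Column name to aggregate (string).
#' @return Tibble `type_group`, `value`.
#' @export
aggregate_by_type <- function(candidates, col) {
  candidates |>
    dplyr::group_by(.data$type_group) |>
    dplyr::summarise(
      value = mean(.data[[col]][!is.na(.data[[col]])]),
      .groups = "drop"
    ) |>
    dplyr::filter(!is.nan(.data$value))
}
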