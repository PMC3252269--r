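# Annotation-based pairwise similarity for the fixture candidates: copies
# of one transfer event share the same product annotation (modulo the
# per-copy gene-name parenthetical).
fixture_similarity <- function(tbl) {
  fam <- setNames(sub(" \\(.*", "", tbl$annotation), tbl$gene_id)
  function(a, b) if (fam[[a]] == fam[[b]]) 100 else 0
}

test_that("no-evidence candidates are flagged as contamination; any evidence clears them", {
  ev <- tibble::tibble(
    gene_id = c("honeybee_like", "chitinase_like", "anchored_only"),
    est_count = c(0L, 25L, 0L),
    cloned = c(FALSE, TRUE, FALSE),
    anchored = c(FALSE, TRUE, TRUE),
    relative_genome_homolog = c(FALSE, TRUE, TRUE),
    top_hit_identity_pct = c(69.5, 72.9, 30)
  )
  out <- triage_contamination(ev)
  expect_equal(out$verdict,
               c("suspected_contaminant", "genuine", "genuine"))
  expect_true("high_identity" %in% out$flags[[1]])
  expect_false("high_identity" %in% out$flags[[3]])
  # high identity alone is never decisive
  solo <- triage_contamination(tibble::tibble(
    gene_id = "x", est_count = 10L, cloned = FALSE, anchored = FALSE,
    relative_genome_homolog = FALSE, top_hit_identity_pct = 96.1
  ))
  expect_equal(solo$verdict, "genuine")
  # unknown evidence treated as absent, with a warning
  expect_warning(
    na_out <- triage_contamination(tibble::tibble(
      gene_id = "y", est_count = NA_integer_, cloned = NA,
      anchored = NA, relative_genome_homolog = NA
    )),
    "absent"
  )
  expect_equal(na_out$verdict, "suspected_contaminant")
})

test_that("the candidate fixture groups into 14 transfer-event types over 22 genes", {
  t2 <- load_fixture("table2_candidates")
  grouped <- group_transfer_types(
    dplyr::select(t2, -"type_group"),
    similarity_fn = fixture_similarity(t2)
  )
  expect_equal(nrow(grouped), 22)
  expect_equal(dplyr::n_distinct(grouped$type_group), 14)
  # derived partition matches the curated one
  expect_equal(
    dplyr::n_distinct(paste(grouped$type_group, t2$type_group)), 14
  )
})

test_that("type grouping links tandem same-scaffold copies and isolates singletons", {
  cand <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    scaffold = c("scafA", "scafA", "scafB"),
    start = c(1000, 5000, 1000), end = c(2000, 6000, 2000)
  )
  out <- group_transfer_types(cand)
  expect_equal(out$type_group[1], out$type_group[2])
  expect_false(out$type_group[3] == out$type_group[1])
  single <- group_transfer_types(cand[3, ])
  expect_equal(single$type_group, "g3")
})

test_that("similarity enrichment reproduces closed-form null behaviour", {
  const <- rep(42, 100)
  res <- similarity_enrichment_test(c(42, 42), const, k = 5, n_reps = 200,
                                    seed = 1)
  expect_equal(res$null_sd, 0)
  expect_true(res$empirical_p %in% c(0, 1))
  expect_error(
    similarity_enrichment_test(1:3, 1:5, k = 10, seed = 1),
    "background"
  )
  # null SD of the mean under without-replacement sampling obeys the
  # finite-population-corrected closed form
  withr::with_seed(77, {
    bg <- rnorm(400, 50, 8)
  })
  res2 <- similarity_enrichment_test(rep(55, 14), bg, k = 14,
                                     n_reps = 4000, seed = 2)
  want <- fpc_mean_sd(bg, 14)
  mc_err <- want / sqrt(2 * 4000)
  expect_lt(abs(res2$null_sd - want), 4 * mc_err)
  # reproducibility
  res3 <- similarity_enrichment_test(rep(55, 14), bg, k = 14,
                                     n_reps = 4000, seed = 2)
  expect_identical(res2$empirical_p, res3$empirical_p)
})

test_that("intron-free test matches the hypergeometric oracle and converges", {
  r <- intron_free_test(1176, 116, 14, n_reps = 50, seed = 3)
  # exact product formula vs the hypergeometric density oracle
  expect_equal(r$exact_p, stats::dhyper(14, 116, 1060, 14),
               tolerance = 1e-12)
  expect_lt(r$exact_p, 1e-10)
  expect_equal(intron_free_test(10, 10, 3, n_reps = 10, seed = 1)$exact_p, 1)
  expect_equal(intron_free_test(10, 2, 5, n_reps = 10, seed = 1)$exact_p, 0)
  expect_error(intron_free_test(10, 11, 3, n_reps = 10, seed = 1),
               "Invalid")
  # Monte-Carlo estimate within 3 MC standard errors of the exact value
  r2 <- intron_free_test(40, 30, 3, n_reps = 4000, seed = 5)
  se <- sqrt(r2$exact_p * (1 - r2$exact_p) / 4000)
  expect_lt(abs(r2$empirical_p - r2$exact_p), 3 * se)
})

test_that("GC summary reports population SDs and the centralization verdict", {
  out <- gc_amelioration_summary(c(40, 44, 48), c(30, 50, 70))
  expect_equal(out$recipient_mean, 44)
  expect_equal(out$recipient_sd, sqrt(mean((c(40, 44, 48) - 44)^2)))
  expect_true(out$centralized)
  expect_equal(gc_amelioration_summary(c(44, 44))$recipient_sd, 0)
  expect_true(is.na(gc_amelioration_summary(c(40, 44))$centralized))
  rev_out <- gc_amelioration_summary(c(30, 50, 70), c(48, 49, 50))
  expect_false(rev_out$centralized)
})

test_that("panel composition fractions divide by the right totals", {
  panel <- load_fixture("panel_composition")
  expect_equal(composition_fractions(panel, "Proteobacteria"), 46.3)
  expect_equal(composition_fractions(panel, "Proteobacteria", "organisms"),
               48.9)
  expect_equal(composition_fractions(panel, "Gammaproteobacteria"), 18.4)
  expect_error(composition_fractions(panel, "Cyanobacteria"), "Unknown")
  zero <- dplyr::add_row(panel, level = "genus", taxon = "Xenorhabdus",
                         organisms = NA, species = 0L)
  expect_equal(composition_fractions(zero, "Xenorhabdus"), 0)
})

test_that("EST evidence counts reconcile raw and cloned-excluded tallies", {
  t2 <- load_fixture("table2_candidates")
  counts <- est_evidence_counts(t2)
  expect_equal(counts$raw, 13)
  expect_equal(counts$excluding_cloned, 10)
})

test_that("per-type aggregation skips missing values", {
  t2 <- load_fixture("table2_candidates")
  per_type <- aggregate_by_type(t2, "top_hit_identity_pct")
  expect_equal(nrow(per_type), 14)
  g1p <- per_type$value[per_type$type_group == "BGIBMGA011199"]
  expect_equal(round(g1p, 2), 40.36)  # mean of the five printed values
})
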