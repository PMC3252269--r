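# Karlin-Altschul parameters for ungapped BLOSUM62 statistics. Desk-scale
# E-values computed from gapped optimal scores with these constants are
# calibration-approximate; every filter in the package depends only on its
# threshold, not on absolute E-value calibration.
KA_LAMBDA <- 0.3176
KA_K <- 0.134

#' Load a protein scoring matrix
#'
#' Accepts either the name of a matrix shipped with Biostrings
#' (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or the path to a standard
#' NCBI-format matrix text file.
#'
#' @param matrix Matrix name or file path.
#' @return A numeric substitution matrix with residue row/column names.
#' @export
load_scoring_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  shipped <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
               "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (matrix %in% shipped) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    return(get(matrix, envir = e))
  }
  if (!file.exists(matrix)) {
    abort(paste0("Unknown scoring matrix (not shipped, not a file): ", matrix))
  }
  tab <- utils::read.table(matrix, comment.char = "#", check.names = FALSE)
  m <- as.matrix(tab)
  rownames(m) <- colnames(m)
  storage.mode(m) <- "numeric"
  m
}

#' Exact local (Smith-Waterman) alignment of two protein sequences
#'
#' Computes the maximal-scoring local alignment under an affine gap model.
#' Identity is counted over all alignment columns including gap columns (the
#' convention of tabular BLAST output); `identity_denominator = "matched"`
#' switches to aligned residue pairs only. Overlap is the aligned span as a
#' percentage of the query length by default (`overlap_anchor = "subject"`
#' for subject-anchored screening).
#'
#' @param query,subject Amino-acid strings, or one-row data frames with an
#'   `id` and `residues` column (as produced by [read_fasta()]).
#' @param matrix Substitution matrix name/path/matrix (default BLOSUM62);
#'   unknown residues score through the matrix's `X` row.
#' @param gap_open,gap_extend Affine gap penalties (positive; the first gap
#'   position costs `gap_open + gap_extend`).
#' @param overlap_anchor `"query"` or `"subject"`.
#' @param identity_denominator `"columns"` (gap columns included) or
#'   `"matched"`.
#' @return A one-row tibble with `query_id`, `subject_id`, `raw_score`,
#'   `identity_pct`, `overlap_pct`, `aligned_length`, `n_identical`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`; or a
#'   zero-row tibble when no alignment scores above 0.
#' @export
#' @examples
#' local_align("MKVLITGA", "MKVLITGA")$identity_pct
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1,
                        overlap_anchor = c("query", "subject"),
                        identity_denominator = c("columns", "matched")) {
  overlap_anchor <- match.arg(overlap_anchor)
  identity_denominator <- match.arg(identity_denominator)
  q <- as_seq_entry(query, "query")
  s <- as_seq_entry(subject, "subject")
  subs <- load_scoring_matrix(matrix)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q$residues),
    subject = Biostrings::AAString(s$residues),
    type = "local", substitutionMatrix = subs,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- Biostrings::score(al)
  if (sc <= 0) return(empty_alignment_row())
  pat <- Biostrings::alignedPattern(al)
  cols <- Biostrings::nchar(pat)
  nid <- Biostrings::nmatch(al)
  denom <- if (identity_denominator == "columns") cols else {
    nid + Biostrings::nmismatch(al)
  }
  qspan <- c(
    Biostrings::start(Biostrings::pattern(al)),
    Biostrings::end(Biostrings::pattern(al))
  )
  sspan <- c(
    Biostrings::start(Biostrings::subject(al)),
    Biostrings::end(Biostrings::subject(al))
  )
  anchor_len <- if (overlap_anchor == "query") nchar(q$residues) else {
    nchar(s$residues)
  }
  span_len <- if (overlap_anchor == "query") {
    qspan[2] - qspan[1] + 1
  } else {
    sspan[2] - sspan[1] + 1
  }
  tibble::tibble(
    query_id = q$id, subject_id = s$id,
    raw_score = as.numeric(sc),
    identity_pct = 100 * nid / denom,
    overlap_pct = 100 * span_len / anchor_len,
    aligned_length = as.integer(cols),
    n_identical = as.integer(nid),
    query_start = qspan[1], query_end = qspan[2],
    subject_start = sspan[1], subject_end = sspan[2]
  )
}

as_seq_entry <- function(x, role) {
  if (is.character(x) && length(x) == 1) {
    x <- list(id = role, residues = x)
  } else if (is.data.frame(x) && nrow(x) == 1) {
    x <- list(id = x$id, residues = x$residues)
  } else if (!is.list(x) || is.null(x$residues)) {
    abort(paste0(role, " must be a string or a one-row sequence record"))
  }
  if (is.na(x$residues) || nchar(x$residues) == 0) {
    abort(paste0("Zero-length ", role, " sequence."))
  }
  x$residues <- clean_residues(x$residues)
  x
}

empty_alignment_row <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), raw_score = numeric(),
    identity_pct = numeric(), overlap_pct = numeric(),
    aligned_length = integer(), n_identical = integer(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), subject_end = integer()
  )
}

#' Karlin-Altschul E-value and bit score from a raw alignment score
#'
#' Uses the classical form `E = K * m * n * exp(-lambda * S)` and
#' `bits = (lambda * S - ln K) / ln 2` with ungapped BLOSUM62 constants by
#' default.
#'
#' @param raw_score Raw alignment score(s).
#' @param query_len Query length in residues.
#' @param db_residues Total residues in the searched database.
#' @param lambda,K Karlin-Altschul parameters for the scoring system.
#' @return A tibble with columns `evalue` and `bit_score`.
#' @export
estimate_evalue <- function(raw_score, query_len, db_residues,
                            lambda = KA_LAMBDA, K = KA_K) {
  if (any(query_len <= 0) || any(db_residues <= 0)) {
    abort("query_len and db_residues must be positive.")
  }
  tibble::tibble(
    evalue = K * query_len * db_residues * exp(-lambda * raw_score),
    bit_score = (lambda * raw_score - log(K)) / log(2)
  )
}

#' Threshold configuration for the similarity-filter stages
#'
#' Stage `blast1` is the insect-versus-prokaryote screen (E \eqn{\le}
#' 1e-40, overlap \eqn{\ge} 25\%, identity \eqn{\ge} 25\%); stage `blast3`
#' is the broad-database confirmation (E \eqn{\le} 1e-3, same overlap and
#' identity floors) where a hit failing the identity floor can be rescued by
#' a shared protein domain.
#'
#' @param stage `"blast1"` or `"blast3"`.
#' @param max_evalue,min_overlap_pct,min_identity_pct Override the stage
#'   defaults.
#' @param domain_rescue Whether shared-domain rescue applies (default only
#'   at `blast3`).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(stage = c("blast1", "blast3"),
                             max_evalue = NULL, min_overlap_pct = 25,
                             min_identity_pct = 25, domain_rescue = NULL) {
  stage <- match.arg(stage)
  if (is.null(max_evalue)) {
    max_evalue <- if (stage == "blast1") 1e-40 else 1e-3
  }
  if (is.null(domain_rescue)) domain_rescue <- stage == "blast3"
  stopifnot(max_evalue > 0,
            min_overlap_pct >= 0, min_overlap_pct <= 100,
            min_identity_pct >= 0, min_identity_pct <= 100)
  structure(
    list(stage = stage, max_evalue = max_evalue,
         min_overlap_pct = min_overlap_pct,
         min_identity_pct = min_identity_pct,
         domain_rescue = isTRUE(domain_rescue)),
    class = "threshold_config"
  )
}

#' Filter a hit table by stage thresholds
#'
#' A hit survives iff its E-value and overlap meet the stage thresholds and
#' either its identity meets the identity floor or (at `blast3`, with
#' `domain_rescue`) query and subject share at least one annotated protein
#' domain. Row order is preserved; output is always a subset of input, so
#' the filter is idempotent.
#'
#' @param hits Hit tibble with columns `evalue`, `identity_pct` and either
#'   `overlap_pct` or enough span information plus `query_lengths` to derive
#'   it.
#' @param thresholds A [threshold_config()].
#' @param domain_annotations Optional named list mapping sequence id to a
#'   character vector of domain identifiers.
#' @param query_lengths Optional named vector of query sequence lengths,
#'   used to derive `overlap_pct` from query spans when the column is
#'   absent.
#' @return The surviving rows of `hits`.
#' @export
apply_hit_filter <- function(hits, thresholds,
                             domain_annotations = NULL,
                             query_lengths = NULL) {
  stopifnot(inherits(thresholds, "threshold_config"))
  if (nrow(hits) == 0) return(hits)
  if (!("overlap_pct" %in% names(hits))) {
    if (is.null(query_lengths)) {
      abort("hits lack overlap_pct; supply query_lengths to derive it.")
    }
    hits$overlap_pct <- 100 *
      (hits$query_end - hits$query_start + 1) /
      unname(query_lengths[hits$query_id])
  }
  base_ok <- hits$evalue <= thresholds$max_evalue &
    hits$overlap_pct >= thresholds$min_overlap_pct
  ident_ok <- hits$identity_pct >= thresholds$min_identity_pct
  rescued <- rep(FALSE, nrow(hits))
  if (thresholds$stage == "blast3" && thresholds$domain_rescue &&
      !is.null(domain_annotations)) {
    rescued <- purrr::map2_lgl(hits$query_id, hits$subject_id, function(q, s) {
      dq <- domain_annotations[[q]]
      ds <- domain_annotations[[s]]
      length(dq) > 0 && length(ds) > 0 && length(intersect(dq, ds)) > 0
    })
  }
  hits[base_ok & (ident_ok | rescued), , drop = FALSE]
}

#' All-against-all local alignment search
#'
#' Aligns every query against every subject with [local_align()]'s scoring
#' (vectorised over subjects through Biostrings), attaches Karlin-Altschul
#' E-values and bit scores, and returns hits in the tabular hit format plus
#' `raw_score` and `overlap_pct`.
#'
#' @param queries,subjects Sequence tibbles (`id`, `residues`, optionally
#'   `species`/`group`).
#' @param matrix,gap_open,gap_extend Scoring parameters as in
#'   [local_align()].
#' @param max_evalue Hits above this E-value are not reported (default 10).
#' @param db_residues Database size used for E-values; defaults to the total
#'   residue count of `subjects`.
#' @param overlap_anchor `"query"` or `"subject"`.
#' @return A hit tibble; one row per query/subject pair scoring above 0 and
#'   below `max_evalue`.
#' @export
search_hits <- function(queries, subjects, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1, max_evalue = 10,
                        db_residues = NULL,
                        overlap_anchor = c("query", "subject")) {
  overlap_anchor <- match.arg(overlap_anchor)
  subs_mat <- load_scoring_matrix(matrix)
  if (is.null(db_residues)) db_residues <- sum(nchar(subjects$residues))
  subj_set <- Biostrings::AAStringSet(
    setNames(clean_residues(subjects$residues), subjects$id)
  )
  res <- purrr::map(seq_len(nrow(queries)), function(i) {
    qres <- clean_residues(queries$residues[i])
    al <- Biostrings::pairwiseAlignment(
      pattern = subj_set, subject = Biostrings::AAString(qres),
      type = "local", substitutionMatrix = subs_mat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    sc <- Biostrings::score(al)
    keep <- which(sc > 0)
    if (length(keep) == 0) return(NULL)
    cols <- Biostrings::nchar(al)[keep]
    nid <- Biostrings::nmatch(al)[keep]
    nmis <- Biostrings::nmismatch(al)[keep]
    ins <- Biostrings::indel(al)
    n_gap_open <- lengths(Biostrings::insertion(ins))[keep] +
      lengths(Biostrings::deletion(ins))[keep]
    # pattern side = subject sequences, subject side = the query
    s_start <- Biostrings::start(Biostrings::pattern(al))[keep]
    s_end <- Biostrings::end(Biostrings::pattern(al))[keep]
    q_start <- Biostrings::start(Biostrings::subject(al))[keep]
    q_end <- Biostrings::end(Biostrings::subject(al))[keep]
    qlen <- nchar(qres)
    slen <- nchar(subjects$residues)[keep]
    span <- if (overlap_anchor == "query") {
      100 * (q_end - q_start + 1) / qlen
    } else {
      100 * (s_end - s_start + 1) / slen
    }
    ka <- estimate_evalue(sc[keep], qlen, db_residues)
    tibble::tibble(
      query_id = queries$id[i], subject_id = subjects$id[keep],
      identity_pct = 100 * nid / cols,
      aligned_length = as.integer(cols),
      mismatches = as.integer(nmis),
      gap_opens = as.integer(n_gap_open),
      query_start = q_start, query_end = q_end,
      subject_start = s_start, subject_end = s_end,
      evalue = ka$evalue, bit_score = ka$bit_score,
      raw_score = as.numeric(sc[keep]),
      overlap_pct = span
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- dplyr::mutate(empty_hit_table(),
                         raw_score = numeric(), overlap_pct = numeric())
  }
  dplyr::filter(out, .data$evalue <= max_evalue)
}
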