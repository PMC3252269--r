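#' Read a protein FASTA file into a sequence tibble
#'
#' Every FASTA identifier must be resolvable to a species and taxonomic group
#' through `species_map`; records are returned in file order with residues
#' upper-cased and any non-canonical letter mapped to `X`.
#'
#' @param path Path to a protein FASTA file.
#' @param species_map A data frame with columns `id`, `species`, `group`
#'   (see [read_species_map()]). Group labels must come from the closed set
#'   `recipient_insect`, `other_insect`, `non_insect_arthropod`,
#'   `non_arthropod_metazoan`, `plant`, `fungus`, `protist`, `eubacterium`,
#'   `archaebacterium`.
#' @return A tibble with columns `id`, `species`, `group`, `residues`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "MKVLaa", ">g2", "MPWT"), fa)
#' sm <- tibble::tibble(id = c("g1", "g2"),
#'                      species = c("Bombyx mori", "Serratia sp."),
#'                      group = c("recipient_insect", "eubacterium"))
#' read_fasta(fa, sm)
read_fasta <- function(path, species_map) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  species_map <- as_species_map(species_map)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    return(tibble::tibble(
      id = character(), species = character(),
      group = character(), residues = character()
    ))
  }
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate sequence id(s) in FASTA: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  missing <- setdiff(ids, species_map$id)
  if (length(missing) > 0) {
    abort(paste0(
      "No species mapping for sequence id(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  res <- clean_residues(as.character(aa))
  tibble::tibble(id = ids, residues = unname(res)) |>
    dplyr::left_join(species_map, by = "id") |>
    dplyr::select("id", "species", "group", "residues")
}

#' Normalise amino-acid strings: upper-case, non-canonical letters to X
#' @noRd
clean_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", x)
  if (any(nchar(x) == 0)) abort("Zero-length sequence in input.")
  x
}

#' Write a sequence tibble to FASTA
#'
#' @param sequences Tibble with columns `id`, `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(setNames(sequences$residues, sequences$id))
  Biostrings::writeXStringSet(aa, path, width = 70)
  invisible(path)
}

#' Read a species map TSV (columns id, species, group)
#'
#' @param path Path to a tab-separated file with columns `id`, `species`,
#'   `group`.
#' @return A tibble with those three columns.
#' @export
read_species_map <- function(path) {
  sm <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  as_species_map(sm)
}

as_species_map <- function(sm) {
  need <- c("id", "species", "group")
  if (!all(need %in% names(sm))) {
    abort("species_map needs columns id, species, group")
  }
  check_groups(sm$group)
  tibble::as_tibble(sm)[, need]
}

#' Write a species map TSV
#' @param species_map Tibble with columns `id`, `species`, `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(species_map, path) {
  readr::write_tsv(as_species_map(species_map), path)
  invisible(path)
}

HIT_COLS <- c(
  "query_id", "subject_id", "identity_pct", "aligned_length", "mismatches",
  "gap_opens", "query_start", "query_end", "subject_start", "subject_end",
  "evalue", "bit_score"
)

#' Read a tabular homology hit table (12-column BLAST-like dialect)
#'
#' Parses the standard 12-column tab-separated hit format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Extra trailing columns are ignored with a warning;
#' short rows are an error reported with their line number.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @return A tibble with typed columns `query_id`, `subject_id`,
#'   `identity_pct`, `aligned_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `evalue`,
#'   `bit_score`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Hit table not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hit_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 12)) {
    bad <- which(nfield < 12)[1]
    abort(paste0(
      "Malformed hit-table row at line ", bad, ": expected 12 tab-separated ",
      "columns, found ", nfield[bad]
    ))
  }
  if (any(nfield > 12)) {
    warn("Hit table has more than 12 columns; extra columns ignored.")
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- tibble::tibble(
    query_id = mat[, 1],
    subject_id = mat[, 2],
    identity_pct = as.numeric(mat[, 3]),
    aligned_length = as.integer(mat[, 4]),
    mismatches = as.integer(mat[, 5]),
    gap_opens = as.integer(mat[, 6]),
    query_start = as.integer(mat[, 7]),
    query_end = as.integer(mat[, 8]),
    subject_start = as.integer(mat[, 9]),
    subject_end = as.integer(mat[, 10]),
    evalue = as.numeric(mat[, 11]),
    bit_score = as.numeric(mat[, 12])
  )
  num_bad <- !stats::complete.cases(
    out[, c("identity_pct", "aligned_length", "evalue", "bit_score")]
  )
  if (any(num_bad)) {
    abort(paste0(
      "Malformed numeric field in hit table at line ", which(num_bad)[1]
    ))
  }
  if (any(out$identity_pct < 0 | out$identity_pct > 100)) {
    abort("identity_pct outside [0, 100] in hit table.")
  }
  out
}

empty_hit_table <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    identity_pct = numeric(), aligned_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), subject_end = integer(),
    evalue = numeric(), bit_score = numeric()
  )
}

#' Write a hit tibble in the 12-column tabular dialect
#' @param hits Hit tibble as returned by [read_hit_table()] or
#'   [search_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[, HIT_COLS], path, col_names = FALSE)
  invisible(path)
}

#' Load a packaged study-table fixture
#'
#' The package ships the printed tables of the silkworm HTG study as plain
#' TSV fixtures so the downstream statistics can be replayed without any
#' external download:
#'
#' * `table2_candidates` — the 22 predicted prokaryote-origin silkworm HTGs
#'   with annotation, GC content, intron and EST counts, cloning status,
#'   probe, scaffold coordinates, and per-gene top bacterial hit
#'   (score / E-value / identity; missing for the truncated
#'   glucose-1-phosphatase copy BGIBMGA011200), plus their grouping into
#'   14 transfer-event types.
#' * `table3_donors` — predicted prokaryotic donors (14 rows; type-level
#'   rows expanded per gene where the printed table gives per-gene values).
#' * `panel_composition` — organism/species composition of the 994-genome
#'   (680-species) prokaryote search panel, by domain, phylum, class and
#'   entomopathogenic genus.
#' * `species_set_sizes` — sizes of the six eukaryote species sets used by
#'   the distribution-spectrum filter.
#' * `table1_funnel` — per-proteome sequence counts surviving each pipeline
#'   stage for the five screened insect proteomes.
#'
#' @param name One of `"table2_candidates"`, `"table3_donors"`,
#'   `"panel_composition"`, `"species_set_sizes"`, `"table1_funnel"`.
#' @return A tibble.
#' @export
#' @examples
#' load_fixture("species_set_sizes")
load_fixture <- function(name) {
  known <- c(
    "table2_candidates", "table3_donors", "panel_composition",
    "species_set_sizes", "table1_funnel"
  )
  if (!is.character(name) || length(name) != 1 || !(name %in% known)) {
    abort(paste0(
      "Unknown fixture name. Use one of: ", paste(known, collapse = ", ")
    ))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "hgtsieve",
                      mustWork = TRUE)
  spec <- switch(
    name,
    table2_candidates = readr::cols(
      gene_id = "c", type_group = "c", annotation = "c",
      protein_length = "i", length_partial = "l", gc = "d",
      intron_count = "i", est_count = "i", cloned = "l", probe_id = "c",
      chromosome = "c", scaffold = "c", start = "d", end = "d", strand = "c",
      top_hit_species = "c", top_hit_score = "d", top_hit_evalue = "d",
      top_hit_identity_pct = "d"
    ),
    table3_donors = readr::cols(.default = "c"),
    panel_composition = readr::cols(
      level = "c", taxon = "c", organisms = "i", species = "i"
    ),
    species_set_sizes = readr::cols(set = "c", n_species = "i"),
    table1_funnel = readr::cols(species = "c", stage = "c", count = "i")
  )
  readr::read_tsv(path, col_types = spec)
}

#' Parse a Newick string (or file) into an `ape` phylo tree
#'
#' Internal node labels are interpreted as bootstrap-style support values
#' when numeric.
#'
#' @param tree_text A Newick string, or a path to a file containing one.
#' @return An object of class `phylo`. Numeric internal labels are kept in
#'   `$node.label`.
#' @export
read_gene_tree <- function(tree_text) {
  txt <- tree_text
  if (length(txt) == 1 && !grepl(";", txt, fixed = TRUE) &&
      file.exists(txt)) {
    txt <- paste(readLines(txt), collapse = "")
  }
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tr)) abort("Failed to parse Newick tree text.")
  tr
}

#' Serialise a phylo tree to Newick, preserving support labels
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_gene_tree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
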