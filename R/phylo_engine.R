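# Distance assigned to saturated pairs (p >= .85 under the Kimura
# correction), in substitutions per site.
SATURATION_CAP <- 10

#' Coerce aligned sequences to a character matrix (taxa x columns)
#' @noRd
as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- alignment
  } else if (inherits(alignment, "AAStringSet")) {
    m <- do.call(rbind, strsplit(as.character(alignment), ""))
    rownames(m) <- names(alignment)
  } else if (is.character(alignment)) {
    if (length(unique(nchar(alignment))) != 1) {
      abort("Aligned sequences must all have the same length.")
    }
    m <- do.call(rbind, strsplit(alignment, ""))
    rownames(m) <- names(alignment)
  } else if (is.data.frame(alignment) &&
             all(c("id", "residues") %in% names(alignment))) {
    m <- as_alignment_matrix(setNames(alignment$residues, alignment$id))
  } else {
    abort("Unsupported alignment representation.")
  }
  if (is.null(rownames(m))) abort("Alignment rows must be named by taxon id.")
  toupper(m)
}

#' Pairwise distance matrix from an aligned protein block
#'
#' Computes p-distances with pairwise deletion of gap columns and, under
#' `model = "kimura"`, applies Kimura's correction for multiple hits,
#' `d = -ln(1 - p - 0.2 p^2)`. Saturated pairs (p \eqn{\ge} 0.85) receive
#' the documented cap of 10 substitutions/site.
#'
#' @param alignment Equal-length aligned sequences: a character matrix, a
#'   named character vector, an `AAStringSet`, or a tibble with `id` and
#'   `residues`.
#' @param model `"kimura"` (default) or `"p"`.
#' @param cap Distance assigned to saturated pairs.
#' @return A symmetric numeric matrix with zero diagonal, taxon ids as
#'   dimnames, and attributes `model` and `cap`.
#' @export
protein_distance_matrix <- function(alignment, model = c("kimura", "p"),
                                    cap = SATURATION_CAP) {
  model <- match.arg(model)
  m <- as_alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2) abort("Need at least two sequences for a distance matrix.")
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0) {
        abort(paste0(
          "No comparable columns between ", rownames(m)[i], " and ",
          rownames(m)[j]
        ))
      }
      p <- sum(m[i, ok] != m[j, ok]) / nc
      val <- if (model == "p") {
        p
      } else if (p >= 0.85) {
        cap
      } else {
        -log(1 - p - 0.2 * p^2)
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  attr(d, "model") <- model
  attr(d, "cap") <- cap
  d
}

#' BIONJ tree from a distance matrix
#'
#' Variance-weighted neighbour joining (BIONJ) agglomeration; negative
#' branch-length estimates are clamped to zero. Three taxa are resolved by
#' the closed-form three-point formulas.
#'
#' @param d Symmetric distance matrix (or `dist`) with taxon ids.
#' @return An unrooted `phylo` tree.
#' @export
bionj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n) || n < 3) abort("BIONJ needs at least 3 taxa.")
  if (any(abs(d - t(d)) > 1e-8)) abort("Distance matrix must be symmetric.")
  ids <- rownames(d)
  if (n == 3) {
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    c_ <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    txt <- sprintf("(%s:%g,%s:%g,%s:%g);",
                   ids[1], max(a, 0), ids[2], max(b, 0), ids[3], max(c_, 0))
    return(ape::read.tree(text = txt))
  }
  tr <- ape::bionj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a distance-tree point estimate
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `tree_builder`, and scores each internal bipartition of
#' the point-estimate tree by the percentage of replicate trees containing
#' it. Supports are stored in `$node.label` (the root/base node carries
#' `NA`).
#'
#' @param alignment Aligned sequences (any form accepted by
#'   [protein_distance_matrix()]).
#' @param tree_builder Function alignment-matrix -> `phylo`; defaults to
#'   Kimura distances + BIONJ.
#' @param n_replicates Number of bootstrap replicates (\eqn{\ge} 1).
#' @param seed Mandatory integer seed; supports are bit-identical across
#'   runs with the same seed.
#' @param model Distance model for the default builder.
#' @return The point-estimate `phylo` with percentage supports in
#'   `$node.label`.
#' @export
bootstrap_support <- function(alignment, tree_builder = NULL,
                              n_replicates = 1000, seed,
                              model = "kimura") {
  if (missing(seed)) abort("bootstrap_support requires an explicit seed.")
  stopifnot(n_replicates >= 1)
  m <- as_alignment_matrix(alignment)
  if (ncol(m) < 2) abort("Alignment must have at least 2 columns.")
  if (is.null(tree_builder)) {
    tree_builder <- function(a) bionj_tree(protein_distance_matrix(a, model))
  }
  point <- tree_builder(m)
  reps <- withr::with_seed(seed, {
    purrr::map(seq_len(n_replicates), function(i) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tree_builder(m[, cols, drop = FALSE])
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_replicates
  support[1] <- NA_real_  # the basal (trivial) partition
  point$node.label <- support
  point
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the midpoint of the longest leaf-to-leaf path.
#' A tree whose branch lengths are all zero cannot be midpoint-rooted; it is
#' returned rooted at its designated base with a warning.
#'
#' @param tree An unrooted `phylo` with branch lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    warn("All branch lengths are zero; rooting at the designated base.")
    return(phangorn::midpoint(ape::compute.brlen(tree, 1)))
  }
  phangorn::midpoint(tree)
}

#' Read a PHYLIP-style square distance matrix
#' @param path File with the taxon count on the first line, then one row
#'   per taxon: id followed by its distances.
#' @return A symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  ids <- vapply(rows, `[`, character(1), 1)
  d <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(d) <- list(ids, ids)
  d
}

#' Write a PHYLIP-style square distance matrix
#' @param d Symmetric matrix with taxon dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], format(d[i, ], digits = 8)),
                     collapse = "  "), con)
  }
  invisible(path)
}
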