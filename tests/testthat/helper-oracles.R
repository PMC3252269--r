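# Independent oracles used by the tests. These are deliberately naive,
# exhaustive implementations kept separate from the package's code paths.

# Full Gotoh dynamic-programming local alignment (affine gaps): returns the
# maximal local score. Convention: the first residue of a gap costs
# gap_open + gap_extend, each further residue gap_extend.
sw_oracle_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      s <- H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]]
      H[i, j] <- max(0, s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Least-squares brute force over all unrooted topologies (4 or 5 taxa):
# returns the minimum-SSQ topology as a phylo.
ls_topology_oracle <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  stopifnot(n %in% c(4, 5))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
  ssq <- vapply(trees, function(tr) {
    tr <- ape::unroot(tr)
    ne <- nrow(tr$edge)
    pairs <- t(combn(seq_len(n), 2))
    X <- matrix(0, nrow(pairs), ne)
    for (r in seq_len(nrow(pairs))) {
      pth <- ape::nodepath(tr, pairs[r, 1], pairs[r, 2])
      for (k in seq_len(length(pth) - 1)) {
        e <- which((tr$edge[, 1] == pth[k] & tr$edge[, 2] == pth[k + 1]) |
                     (tr$edge[, 2] == pth[k] & tr$edge[, 1] == pth[k + 1]))
        X[r, e] <- 1
      }
    }
    y <- d[pairs]
    fit <- qr.solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% fit)^2)
  }, numeric(1))
  ape::unroot(trees[[which.min(ssq)]])
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Random additive (tree-generated) distance matrix on n taxa.
random_additive_matrix <- function(n, min_edge = 0.05) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, min_edge, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = ape::unroot(tr), d = ape::cophenetic.phylo(tr))
}

# SD of the mean of k draws without replacement from a finite population,
# from the population SD (divisor N) and the finite-population correction.
fpc_mean_sd <- function(values, k) {
  N <- length(values)
  sigma2 <- mean((values - mean(values))^2)
  sqrt(sigma2 / k * (N - k) / (N - 1))
}

# Tiny deterministic alignment fixture builders.
toy_taxa <- function() {
  tibble::tibble(
    id = c("focal", "lep2", "bacA", "bacB", "euk1", "euk2", "ins1"),
    species = c("Bombyx mori", "Manduca sexta", "Serratia sp.",
                "Bacillus sp.", "Homo sapiens", "Saccharomyces sp.",
                "Drosophila melanogaster"),
    group = c("recipient_insect", "recipient_insect", "eubacterium",
              "eubacterium", "non_arthropod_metazoan", "fungus",
              "other_insect")
  )
}
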