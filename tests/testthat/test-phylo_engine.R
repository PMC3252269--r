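test_that("protein distances: identity, Kimura correction, saturation cap, pairwise deletion", {
  aln <- c(a = "MKVLITGAGG", b = "MKVLITGAGG")
  d <- protein_distance_matrix(aln)
  expect_equal(d["a", "b"], 0)
  # p = 0.5 -> -ln(1 - 0.5 - 0.2*0.25) = -ln(0.45)
  aln2 <- c(a = "AAAAAAAAAA", b = "AAAAACCCCC")
  expect_equal(protein_distance_matrix(aln2)["a", "b"], -log(0.45))
  expect_equal(protein_distance_matrix(aln2, model = "p")["a", "b"], 0.5)
  # p = 0.9 -> cap
  aln3 <- c(a = "AAAAAAAAAA", b = "ACCCCCCCCC")
  expect_equal(protein_distance_matrix(aln3)["a", "b"], 10)
  # gap columns are deleted pairwise
  aln4 <- c(a = "MK-LI", b = "MKVLI", c = "MKWLI")
  d4 <- protein_distance_matrix(aln4, model = "p")
  expect_equal(d4["a", "c"], 0)
  expect_equal(d4["b", "c"], 0.2)
  # a pair with no comparable columns errors with the pair named
  aln5 <- c(a = "MK---", b = "--VLI", c = "MKVLI")
  expect_error(protein_distance_matrix(aln5), "a and b")
})

test_that("Kimura distance dominates p and is monotone below saturation", {
  p <- seq(0.01, 0.84, by = 0.01)
  k <- -log(1 - p - 0.2 * p^2)
  expect_true(all(k >= p))
  expect_true(all(diff(k) > 0))
})

test_that("BIONJ recovers generating topology of additive matrices (4 and 5 taxa)", {
  withr::with_seed(17, {
    for (i in 1:25) {
      for (n in c(4, 5)) {
        truth <- random_additive_matrix(n)
        tr <- bionj_tree(truth$d)
        expect_true(same_topology(tr, truth$tree))
        # and agrees with the least-squares brute-force oracle
        expect_true(same_topology(tr, ls_topology_oracle(truth$d)))
      }
    }
  })
})

test_that("three taxa give the closed-form star", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- bionj_tree(d)
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.5)  # (2 + 3 - 4) / 2
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)
  expect_error(bionj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("ultrametric matrices reproduce the single-linkage clustering topology", {
  withr::with_seed(23, {
    for (i in 1:10) {
      tr <- ape::rcoal(5)
      tr$tip.label <- paste0("t", 1:5)
      d <- ape::cophenetic.phylo(tr)
      bt <- bionj_tree(d)
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      hctree <- ape::unroot(ape::as.phylo(hc))
      expect_true(same_topology(bt, hctree))
    }
  })
})

test_that("bootstrap supports: forced cherry at 100, single replicate in {0,100}, seeded determinism", {
  withr::with_seed(2, {
    base <- replicate(4, paste(sample(Biostrings::AA_STANDARD, 120, TRUE),
                               collapse = ""))
  })
  aln <- c(a1 = base[1], a2 = base[1], b = base[2], c = base[3],
           d = base[4])
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 1)
  cherry_node <- ape::getMRCA(tr, c("a1", "a2"))
  expect_equal(node_sup <- tr$node.label[cherry_node - ape::Ntip(tr)], 100)
  tr1 <- bootstrap_support(aln, n_replicates = 1, seed = 4)
  expect_true(all(tr1$node.label %in% c(0, 100, NA)))
  tr2a <- bootstrap_support(aln, n_replicates = 25, seed = 9)
  tr2b <- bootstrap_support(aln, n_replicates = 25, seed = 9)
  expect_identical(tr2a$node.label, tr2b$node.label)
  expect_error(bootstrap_support(c(a = "M", b = "K", c = "V"), seed = 1),
               "2 columns")
})

test_that("bootstrap supports are invariant to leaf order permutation", {
  withr::with_seed(31, {
    tr0 <- ape::rtree(6)
    tr0$tip.label <- paste0("t", 1:6)
    aln <- evolve_family(150, tr0, seed = 5)
  })
  sup_of <- function(m) {
    tr <- bootstrap_support(m, n_replicates = 30, seed = 3)
    # index supports by the clade they subtend
    ntip <- ape::Ntip(tr)
    labs <- vapply((ntip + 1):(ntip + tr$Nnode), function(nd) {
      paste(sort(tree_tips_under_export(tr, nd)), collapse = ",")
    }, character(1))
    setNames(tr$node.label, labs)
  }
  # helper mirrors the internal tip-gathering
  tree_tips_under_export <- function(tree, node) {
    tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
  }
  s1 <- sup_of(aln)
  s2 <- sup_of(aln[rev(rownames(aln)), ])
  shared <- intersect(names(s1), names(s2))
  expect_gt(length(shared), 0)
  expect_equal(s1[shared], s2[shared])
})

test_that("midpoint rooting splits the longest leaf-to-leaf path", {
  tr <- read_gene_tree("((A:1,B:1):1,C:4);")
  rooted <- midpoint_root(tr)
  expect_true(ape::is.rooted(rooted))
  # root must fall on C's terminal edge: C alone on one side
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  sides <- lapply(kids, function(k) {
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k] else
      rooted$tip.label[phangorn::Descendants(rooted, k, "tips")[[1]]]
  })
  expect_true(any(vapply(sides, function(s) identical(s, "C"), logical(1))))
  expect_warning(midpoint_root(read_gene_tree("((A:0,B:0):0,C:0);")),
                 "zero")
})

test_that("distance matrices survive a PHYLIP-style write/read round trip", {
  withr::with_seed(7, {
    d <- random_additive_matrix(5)$d
  })
  f <- withr::local_tempfile(fileext = ".dist")
  write_distance_matrix(d, f)
  d2 <- read_distance_matrix(f)
  expect_equal(d2, d, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(rownames(d2), rownames(d))
})
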