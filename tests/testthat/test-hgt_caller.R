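test_that("nesting among bacteria is called HGT with the bacterial sister reported", {
  taxa <- toy_taxa()
  tr <- read_gene_tree(
    "((focal:0.1,bacA:0.1)95:0.3,(bacB:0.2,(euk1:0.1,euk2:0.1):0.2):0.1);"
  )
  call <- classify_topology(tr, "focal", taxa)
  expect_equal(call$class, "hgt")
  expect_equal(call$sister_taxa[[1]]$species, "Serratia sp.")
  expect_equal(call$six_type, "A")
  expect_equal(call$nesting_support, 95)
})

test_that("a eukaryote first sister is called vertical; mixed sisters are unresolved", {
  taxa <- toy_taxa()
  vert <- read_gene_tree(
    "((focal:0.1,ins1:0.1):0.3,(euk1:0.2,(bacA:0.1,bacB:0.1):0.2):0.1);"
  )
  call <- classify_topology(vert, "focal", taxa)
  expect_equal(call$class, "vertical")
  expect_equal(call$six_type, "C")
  mixed <- read_gene_tree(
    "((focal:0.1,(bacA:0.1,euk2:0.1):0.05):0.3,(euk1:0.2,bacB:0.2):0.1);"
  )
  call2 <- classify_topology(mixed, "focal", taxa)
  expect_equal(call2$class, "unresolved")
})

test_that("recipient-lineage homologs are absorbed into the focal side", {
  taxa <- toy_taxa()
  tr <- read_gene_tree(
    "(((focal:0.05,lep2:0.05):0.1,bacA:0.1):0.3,(bacB:0.2,(euk1:0.1,euk2:0.1):0.2):0.1);"
  )
  call <- classify_topology(tr, c("focal", "lep2"), taxa)
  expect_equal(call$class, "hgt")
  # even when only the candidate is given, lep2 is treated as lineage
  call2 <- classify_topology(tr, "focal", taxa)
  expect_equal(call2$class, "hgt")
})

test_that("low support on the decisive clade demotes HGT to unresolved", {
  taxa <- toy_taxa()
  tr <- read_gene_tree(
    "((focal:0.1,bacA:0.1)30:0.3,(bacB:0.2,(euk1:0.1,euk2:0.1):0.2):0.1);"
  )
  expect_equal(classify_topology(tr, "focal", taxa)$class, "unresolved")
  expect_equal(classify_topology(tr, "focal", taxa,
                                 min_support = 20)$class, "hgt")
})

test_that("classification is invariant to leaf order and branch-length scaling", {
  taxa <- toy_taxa()
  txt <- "((focal:0.1,bacA:0.1):0.3,(bacB:0.2,(euk1:0.1,euk2:0.1):0.2):0.1);"
  tr <- read_gene_tree(txt)
  base <- classify_topology(tr, "focal", taxa)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(classify_topology(rot, "focal", taxa)$class, base$class)
  scaled <- tr
  scaled$edge.length <- scaled$edge.length * 7
  expect_equal(classify_topology(scaled, "focal", taxa)$class, base$class)
  expect_error(classify_topology(tr, "absent", taxa), "absent")
})

test_that("refinement prunes clutter and recovers a planted transfer", {
  # family where the focal copy sits in a bacterial clade, with many noisy
  # distant eukaryote homologs that clutter the first-pass tree
  tr0 <- read_gene_tree(paste0(
    "(((focal:0.05,bacA:0.05):0.05,bacB:0.1):0.9,",
    "((euk1:0.4,euk2:0.45):0.3,(ins1:0.5,lep2:0.55):0.3):0.9);"
  ))
  withr::with_seed(13, {
    aln <- evolve_family(220, tr0, seed = 99)
  })
  taxa <- toy_taxa()
  call <- refine_and_recall("focal", aln, taxa, focal_ids = "focal",
                            n_bootstrap = 100, seed = 8)
  expect_equal(call$class, "hgt")
  rep2 <- refine_and_recall("focal", aln, taxa, focal_ids = "focal",
                            n_bootstrap = 100, seed = 8)
  expect_identical(call$nesting_support, rep2$nesting_support)
  # over-aggressive pruning leaves too few taxa
  small <- aln[c("focal", "bacA", "lep2"), ]
  few <- refine_and_recall("focal", small, taxa, focal_ids = "focal",
                           n_bootstrap = 10, seed = 8)
  expect_equal(few$class, "unresolved")
  expect_equal(few$reason, "too_few_taxa")
})

test_that("donor inference: single sister at species rank, sets resolved by hit ranking at genus rank", {
  taxa <- toy_taxa()
  single <- classify_topology(read_gene_tree(
    "((focal:0.1,bacA:0.1)95:0.3,(bacB:0.2,(euk1:0.1,euk2:0.1):0.2):0.1);"
  ), "focal", taxa)
  single$sister_taxa[[1]]$species <- "Listeria grayi DSM 20601"
  don <- infer_donor(single)
  expect_equal(don$donor, "Listeria grayi DSM 20601")
  expect_equal(don$rank, "species")

  multi <- classify_topology(read_gene_tree(
    "((focal:0.1,(bacA:0.1,bacB:0.1):0.1)95:0.3,(euk1:0.1,euk2:0.1):0.2);"
  ), "focal", taxa)
  multi$sister_taxa[[1]]$species <- c("Serratia proteamaculans 568",
                                      "Yersinia pestis")
  don2 <- infer_donor(multi, c("Serratia proteamaculans 568",
                               "Yersinia pestis"))
  expect_equal(don2$donor, "Serratia")
  expect_equal(don2$rank, "genus")

  vert <- classify_topology(read_gene_tree(
    "((focal:0.1,ins1:0.1):0.3,(euk1:0.2,(bacA:0.1,bacB:0.1):0.2):0.1);"
  ), "focal", taxa)
  expect_error(infer_donor(vert), "HGT")
})

test_that("transfer depth maps presence sets onto the superfamily hierarchy", {
  expect_equal(infer_transfer_depth("Bombycoidea"), "Bombycoidea")
  expect_equal(
    infer_transfer_depth(c("Bombycoidea", "Papilionoidea", "Noctuoidea")),
    "Macrolepidoptera"
  )
  expect_equal(
    infer_transfer_depth(c("Bombycoidea", "Papilionoidea", "Noctuoidea",
                           "Pyraloidea", "Tortricoidea")),
    "Apoditrysia"
  )
  expect_error(infer_transfer_depth(character(0)), "non-empty")
  expect_error(infer_transfer_depth("Sphingidae"), "Unknown")
})

test_that("adding a superfamily never yields a shallower depth label", {
  depth_rank <- function(lbl) {
    match(lbl, c("Bombycoidea", "Macrolepidoptera", "Obtectmera",
                 "Apoditrysia"))
  }
  sf <- c("Bombycoidea", "Papilionoidea", "Noctuoidea", "Pyraloidea",
          "Tortricoidea")
  withr::with_seed(29, {
    for (i in 1:30) {
      base <- unique(c("Bombycoidea", sample(sf, sample(0:3, 1))))
      remaining <- setdiff(sf, base)
      add <- remaining[sample.int(length(remaining), 1)]
      expect_gte(depth_rank(infer_transfer_depth(c(base, add))),
                 depth_rank(infer_transfer_depth(base)))
    }
  })
})
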