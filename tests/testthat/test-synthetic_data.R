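test_that("sequence evolution: zero-length trees copy the root, divergence grows with distance", {
  star <- read_gene_tree("(a:0,b:0,c:0);")
  m <- evolve_family(80, star, seed = 1)
  expect_equal(m["a", ], m["b", ], ignore_attr = TRUE)
  expect_equal(m["a", ], m["c", ], ignore_attr = TRUE)
  # mean p-distance ordered by path length over repeated simulations
  near <- read_gene_tree("(a:0.05,b:0.05);")
  far <- read_gene_tree("(a:0.5,b:0.5);")
  pdist <- function(tr, seed) {
    mm <- evolve_family(100, tr, seed = seed)
    mean(mm["a", ] != mm["b", ])
  }
  p_near <- mean(vapply(1:40, function(s) pdist(near, s), numeric(1)))
  p_far <- mean(vapply(1:40, function(s) pdist(far, s), numeric(1)))
  expect_lt(p_near, p_far)
  # determinism and error paths
  expect_identical(evolve_family(60, near, seed = 7),
                   evolve_family(60, near, seed = 7))
  bad <- near
  bad$edge.length[1] <- -0.1
  expect_error(evolve_family(60, bad, seed = 1), "non-negative")
})

test_that("planted transfers regraft the recipient subtree into the donor clade", {
  pl <- plant_transfer("Serratia_marcescens", "Apoditrysia", seed = 4)
  tips <- pl$tree$tip.label
  # all five superfamilies present, nested next to the donor
  expect_true(all(c("Bombyx_mori", "Papilio_xuthus", "Helicoverpa_armigera",
                    "Ostrinia_nubilalis", "Cydia_pomonella") %in% tips))
  mrca <- ape::getMRCA(pl$tree, c("Bombyx_mori", "Serratia_marcescens"))
  under <- pl$tree$tip.label[phangorn::Descendants(pl$tree, mrca,
                                                   "tips")[[1]]]
  expect_false("Saccharomyces_cerevisiae" %in% under)
  # shallow transfer carries only Bombycoidea
  pl2 <- plant_transfer("Listeria_grayi", "Bombycoidea", seed = 4)
  expect_false("Papilio_xuthus" %in% pl2$tree$tip.label)
  # duplication_p = 1 adds a tandem focal copy
  pl3 <- plant_transfer("Listeria_grayi", "Bombycoidea",
                        duplication_p = 1, seed = 4)
  expect_true(pl3$duplicated)
  expect_true("Bombyx_mori_dup" %in% pl3$tree$tip.label)
  expect_error(plant_transfer("Escherichia_coli", "Bombycoidea", seed = 1),
               "donor")
  expect_error(plant_transfer("Listeria_grayi", "Sphingidae", seed = 1),
               "recipient node")
})

test_that("amelioration endpoints pin the GC metadata to donor or recipient background", {
  gc_at <- function(strength, seeds) {
    vapply(seeds, function(s) {
      plant_transfer("Methylobacterium_radiotolerans", "Bombycoidea",
                     amelioration = strength, seed = s)$gc
    }, numeric(1))
  }
  seeds <- withr::with_seed(19, sample.int(1e6, 30))
  gc0 <- gc_at(0, seeds)
  gc1 <- gc_at(1, seeds)
  expect_lt(abs(mean(gc0) - 0.69), 0.02)   # donor baseline
  expect_lt(abs(mean(gc1) - 0.478), 0.02)  # recipient background
})

test_that("generated datasets respect config counts, cross-reference ids and repeat bit-identically", {
  cfg <- simulation_config(seed = 5, n_families = 8,
                           transfer_fraction = 0.25,
                           contaminant_fraction = 0.125,
                           sequence_length = 60)
  sim <- generate_dataset(cfg)
  expect_equal(dplyr::n_distinct(sim$sequences$family_id), 8)
  fam_status <- unique(sim$truth[, c("family_id", "status")])
  counts <- as.data.frame(table(status = fam_status$status))
  names(counts)[2] <- "n"
  expect_equal(counts$n[counts$status == "hgt"], 2)
  expect_equal(counts$n[counts$status == "contaminant"], 1)
  expect_true(all(sim$annotations$gene_id %in% sim$sequences$id))
  expect_true(all(sim$truth$gene_id %in% sim$annotations$gene_id))
  expect_false(anyDuplicated(sim$sequences$id) > 0)
  sim2 <- generate_dataset(cfg)
  expect_identical(sim$sequences, sim2$sequences)
  expect_identical(sim$annotations, sim2$annotations)
  # no transfers when the fraction is zero
  none <- generate_dataset(simulation_config(seed = 5, n_families = 6,
                                             transfer_fraction = 0,
                                             contaminant_fraction = 0,
                                             sequence_length = 60))
  expect_false(any(none$truth$status == "hgt"))
})

test_that("contaminant entries carry the full no-evidence profile and a bacterial sequence", {
  cfg <- simulation_config(seed = 11, n_families = 8,
                           transfer_fraction = 0, contaminant_fraction = 0.25,
                           sequence_length = 60)
  sim <- generate_dataset(cfg)
  cont <- sim$truth$gene_id[sim$truth$status == "contaminant"]
  expect_gt(length(cont), 0)
  ann <- sim$annotations[sim$annotations$gene_id %in% cont, ]
  expect_true(all(ann$est_count == 0))
  expect_true(all(!ann$cloned & !ann$anchored & !ann$relative_genome_homolog))
  # near-verbatim bacterial copy: ~98% identical to its source
  tr <- sim$truth[sim$truth$status == "contaminant", ][1, ]
  seqs <- sim$sequences
  cseq <- seqs$residues[seqs$id == tr$gene_id]
  src <- seqs$residues[seqs$family_id == tr$family_id &
                         seqs$species == tr$donor_lineage]
  pid <- mean(strsplit(cseq, "")[[1]] == strsplit(src, "")[[1]])
  expect_gt(pid, 0.9)
})

test_that("datasets round-trip through the on-disk formats", {
  cfg <- simulation_config(seed = 2, n_families = 4, sequence_length = 55)
  sim <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  back <- read_fasta(file.path(dir, "sequences.fasta"),
                     read_species_map(file.path(dir, "species_map.tsv")))
  expect_equal(nrow(back), nrow(sim$sequences))
  expect_equal(sort(back$id), sort(sim$sequences$id))
  cfg2 <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$seed, 2)
})

test_that("call evaluation scores perfect and degenerate callers correctly", {
  truth <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    family_id = paste0("f", 1:6),
    status = c("hgt", "hgt", "vertical", "vertical", "contaminant",
               "vertical"),
    transfer_node = c("Apoditrysia", "Bombycoidea", NA, NA, NA, NA),
    duplicated = FALSE
  )
  perfect <- tibble::tibble(gene_id = truth$gene_id,
                            final_call = truth$status)
  ev <- evaluate_calls(perfect, truth)
  expect_equal(ev$hgt_sensitivity, 1)
  expect_equal(ev$hgt_specificity, 1)
  expect_equal(ev$contamination_precision, 1)
  expect_equal(ev$contamination_recall, 1)
  allvert <- tibble::tibble(gene_id = truth$gene_id,
                            final_call = "vertical")
  ev2 <- evaluate_calls(allvert, truth)
  expect_equal(ev2$hgt_sensitivity, 0)
  expect_equal(ev2$hgt_specificity, 1)
  expect_equal(ev2$contamination_recall, 0)
  expect_error(evaluate_calls(perfect[1:3, ], truth), "match")
})
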