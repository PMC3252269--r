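# Fixed taxon panel emulated by the generator: a recipient Lepidopteran
# clade (five superfamilies) nested among other eukaryotes, plus eubacterial
# clades (candidate donors) and archaea. GC baselines are per-genome
# compositional proxies used for the amelioration metadata.
synthetic_taxa_table <- function() {
  tibble::tribble(
    ~species, ~group, ~superfamily, ~gc_baseline,
    "Bombyx_mori", "recipient_insect", "Bombycoidea", 0.478,
    "Manduca_sexta", "recipient_insect", "Bombycoidea", 0.478,
    "Papilio_xuthus", "recipient_insect", "Papilionoidea", 0.478,
    "Helicoverpa_armigera", "recipient_insect", "Noctuoidea", 0.478,
    "Ostrinia_nubilalis", "recipient_insect", "Pyraloidea", 0.478,
    "Cydia_pomonella", "recipient_insect", "Tortricoidea", 0.478,
    "Drosophila_melanogaster", "other_insect", NA, 0.43,
    "Anopheles_gambiae", "other_insect", NA, 0.45,
    "Tribolium_castaneum", "other_insect", NA, 0.40,
    "Apis_mellifera", "other_insect", NA, 0.33,
    "Daphnia_pulex", "non_insect_arthropod", NA, 0.41,
    "Ixodes_scapularis", "non_insect_arthropod", NA, 0.45,
    "Homo_sapiens", "non_arthropod_metazoan", NA, 0.41,
    "Danio_rerio", "non_arthropod_metazoan", NA, 0.37,
    "Caenorhabditis_elegans", "non_arthropod_metazoan", NA, 0.35,
    "Saccharomyces_cerevisiae", "fungus", NA, 0.38,
    "Neurospora_crassa", "fungus", NA, 0.49,
    "Aspergillus_niger", "fungus", NA, 0.50,
    "Arabidopsis_thaliana", "plant", NA, 0.36,
    "Oryza_sativa", "plant", NA, 0.44,
    "Zea_mays", "plant", NA, 0.47,
    "Plasmodium_falciparum", "protist", NA, 0.19,
    "Dictyostelium_discoideum", "protist", NA, 0.22,
    "Serratia_marcescens", "eubacterium", NA, 0.59,
    "Photorhabdus_luminescens", "eubacterium", NA, 0.42,
    "Pseudomonas_fluorescens", "eubacterium", NA, 0.60,
    "Bacillus_thuringiensis", "eubacterium", NA, 0.35,
    "Listeria_grayi", "eubacterium", NA, 0.41,
    "Enterococcus_faecalis", "eubacterium", NA, 0.37,
    "Methylobacterium_radiotolerans", "eubacterium", NA, 0.69,
    "Wolbachia_pipientis", "eubacterium", NA, 0.35,
    "Lactococcus_lactis", "eubacterium", NA, 0.36,
    "Methanosarcina_barkeri", "archaebacterium", NA, 0.39,
    "Sulfolobus_solfataricus", "archaebacterium", NA, 0.36
  )
}

# Terminal branch lengths of the eubacterial leaves (substitutions/site);
# the donor leaf edge is split when a transfer is grafted onto it.
DONOR_TERMINALS <- c(
  Serratia_marcescens = 0.15, Photorhabdus_luminescens = 0.15,
  Pseudomonas_fluorescens = 0.25, Bacillus_thuringiensis = 0.15,
  Listeria_grayi = 0.15, Enterococcus_faecalis = 0.25,
  Methylobacterium_radiotolerans = 0.2, Wolbachia_pipientis = 0.25,
  Lactococcus_lactis = 0.3
)

lep_subtree_newick <- function(depth, focal_dup = FALSE) {
  bm <- if (focal_dup) {
    "(Bombyx_mori:0.02,Bombyx_mori_dup:0.02):0.03"
  } else {
    "Bombyx_mori:0.05"
  }
  bomb <- sprintf("(%s,Manduca_sexta:0.05)", bm)
  macro <- sprintf(
    "(%s:0.04,(Papilio_xuthus:0.06,Helicoverpa_armigera:0.06):0.03)", bomb
  )
  obt <- sprintf("(%s:0.03,Ostrinia_nubilalis:0.12)", macro)
  apo <- sprintf("(%s:0.04,Cydia_pomonella:0.16)", obt)
  switch(depth,
         Bombycoidea = bomb,
         Macrolepidoptera = macro,
         Obtectmera = obt,
         Apoditrysia = apo,
         abort(paste0("Unknown transfer node: ", depth)))
}

other_eukaryote_newick <- function(lep = NULL) {
  oth <- paste0("((Drosophila_melanogaster:0.15,Anopheles_gambiae:0.15)",
                ":0.08,(Tribolium_castaneum:0.18,Apis_mellifera:0.18):0.05)")
  insecta <- if (is.null(lep)) {
    oth
  } else {
    sprintf("(%s:0.12,%s:0.08)", lep, oth)
  }
  arthropoda <- sprintf(
    "(%s:0.08,(Daphnia_pulex:0.3,Ixodes_scapularis:0.3):0.06)", insecta
  )
  metazoa <- sprintf(
    "(%s:0.08,((Homo_sapiens:0.2,Danio_rerio:0.2):0.1,Caenorhabditis_elegans:0.35):0.05)",
    arthropoda
  )
  opistho <- sprintf(
    "(%s:0.1,(Saccharomyces_cerevisiae:0.25,(Neurospora_crassa:0.2,Aspergillus_niger:0.2):0.08):0.15)",
    metazoa
  )
  sprintf(
    "(%s:0.1,((Arabidopsis_thaliana:0.15,(Oryza_sativa:0.1,Zea_mays:0.1):0.08):0.25,(Plasmodium_falciparum:0.45,Dictyostelium_discoideum:0.4):0.1):0.1)",
    opistho
  )
}

prokaryote_newick <- function(donor = NULL, graft = NULL,
                              transfer_stem = 0.1) {
  leaves <- DONOR_TERMINALS
  leaf_txt <- vapply(names(leaves), function(nm) {
    txt <- sprintf("%s:%g", nm, leaves[[nm]])
    if (!is.null(donor) && nm == donor) {
      txt <- sprintf("(%s:%g,%s:%g):%g",
                     nm, leaves[[nm]] / 2, graft, transfer_stem,
                     leaves[[nm]] / 2)
    }
    txt
  }, character(1))
  c1 <- sprintf("((%s,%s):0.1,%s)",
                leaf_txt["Serratia_marcescens"],
                leaf_txt["Photorhabdus_luminescens"],
                leaf_txt["Pseudomonas_fluorescens"])
  c2 <- sprintf("((%s,%s):0.1,%s)",
                leaf_txt["Bacillus_thuringiensis"],
                leaf_txt["Listeria_grayi"],
                leaf_txt["Enterococcus_faecalis"])
  c3 <- sprintf("((%s,%s):0.1,%s)",
                leaf_txt["Methylobacterium_radiotolerans"],
                leaf_txt["Wolbachia_pipientis"],
                leaf_txt["Lactococcus_lactis"])
  bact <- sprintf("((%s:0.15,%s:0.15):0.08,%s:0.2)", c1, c2, c3)
  arch <- "(Methanosarcina_barkeri:0.3,Sulfolobus_solfataricus:0.3)"
  sprintf("(%s:0.15,%s:0.25)", bact, arch)
}

#' Simulation configuration for the synthetic HGT dataset
#'
#' Fixes every knob of the generator: family count, planted-transfer and
#' contaminant fractions, sequence length, substitution model,
#' post-transfer tandem-duplication probability, GC amelioration strength,
#' and the mandatory seed. Defaults describe the emulated study regime: a
#' recipient clade of five Lepidopteran superfamilies nested among
#' eukaryote relatives, distant eubacterial donor clades, transfers planted
#' at every level of the superfamily hierarchy, and metadata-free
#' contaminant sequences copied from bacteria.
#'
#' @param seed Mandatory integer seed.
#' @param n_families Number of gene families (default 60).
#' @param transfer_fraction Fraction of families carrying one planted
#'   transfer (default 0.25).
#' @param contaminant_fraction Fraction of families realised as bacterial
#'   contaminant entries in the recipient gene set (default 0.1).
#' @param sequence_length Alignment length in residues (default 250,
#'   minimum 50).
#' @param model Amino-acid substitution model for sequence evolution
#'   (default `"WAG"`).
#' @param duplication_p Probability of a post-transfer tandem duplicate
#'   (default 0.3).
#' @param amelioration GC amelioration strength in `[0, 1]`: 0 keeps the
#'   donor's composition, 1 reaches the recipient background (default 0.5).
#' @param transfer_stem Branch length between the donor lineage and the
#'   transferred copy's origin (default 0.1 substitutions/site).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_families = 60,
                              transfer_fraction = 0.25,
                              contaminant_fraction = 0.1,
                              sequence_length = 250, model = "WAG",
                              duplication_p = 0.3, amelioration = 0.5,
                              transfer_stem = 0.1) {
  if (missing(seed)) abort("simulation_config requires an explicit seed.")
  stopifnot(
    n_families >= 1,
    transfer_fraction >= 0, transfer_fraction <= 1,
    contaminant_fraction >= 0, contaminant_fraction <= 1,
    transfer_fraction + contaminant_fraction <= 1,
    sequence_length >= 50,
    duplication_p >= 0, duplication_p <= 1,
    amelioration >= 0, amelioration <= 1,
    transfer_stem > 0
  )
  structure(
    list(seed = as.integer(seed), n_families = as.integer(n_families),
         transfer_fraction = transfer_fraction,
         contaminant_fraction = contaminant_fraction,
         sequence_length = as.integer(sequence_length), model = model,
         duplication_p = duplication_p, amelioration = amelioration,
         transfer_stem = transfer_stem),
    class = "simulation_config"
  )
}

#' Evolve one gene family along a tree
#'
#' Simulates amino-acid sequences of length `root_length` along
#' `tree_with_rates` (branch lengths in expected substitutions/site) under
#' an empirical substitution model, via Markov substitution from a root
#' sequence drawn at the model's stationary frequencies. Leaves are
#' returned as an aligned (gap-free) character matrix.
#'
#' @param root_length Number of residues.
#' @param tree_with_rates A `phylo` with non-negative branch lengths.
#' @param model Substitution model name (default `"WAG"`).
#' @param seed Mandatory seed; output is bit-identical for a fixed seed.
#' @return Character matrix, one row per leaf.
#' @export
evolve_family <- function(root_length, tree_with_rates, model = "WAG",
                          seed) {
  if (missing(seed)) abort("evolve_family requires an explicit seed.")
  if (is.null(tree_with_rates$edge.length) ||
      any(!is.finite(tree_with_rates$edge.length)) ||
      any(tree_with_rates$edge.length < 0)) {
    abort("Tree branch lengths must be finite and non-negative.")
  }
  sim <- withr::with_seed(seed, {
    phangorn::simSeq(tree_with_rates, l = root_length, type = "AA",
                     model = model)
  })
  m <- toupper(as.character(sim))
  m
}

#' Plant a horizontal transfer into a gene family
#'
#' Builds the gene tree of a family carrying one transfer event: the
#' recipient subtree rooted at `recipient_node` (a superfamily-hierarchy
#' label) is regrafted onto the `donor_lineage` leaf edge at the event
#' time, the recipient lineage's vertical copy is absent, and the other
#' eukaryotes retain only distant homologs. With probability
#' `duplication_p` the focal recipient copy is tandemly duplicated after
#' the transfer. The GC metadata proxy of the transferred copy is shifted
#' from the donor's composition toward the recipient background in
#' proportion to `amelioration`.
#'
#' @param donor_lineage One of the eubacterial leaf names (see
#'   `synthetic_taxa()`).
#' @param recipient_node `"Bombycoidea"`, `"Macrolepidoptera"`,
#'   `"Obtectmera"` or `"Apoditrysia"`.
#' @param duplication_p Tandem duplication probability.
#' @param amelioration GC amelioration strength in `[0, 1]`.
#' @param transfer_stem Donor-to-copy branch length.
#' @param seed Mandatory seed.
#' @return A list: `tree` (`phylo`), `duplicated` (logical), `gc`
#'   (metadata GC of the transferred copy), `donor_lineage`,
#'   `recipient_node`.
#' @export
plant_transfer <- function(donor_lineage, recipient_node,
                           duplication_p = 0, amelioration = 0.5,
                           transfer_stem = 0.1, seed) {
  if (missing(seed)) abort("plant_transfer requires an explicit seed.")
  if (!(donor_lineage %in% names(DONOR_TERMINALS))) {
    abort(paste0("Unknown donor lineage: ", donor_lineage))
  }
  if (!(recipient_node %in% DEPTH_LABELS)) {
    abort(paste0("Unknown recipient node: ", recipient_node))
  }
  taxa <- synthetic_taxa_table()
  res <- withr::with_seed(seed, {
    duplicated <- runif(1) < duplication_p
    graft <- lep_subtree_newick(recipient_node, focal_dup = duplicated)
    euk <- other_eukaryote_newick(lep = NULL)
    prok <- prokaryote_newick(donor = donor_lineage, graft = graft,
                              transfer_stem = transfer_stem)
    txt <- sprintf("(%s:1.0,%s:1.0);", euk, prok)
    donor_gc <- taxa$gc_baseline[taxa$species == donor_lineage]
    recipient_gc <- taxa$gc_baseline[taxa$species == "Bombyx_mori"]
    gc <- donor_gc + amelioration * (recipient_gc - donor_gc) +
      rnorm(1, 0, 0.01)
    list(tree = ape::read.tree(text = txt), duplicated = duplicated,
         gc = min(max(gc, 0.05), 0.95))
  })
  res$donor_lineage <- donor_lineage
  res$recipient_node <- recipient_node
  res
}

#' Generate a complete synthetic dataset with truth table
#'
#' Produces `n_families` gene families on the fixed multi-clade taxon
#' panel: vertical families span the whole species tree; transfer families
#' carry one planted prokaryote-to-Lepidoptera transfer (donor lineage and
#' transfer depth drawn uniformly, optional tandem duplication, GC
#' amelioration applied to metadata); contaminant families contribute a
#' near-verbatim bacterial sequence labelled as a recipient gene with the
#' full no-evidence annotation profile (no EST, not cloned, unanchored, no
#' relative-genome homolog). All outputs are cross-referenced by gene id
#' and byte-identical for a fixed config.
#'
#' @param config A [simulation_config()].
#' @return A list of class `hgt_simulation`: `sequences` (all simulated
#'   sequences: `id`, `species`, `group`, `family_id`, `residues`),
#'   `recipient_species`, `species_map`, `annotations` (recipient gene
#'   metadata), `truth` (per recipient gene: `status`, `donor_lineage`,
#'   `transfer_node`, `duplicated`), `alignments` (per-family aligned
#'   matrices), `superfamily_map`, `taxa`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  taxa <- synthetic_taxa_table()
  n <- config$n_families
  n_hgt <- round(n * config$transfer_fraction)
  n_cont <- round(n * config$contaminant_fraction)
  statuses <- c(rep("hgt", n_hgt), rep("contaminant", n_cont),
                rep("vertical", n - n_hgt - n_cont))
  plan <- withr::with_seed(config$seed, {
    tibble::tibble(
      family_id = sprintf("fam%03d", seq_len(n)),
      status = sample(statuses),
      donor_lineage = sample(names(DONOR_TERMINALS), n, replace = TRUE),
      transfer_node = sample(DEPTH_LABELS, n, replace = TRUE),
      family_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  plan$donor_lineage[plan$status == "vertical"] <- NA
  plan$transfer_node[plan$status != "hgt"] <- NA

  fams <- purrr::map(seq_len(n), function(i) {
    simulate_one_family(plan[i, ], config, taxa)
  })

  sequences <- dplyr::bind_rows(purrr::map(fams, "sequences"))
  annotations <- dplyr::bind_rows(purrr::map(fams, "annotations"))
  truth <- dplyr::bind_rows(purrr::map(fams, "truth"))
  alignments <- setNames(purrr::map(fams, "alignment"), plan$family_id)
  out <- list(
    sequences = sequences,
    recipient_species = "Bombyx_mori",
    species_map = sequences[, c("id", "species", "group")],
    annotations = annotations,
    truth = truth,
    alignments = alignments,
    superfamily_map = setNames(taxa$superfamily, taxa$species),
    taxa = taxa,
    config = config
  )
  class(out) <- "hgt_simulation"
  out
}

simulate_one_family <- function(fam, config, taxa) {
  fid <- fam$family_id
  len <- config$sequence_length
  grp <- setNames(taxa$group, taxa$species)
  gcb <- setNames(taxa$gc_baseline, taxa$species)
  meta <- NULL

  if (fam$status == "hgt") {
    planted <- plant_transfer(
      fam$donor_lineage, fam$transfer_node,
      duplication_p = config$duplication_p,
      amelioration = config$amelioration,
      transfer_stem = config$transfer_stem, seed = fam$family_seed
    )
    m <- evolve_family(len, planted$tree, config$model,
                       seed = fam$family_seed + 1L)
    meta <- planted
  } else if (fam$status == "contaminant") {
    txt <- sprintf("%s;", prokaryote_newick())
    m <- evolve_family(len, ape::read.tree(text = txt), config$model,
                       seed = fam$family_seed + 1L)
    # verbatim bacterial copy (light sequencing-noise mutation) labelled
    # as a recipient gene
    src <- withr::with_seed(fam$family_seed, {
      sample(rownames(m)[grp[rownames(m)] == "eubacterium"], 1)
    })
    cont <- withr::with_seed(fam$family_seed + 2L, {
      s <- m[src, ]
      flip <- runif(length(s)) < 0.02
      s[flip] <- sample(Biostrings::AA_STANDARD, sum(flip), replace = TRUE)
      s
    })
    m <- rbind(m, Bombyx_mori = cont)
    meta <- list(gc = gcb[src], donor_lineage = src)
  } else {
    lep <- lep_subtree_newick("Apoditrysia")
    txt <- sprintf("(%s:1.0,%s:1.0);", other_eukaryote_newick(lep),
                   prokaryote_newick())
    m <- evolve_family(len, ape::read.tree(text = txt), config$model,
                       seed = fam$family_seed + 1L)
  }

  tips <- rownames(m)
  species <- sub("_dup$", "", tips)
  ids <- paste0(fid, "_", tips)
  rownames(m) <- ids
  sequences <- tibble::tibble(
    id = ids, species = species, group = unname(grp[species]),
    family_id = fid, residues = apply(m, 1, paste, collapse = "")
  )

  # Recipient gene metadata (every Bombyx_mori-labelled entry)
  rec_ids <- ids[species == "Bombyx_mori"]
  ann <- withr::with_seed(fam$family_seed + 3L, {
    k <- length(rec_ids)
    genuine <- fam$status != "contaminant"
    gc <- if (fam$status == "vertical") {
      min(max(rnorm(1, 0.478, 0.05), 0.2), 0.75)
    } else {
      unname(meta$gc)
    }
    start <- sample.int(5e6, 1)
    span <- 3 * len
    tibble::tibble(
      gene_id = rec_ids,
      family_id = fid,
      gc = rep(gc, k),
      intron_count = if (fam$status == "vertical") rpois(k, 2.3) else
        rep(0L, k),
      est_count = if (genuine) rpois(k, 4) else rep(0L, k),
      cloned = rep(FALSE, k),
      anchored = rep(genuine, k),
      relative_genome_homolog = rep(genuine, k),
      scaffold = rep(paste0("scaf_", fid), k),
      start = start + (seq_len(k) - 1) * (span + 3000),
      end = start + (seq_len(k) - 1) * (span + 3000) + span - 1,
      strand = rep("+", k),
      protein_length = rep(len, k)
    )
  })
  truth <- tibble::tibble(
    gene_id = rec_ids,
    family_id = fid,
    status = fam$status,
    donor_lineage = if (fam$status == "vertical") NA_character_ else
      unname(meta$donor_lineage),
    transfer_node = fam$transfer_node,
    duplicated = isTRUE(meta$duplicated)
  )
  list(sequences = sequences, annotations = ann, truth = truth,
       alignment = m)
}

#' Write a synthetic dataset to disk in pipeline-ready formats
#'
#' @param sim An `hgt_simulation`.
#' @param dir Output directory (created if needed): FASTA sequences,
#'   species map / annotation / truth TSVs, and the config as YAML.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$sequences, file.path(dir, "sequences.fasta"))
  write_species_map(sim$species_map, file.path(dir, "species_map.tsv"))
  readr::write_tsv(sim$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Score pipeline calls against the simulation truth
#'
#' Joins calls and truth by gene id (an id mismatch is an error) and
#' reports standard confusion-matrix metrics, scoring the HGT-versus-
#' vertical task and the contaminant-versus-genuine task separately.
#'
#' @param calls Tibble with `gene_id` and `final_call` in
#'   `c("hgt", "vertical", "contaminant")` (the pipeline's complete call
#'   table).
#' @param truth Truth tibble from [generate_dataset()].
#' @return A list: `hgt_sensitivity`, `hgt_specificity`,
#'   `contamination_precision`, `contamination_recall`, `confusion`
#'   (truth x call contingency tibble), `sensitivity_by_depth`.
#' @export
evaluate_calls <- function(calls, truth) {
  if (!setequal(calls$gene_id, truth$gene_id)) {
    abort("calls and truth gene ids do not match.")
  }
  j <- dplyr::inner_join(
    truth, calls[, c("gene_id", "final_call")], by = "gene_id"
  )
  called_hgt <- j$final_call == "hgt"
  called_cont <- j$final_call == "contaminant"
  is_hgt <- j$status == "hgt"
  is_vert <- j$status == "vertical"
  is_cont <- j$status == "contaminant"
  by_depth <- j |>
    dplyr::filter(.data$status == "hgt") |>
    dplyr::group_by(.data$transfer_node) |>
    dplyr::summarise(
      n = dplyr::n(),
      sensitivity = mean(.data$final_call == "hgt"),
      .groups = "drop"
    )
  list(
    hgt_sensitivity = if (any(is_hgt)) mean(called_hgt[is_hgt]) else NA,
    hgt_specificity = if (any(is_vert)) mean(!called_hgt[is_vert]) else NA,
    contamination_precision = if (any(called_cont)) {
      mean(is_cont[called_cont])
    } else {
      NA
    },
    contamination_recall = if (any(is_cont)) {
      mean(called_cont[is_cont])
    } else {
      NA
    },
    confusion = dplyr::count(j, .data$status, .data$final_call),
    sensitivity_by_depth = by_depth
  )
}
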