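tree_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]
tree_parent <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(p) == 0) NA_integer_ else p
}
tree_tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}
node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label) || node <= ntip) return(NA_real_)
  suppressWarnings(as.numeric(tree$node.label[node - ntip]))
}

as_taxa_table <- function(taxa) {
  if (is.data.frame(taxa)) {
    if (!all(c("id", "group") %in% names(taxa))) {
      abort("taxa need columns id and group (species optional).")
    }
    t <- tibble::as_tibble(taxa)
    if (!("species" %in% names(t))) t$species <- t$id
    return(t[, c("id", "species", "group")])
  }
  if (!is.null(names(taxa))) {
    return(tibble::tibble(id = names(taxa), species = names(taxa),
                          group = unname(taxa)))
  }
  abort("taxa must be a data frame or named group vector.")
}

#' Classify a rooted gene-tree topology as HGT, vertical, or unresolved
#'
#' Starting from the clade spanned by the focal sequences (the candidate
#' plus its recipient-lineage homologs), the walk toward the root records
#' the taxonomic composition of each successive sister subtree.
#' Recipient-group leaves encountered on the way are absorbed into the focal
#' side. The call is:
#'
#' * `hgt` — every sister subtree up to the smallest clade separating the
#'   focal set from all non-recipient eukaryotes consists exclusively of
#'   prokaryote leaves (the candidate is nested among bacteria), and that
#'   clade's bootstrap support, when available, is at least `min_support`;
#' * `vertical` — the first sister subtree carrying non-recipient leaves is
#'   purely eukaryotic;
#' * `unresolved` — a mixed prokaryote/eukaryote sister, insufficient
#'   support, or no informative sister at all.
#'
#' An optional A-F sub-label summarises the sister-composition pattern
#' (single prokaryote leaf, one prokaryote clade, or repeated prokaryote
#' nesting for HGT; insect, metazoan or other-eukaryote sister for
#' vertical). The A-F labels are a heuristic annotation; the ternary class
#' is the normative verdict.
#'
#' @param tree A `phylo`; rooted trees are used as-is, unrooted trees are
#'   rooted with `outgroup` when given, else by midpoint.
#' @param focal_ids Tip labels of the candidate and its recipient-lineage
#'   homologs; all must be in the tree.
#' @param taxa Tibble (`id`, `species`, `group`) or named group vector
#'   covering every leaf.
#' @param min_support Minimum support of the decisive clade for an `hgt`
#'   call, applied only when supports are present (default 50).
#' @param outgroup Optional outgroup tip label(s) for rooting.
#' @return A one-row tibble of class `topology_call`: `candidate_id`,
#'   `class`, `six_type`, `nesting_support`, and list-column `sister_taxa`
#'   (tibble of `species`, `group` at the decisive node).
#' @export
classify_topology <- function(tree, focal_ids, taxa, min_support = 50,
                              outgroup = NULL) {
  taxa <- as_taxa_table(taxa)
  missing_focal <- setdiff(focal_ids, tree$tip.label)
  if (length(missing_focal) > 0) {
    abort(paste0("Focal id(s) absent from tree: ",
                 paste(missing_focal, collapse = ", ")))
  }
  unlabelled <- setdiff(tree$tip.label, taxa$id)
  if (length(unlabelled) > 0) {
    abort(paste0("Leaves without group labels: ",
                 paste(unlabelled, collapse = ", ")))
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  } else if (!ape::is.rooted(tree)) {
    tree <- midpoint_root(tree)
  }
  grp <- setNames(taxa$group, taxa$id)
  spc <- setNames(taxa$species, taxa$id)
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  leaf_kind <- function(ids) {
    g <- grp[ids]
    dplyr::case_when(
      g == "recipient_insect" ~ "recipient",
      g %in% PROKARYOTE_GROUPS ~ "prokaryote",
      TRUE ~ "eukaryote"
    )
  }
  result <- function(class, six_type, support, sister_ids, reason = NA) {
    st <- tibble::tibble(species = unname(spc[sister_ids]),
                         group = unname(grp[sister_ids]))
    out <- tibble::tibble(
      candidate_id = focal_ids[1], class = class, six_type = six_type,
      nesting_support = support, sister_taxa = list(st),
      reason = as.character(reason)
    )
    class(out) <- c("topology_call", class(out))
    out
  }

  cur <- if (length(focal_ids) == 1) {
    which(tree$tip.label == focal_ids)
  } else {
    ape::getMRCA(tree, focal_ids)
  }
  prok_steps <- list()
  decisive_node <- NA_integer_
  # Non-focal leaves already inside the focal MRCA clade
  inside <- setdiff(tree_tips_under(tree, cur), focal_ids)
  inside <- inside[leaf_kind(inside) != "recipient"]
  if (length(inside) > 0) {
    kinds <- leaf_kind(inside)
    if (any(kinds == "eukaryote")) {
      return(result("unresolved", NA, NA_real_, character(0),
                    "eukaryote leaves interleaved with focal clade"))
    }
    prok_steps <- list(inside)
    decisive_node <- cur
  }
  while (cur != root) {
    parent <- tree_parent(tree, cur)
    sibs <- setdiff(tree_children(tree, parent), cur)
    sister_ids <- unlist(lapply(sibs, tree_tips_under, tree = tree))
    kinds <- leaf_kind(sister_ids)
    informative <- sister_ids[kinds != "recipient"]
    if (length(informative) > 0) {
      ik <- leaf_kind(informative)
      if (all(ik == "prokaryote")) {
        prok_steps <- c(prok_steps, list(informative))
        decisive_node <- parent
      } else if (all(ik == "eukaryote")) {
        if (length(prok_steps) > 0) {
          return(hgt_or_unresolved(tree, prok_steps, decisive_node,
                                   min_support, result))
        }
        six <- vertical_subtype(grp[informative])
        return(result("vertical", six, node_support(tree, parent),
                      informative))
      } else {
        if (length(prok_steps) > 0) {
          return(hgt_or_unresolved(tree, prok_steps, decisive_node,
                                   min_support, result))
        }
        return(result("unresolved", NA, node_support(tree, parent),
                      informative,
                      "mixed prokaryote/eukaryote sister subtree"))
      }
    }
    cur <- parent
  }
  if (length(prok_steps) > 0) {
    return(hgt_or_unresolved(tree, prok_steps, decisive_node, min_support,
                             result))
  }
  result("unresolved", NA, NA_real_, character(0),
         "no informative sister subtree")
}

hgt_or_unresolved <- function(tree, prok_steps, decisive_node, min_support,
                              result) {
  support <- node_support(tree, decisive_node)
  nearest <- prok_steps[[1]]
  if (!is.na(support) && support < min_support) {
    return(result("unresolved", NA, support, nearest,
                  "decisive clade below support threshold"))
  }
  six <- if (length(prok_steps) > 1) {
    "F"
  } else if (length(nearest) == 1) {
    "A"
  } else {
    "B"
  }
  result("hgt", six, support, nearest)
}

vertical_subtype <- function(groups) {
  if (any(groups %in% c("other_insect", "recipient_insect"))) return("C")
  if (any(groups %in% c("non_insect_arthropod", "non_arthropod_metazoan"))) {
    return("D")
  }
  "E"
}

#' Refine a gene family and re-classify its topology
#'
#' For a candidate left unresolved by the first-pass tree, retains the
#' top-`k_per_group` homologs per taxonomic group (ranked by similarity to
#' the candidate), rebuilds the tree with bootstrap support, midpoint-roots
#' it, and re-classifies. Deterministic for a fixed seed.
#'
#' @param candidate_id Tip label of the candidate sequence.
#' @param alignment Aligned family sequences (any form accepted by
#'   [protein_distance_matrix()]) including the candidate.
#' @param taxa Tibble (`id`, `species`, `group`) covering the alignment.
#' @param focal_ids Candidate plus recipient-lineage homolog ids (default:
#'   all recipient-group leaves).
#' @param similarity Optional named numeric ranking homologs (higher =
#'   more similar to the candidate); defaults to alignment identity to the
#'   candidate row.
#' @param k_per_group Homologs kept per group (default 3).
#' @param n_bootstrap Bootstrap replicates (default 1000).
#' @param min_support Support threshold for the decisive clade.
#' @param seed Mandatory seed.
#' @return A `topology_call` tibble; when fewer than 4 taxa remain the call
#'   is `unresolved` with `reason = "too_few_taxa"`.
#' @export
refine_and_recall <- function(candidate_id, alignment, taxa,
                              focal_ids = NULL, similarity = NULL,
                              k_per_group = 3, n_bootstrap = 1000,
                              min_support = 50, seed) {
  if (missing(seed)) abort("refine_and_recall requires an explicit seed.")
  taxa <- as_taxa_table(taxa)
  m <- as_alignment_matrix(alignment)
  if (!(candidate_id %in% rownames(m))) {
    abort("candidate_id missing from alignment.")
  }
  if (is.null(focal_ids)) {
    focal_ids <- union(
      candidate_id,
      intersect(rownames(m), taxa$id[taxa$group == "recipient_insect"])
    )
  }
  if (is.null(similarity)) {
    cand <- m[candidate_id, ]
    similarity <- apply(m, 1, function(r) {
      ok <- r != "-" & cand != "-"
      if (sum(ok) == 0) return(0)
      mean(r[ok] == cand[ok])
    })
  }
  others <- setdiff(rownames(m), focal_ids)
  ranked <- taxa |>
    dplyr::filter(.data$id %in% others) |>
    dplyr::mutate(sim = unname(similarity[.data$id])) |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$sim, n = k_per_group, with_ties = FALSE) |>
    dplyr::ungroup()
  keep <- union(intersect(focal_ids, rownames(m)), ranked$id)
  if (length(keep) < 4) {
    out <- tibble::tibble(
      candidate_id = candidate_id, class = "unresolved",
      six_type = NA_character_, nesting_support = NA_real_,
      sister_taxa = list(tibble::tibble(species = character(),
                                        group = character())),
      reason = "too_few_taxa"
    )
    class(out) <- c("topology_call", class(out))
    return(out)
  }
  sub <- m[keep, , drop = FALSE]
  tr <- bootstrap_support(sub, n_replicates = n_bootstrap, seed = seed)
  tr <- phangorn::midpoint(tr, node.labels = "support")
  classify_topology(tr, intersect(focal_ids, keep), taxa,
                    min_support = min_support)
}

#' Infer the donor taxon for an HGT call
#'
#' A single-leaf decisive sister clade names the donor at species rank;
#' when several bacteria form the sister clade, the highest-ranked of them
#' in the supplied similarity ranking is reported at genus rank.
#'
#' @param call A `topology_call` with `class == "hgt"`.
#' @param blast_ranking Species names in decreasing hit-score order: a
#'   character vector, or a hit tibble with `species` and `bit_score`
#'   columns.
#' @return A one-row tibble: `donor`, `rank` (`"species"`/`"genus"`),
#'   `donor_species`.
#' @export
infer_donor <- function(call, blast_ranking = NULL) {
  stopifnot(inherits(call, "topology_call"))
  if (call$class != "hgt") {
    abort("Donor inference is defined only for HGT calls.")
  }
  sisters <- call$sister_taxa[[1]]
  if (nrow(sisters) == 0) abort("HGT call has no sister taxa.")
  if (nrow(sisters) == 1 || length(unique(sisters$species)) == 1) {
    sp <- sisters$species[1]
    return(tibble::tibble(donor = sp, rank = "species", donor_species = sp))
  }
  ranking <- if (is.data.frame(blast_ranking)) {
    dplyr::arrange(blast_ranking, dplyr::desc(.data$bit_score))$species
  } else {
    blast_ranking
  }
  hit <- ranking[ranking %in% sisters$species]
  sp <- if (length(hit) > 0) hit[1] else sort(sisters$species)[1]
  tibble::tibble(donor = strsplit(sp, "\\s+")[[1]][1], rank = "genus",
                 donor_species = sp)
}

#' Transfer depth from homolog presence across Lepidopteran superfamilies
#'
#' Maps the set of superfamilies in which homologs of a transferred gene
#' are found to the most recent common ancestor label on the fixed nested
#' hierarchy Bombycoidea \eqn{\subset} Macrolepidoptera (adds
#' Papilionoidea, Noctuoidea) \eqn{\subset} Obtectmera (adds Pyraloidea)
#' \eqn{\subset} Apoditrysia (adds Tortricoidea). The label is a lower
#' bound on the age of the transfer.
#'
#' @param presence Character vector of superfamily names (subset of
#'   Bombycoidea, Papilionoidea, Noctuoidea, Pyraloidea, Tortricoidea).
#' @return One of `"Bombycoidea"`, `"Macrolepidoptera"`, `"Obtectmera"`,
#'   `"Apoditrysia"`.
#' @export
#' @examples
#' infer_transfer_depth(c("Bombycoidea", "Noctuoidea"))
infer_transfer_depth <- function(presence) {
  if (length(presence) == 0) abort("presence must be non-empty.")
  bad <- setdiff(presence, SUPERFAMILIES)
  if (length(bad) > 0) {
    abort(paste0("Unknown superfamily label(s): ", paste(bad, collapse = ", ")))
  }
  if ("Tortricoidea" %in% presence) return("Apoditrysia")
  if ("Pyraloidea" %in% presence) return("Obtectmera")
  if (any(c("Papilionoidea", "Noctuoidea") %in% presence)) {
    return("Macrolepidoptera")
  }
  "Bombycoidea"
}
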