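---
title: "Methods: a staged screen for bacteria-to-insect gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a staged screen for bacteria-to-insect gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hgtsieve)
```

## The detection problem

A gene in an insect genome that aligns strongly to bacteria can have three
explanations: genuine horizontal transfer from a prokaryote, ordinary
vertical descent within a widely conserved protein family, or bacterial
contamination of the sequenced assembly. `hgtsieve` separates the three
with a staged sieve: similarity thresholds remove everything without a
credible bacterial affinity, a taxonomic distribution filter removes
candidates that eukaryote homology explains better, gene-tree topology
supplies the positive evidence of transfer, and gene-level metadata
(transcripts, cloning, assembly anchoring, relative-genome homologs)
separates real genes from contaminant reads. No single stage is trusted on
its own; a candidate must survive all of them.

## Similarity stages

The screen uses exact Smith–Waterman local alignment with affine gaps
(default BLOSUM62, gap open 11, extend 1) rather than a heuristic
seeded search — at the scale this package targets (thousands of queries
against a desk-scale panel) exhaustive dynamic programming is affordable
and removes seeding artefacts from the analysis. E-values use the
Karlin–Altschul form $E = K m n e^{-\lambda S}$ with published ungapped
BLOSUM62 constants ($\lambda = 0.3176$, $K = 0.134$). Applying ungapped
constants to gapped optimal scores makes the absolute E-values
calibration-approximate; every decision in the pipeline depends only on a
threshold crossing, not on absolute calibration, and externally produced
hit tables (12-column tabular format) are accepted interchangeably.

Two threshold stages are predefined. The prokaryote screen (`blast1`)
requires $E \le 10^{-40}$, overlap $\ge 25\%$ and identity $\ge 25\%$; the
broad-database confirmation (`blast3`) relaxes to $E \le 10^{-3}$ and can
rescue a hit below the identity floor when query and subject share an
annotated protein domain. Two conventions here were genuinely open and are
configurable:

* **Overlap** is defined query-anchored — aligned span over query length —
  because the screen asks whether enough of the *candidate* is explained
  by the bacterial hit; a subject-anchored mode is provided.
* **Identity** counts identical pairs over all alignment columns,
  including gap columns (the convention of tabular alignment output); a
  matched-columns-only mode is provided.

## The distribution-spectrum filter

Eukaryote genomes are partitioned into six sets (protists, fungi, plants,
insects, non-insect arthropods, non-arthropod metazoans). A candidate is
dropped when **more than two** distinct species in one non-insect set each
beat the candidate's top bacterial hit on **both** score and identity.
Three readings were fixed deliberately: "more than two" is strict
($\ge 3$); "higher" is strict on both criteria, so ties never count
against a candidate; and species are counted once regardless of how many
sequences they contribute — the signal is taxonomic breadth, not hit
multiplicity. Bit score is the default score field (raw score available
via `score_field`), since bit scores are comparable across subjects of
different length. A candidate that would be dropped but has no insect
homolog at all is *recovered*: absence from all other insects is itself
consistent with a lineage-specific acquisition. These choices make the
filter monotone — weakening eukaryote evidence can never turn a kept
candidate into a dropped one — which the test suite checks by simulation.

## Trees and topology classification

Distances are p-distances with pairwise deletion of gap columns, corrected
for multiple hits with Kimura's approximation
$d = -\ln(1 - p - 0.2\,p^2)$. The correction diverges near $p \approx
0.87$, so saturated pairs ($p \ge 0.85$) receive a documented cap of 10
substitutions/site; maximum-likelihood distances are intentionally out of
scope, and externally computed matrices can be supplied for parity
studies. Trees are built with BIONJ (variance-weighted neighbour joining,
via `ape`), negative branch estimates clamped to zero, and rooted at the
midpoint of the longest leaf-to-leaf path unless an outgroup is given.
Bootstrap support resamples alignment columns with replacement and scores
each internal bipartition of the point-estimate tree across replicate
trees; all resampling is seeded and bit-reproducible.

Classification walks from the clade spanned by the focal set (the
candidate plus its recipient-lineage homologs, which are merged first so a
lineage-wide transfer is not mistaken for a contaminant-like singleton)
toward the root, recording the composition of each successive sister
subtree. Exclusively prokaryotic sisters up to the first
eukaryote-containing sister mean the candidate is *nested among bacteria*:
an `hgt` call, provided the decisive clade's support (when supports exist)
reaches `min_support`. A purely eukaryotic first sister is `vertical`; a
mixed sister, low support, or no informative sister is `unresolved`.
`min_support` defaults to 50 — the conventional "majority support" floor
for distance trees; no stricter value is forced because the decisive
evidence is the composition pattern, with support acting as a veto. The
A–F sub-labels (single prokaryote leaf; one prokaryote clade; repeated
prokaryote nesting; insect / metazoan / other-eukaryote vertical sisters)
are a heuristic summary of the sister pattern; the ternary class is the
normative output. Unresolved candidates are rebuilt with the top
`k_per_group = 3` homologs per taxonomic group and 1000 bootstrap
replicates before the final verdict.

## Contamination triage

The triage rule is conjunctive on *absence*: a candidate is a suspected
contaminant only when it has no EST, was never cloned, is not anchored on
a scaffold or chromosome with host neighbours, and has no homolog in a
related genome. High identity to the top bacterial hit (above a
configurable alert level, default 60 %) is reported as a supporting flag
but can never condemn a candidate by itself — genuinely recent transfers
are also highly similar to their donors. Unknown evidence fields are
treated as absent and logged, which biases the rule toward flagging; for a
screen whose false positives are contaminants, that is the conservative
direction.

## Transfer events, donors, depth

Tandem copies (same scaffold within 50 kb) and reciprocal-best homologs at
$\ge 40\%$ identity collapse into one transfer-event *type* (transitive
closure), since one integration followed by duplication is one event. The
gap and identity defaults bracket the tandem arrays seen in the packaged
candidate table (copies a few kb apart) with an order-of-magnitude margin.
Donor naming follows the decisive sister clade: a single-species sister is
reported at species rank; a multi-species bacterial sister is resolved to
the highest-ranking species in the hit ranking and reported at genus rank,
reflecting that the true donor lineage is then only resolvable to genus
level. Transfer depth is the most recent common ancestor label of the
superfamilies carrying homologs, on the fixed nested hierarchy
Bombycoidea ⊂ Macrolepidoptera ⊂ Obtectmera ⊂ Apoditrysia — a lower bound
on transfer age, since undetected homologs can only deepen it.

## Resampling statistics

Per-type aggregation takes within-type means, excluding missing values
(one packaged candidate has no recorded top-hit identity). Summary SDs use
the population (divisor-$N$) form, which is what reproduces the packaged
table's printed spread. The enrichment test draws $k$ values *without
replacement* from the screened background (matching a draw from a finite
gene set) and counts replicate means at or above the observed per-type
mean; the intron-free test reports both a Monte-Carlo estimate and the
exact sequential product $\prod_{i=0}^{k-1} (n_{if}-i)/(n_{bg}-i)$,
evaluated in log space and cross-checked in the tests against the
hypergeometric density. Both tests take explicit seeds and report the
replicate count, extreme count, and seed for exact reproducibility.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds gene families on a fixed 35-taxon panel: a
recipient clade of five Lepidopteran superfamilies nested among other
insects, arthropods, metazoans, fungi, plants and protists, three
eubacterial clades and two archaea. Sequences evolve by Markov
substitution under WAG along the family tree (via `phangorn`); a planted
transfer regrafts the recipient subtree at a chosen hierarchy depth onto a
donor leaf edge, optionally adds a tandem duplicate, and shifts the gene's
GC metadata from the donor's compositional baseline toward the recipient
background in proportion to the amelioration strength. Contaminants are
near-verbatim copies of a bacterial sequence (2 % noise) labelled as
recipient genes with the full no-evidence profile. Branch lengths place
vertical recipient-to-bacteria divergence far beyond the similarity
thresholds (root-to-root separation 2.0 substitutions/site) and planted
transfers well within them (donor-to-copy stem 0.1), mirroring the regime
in which the original screen operated (candidate identities roughly
35–75 %).

The default scenario — 60 families of length 250 over 35 taxa, 25 %
transfer families, 10 % contaminants, duplication probability 0.3,
amelioration 0.5 — was chosen once as the desk-scale study condition: it
keeps a complete pipeline run with exact alignment under ten minutes on a
single core while leaving every stage with real work to do. GC is carried
as *metadata*, not simulated at codon level, because composition enters
the method only as a summary statistic. The generator also omits indels
(families are gap-free, so alignment is trivially exact), rate
heterogeneity across sites, gene loss in non-recipient lineages, and any
realistic model of assembly error. Passing the end-to-end tests therefore
shows that the pipeline's logic recovers planted structure under its own
assumptions; it does not certify performance on real proteomes, where
alignment quality, incomplete taxon sampling and annotation noise
dominate.

## Degenerate inputs and tie handling

Zero-length sequences, prokaryote labels in the spectrum filter, focal ids
absent from a tree, and invalid count configurations are hard errors. A
taxon pair with no comparable alignment columns is an error naming the
pair. An all-zero-branch-length tree cannot be midpoint-rooted and falls
back to the designated base with a warning. Fewer than four taxa after
refinement pruning returns `unresolved` with reason `too_few_taxa` rather
than a degenerate tree. Three-taxon distance inputs use the closed-form
three-point branch lengths. Negative BIONJ branch estimates are clamped to
zero.

## Known limitations

Topology classification assumes the tree can be meaningfully rooted;
midpoint rooting misleads when rate variation is extreme. The E-value
calibration is approximate by construction (ungapped constants, gapped
scores). Donor inference reports the sister lineage, which for ancient
transfers may be a relative of the true (possibly extinct or unsampled)
donor. Transfer-depth labels are lower bounds that inherit the sampling
bias of the homolog search. Reconciliation-based (duplication–transfer–
loss) inference and absolute dating are out of scope.
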