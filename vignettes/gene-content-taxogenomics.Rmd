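---
title: "Gene-content taxogenomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-content taxogenomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxgen)
```

## The problem

Some bacterial species pairs are too close for single-marker taxonomy: their
16S rRNA genes are effectively identical, yet by whole-genome criteria they
are distinct species. Whole-genome comparison resolves them along three
independent evidence lines, all computed by this package from one amino-acid
multi-FASTA of annotated protein-coding genes per genome:

1. a **gene-content dendrogram** — how much of the annotated gene repertoire
   two genomes share;
2. **pairwise protein identity** of the shared genes — strongly bimodal
   between within-species pairs (above 99 %) and between-species pairs
   (below 89 %);
3. the **core genome** of a candidate group — the residue fraction belonging
   to gene families present in every member, which collapses from roughly
   three quarters within a species to near 10 % when two species are mixed.

## Models and procedures

### Reciprocal best hits

All genes of one genome are compared to all genes of another by local
(Smith–Waterman) alignment under a substitution matrix with affine gap
penalties; the defaults — BLOSUM62, gap open 11, gap extend 1 — are the BLAST
protein defaults, since the procedure emulates a BLAST-based annotation-server
comparison. Identity is BLAST-style: matches over alignment columns, internal
gap columns counted in the denominator. Coverage is the aligned span on the
shorter protein over the shorter protein's length.

A hit qualifies if it has positive score, identity ≥ 30 % and coverage ≥ 50 %.
These floors are deliberate artifact decisions: the upstream web service the
procedure emulates documents no cutoffs, so ours are declared, conservative
(they mainly suppress spurious low-complexity pairs), and printed in every
report. Each gene's best qualifying hit is chosen by score, then identity,
then lexicographically smallest target gene id — the two extra keys exist
purely to make results platform-independent. A pair is *bidirectional*
(a reciprocal best hit) when each gene is the other's best hit; bidirectional
pairing is therefore a partial matching, injective in both directions.

An optional k-mer prescreen (default: at least 3 shared 5-mers) skips
alignments between genes that cannot plausibly be homologs. At 85 % identity
two 250-residue orthologs share over a hundred 5-mers, while two unrelated
proteins share about 0.8, so the prescreen is safe in the identity regimes
this pipeline targets; it is off by default in `pair_filters()` and must stay
off when exact equivalence with exhaustive all-vs-all alignment matters (the
test suite's oracle comparisons run with it off). Genes shorter than the
k-mer size are never candidates under the prescreen.

### Gene-content distance

For genomes $G_1, G_2$ with annotated gene counts $|G_1|, |G_2|$ and
$|G_1 \cap G_2|$ bidirectional pairs,

$$d(G_1, G_2) = 1 - \frac{|G_1 \cap G_2|}{\min(|G_1|, |G_2|)}.$$

The denominator uses the annotated protein-coding gene counts of the input
proteomes, not pair-table sizes; RNA genes are outside this package's scope
and reports state that gene totals are CDS-only. The matching invariant keeps
$d$ in $[0,1]$; $d$ is symmetric, zero on self-comparison, and strictly
decreasing in the number of bidirectional pairs. It need not satisfy the
triangle inequality — a genome nearly contained in two dissimilar larger
genomes violates it — and the neighbour-joining stage accepts such matrices
deliberately. Undefined identity entries (genome pairs with no bidirectional
pairs) are reported as missing, never imputed or zeroed, because an imputed
identity would silently distort delimitation.

### Neighbour joining

Classic Saitou–Nei neighbour joining is implemented in the package: join the
pair minimising $Q_{ij} = (n-2)\,d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}$,
assign branch lengths by the two-point formulas, reduce the matrix by
$d_{uk} = (d_{ik}+d_{jk}-d_{ij})/2$, and finish with an unrooted
trifurcation. Numerical choices:

* **Ties** in $Q$ (within $10^{-9}$ relative) are broken by the
  lexicographically smallest pair of cluster labels, a cluster being labelled
  by its smallest leaf — determinism across platforms.
* **Negative branch lengths**, which arise on non-additive input, are clamped
  to zero *without* transferring length to the sibling edge; every clamp is
  reported via a `message()`. This is the simplest standard treatment and
  keeps the event visible.
* The output stays **unrooted**; rooting is a display decision applied
  separately by `midpoint_root()` (root at the centre of the longest
  leaf-to-leaf path). An all-zero-length tree has no midpoint; the root then
  goes deterministically on the first tip's edge with a warning.

On additive matrices NJ is consistent, and the test suite verifies exact
(≤ 1e-9) path-length recovery on random additive matrices of 4–10 taxa. The
plain Saitou–Nei variant was chosen over BIONJ/FastME because the emulated
workflow specifies neighbour joining without further qualification;
`ape::nj()` serves as an independent topology cross-check in the tests, never
as the implementation.

### Ortholog families and the core genome

Within a group, families are seeded from the genome with the fewest genes
(reference): each reference gene's family collects, per other genome, its
bidirectional partner with the reference if any; unmatched non-reference
genes stay singletons. Reference-star expansion was chosen over
connected-component clustering because it is deterministic, needs only the
pairwise tables the pipeline already has, and cannot chain unrelated families
through promiscuous hits; its cost is that orthologs absent from the
reference genome are not grouped, which biases the core (families present in
*every* genome) not at all and the accessory partition only mildly.

The core is measured in **residue length**: the group total percentage is the
summed length of all core-family members over the summed length of all
proteins in the group; per-strain percentages are the per-genome analogue,
summarised as mean ± SD with the population (divisor $n$) formula — the
groups are small, fixed, and the ± SD is descriptive, not inferential. A
gene-count core share is reported alongside for transparency. One dialect
difference is intentional and flagged in the documentation: the reference
workflow computes its core on nucleotide whole-genome alignments, whereas
this package uses a protein/gene-based proxy, so published core percentages
are a qualitative, not numeric, reference for real data. The eligibility rule
for a core-genome phylogeny is strict: total core **above** 70 %, so 70.0 %
exactly does not qualify.

### Species delimitation

Genome pairs whose mean bidirectional-pair identity is defined and at least
the within-species threshold are linked; clusters are connected components
(single linkage). Single linkage mirrors the dichotomous identity regime —
within-species values sit several points above any between-species value, so
chaining is not a practical risk — and is order-independent. The default
threshold of 95 % sits in the middle of the observed gap (above 99.4 % within,
below 89 % between); no numeric cutoff is claimed by the source workflow, so
the threshold is an explicit report parameter, never hard-coded. Raising it
can only refine the partition (tested). Each cluster is then checked for
monophyly on the unrooted NJ tree: a cluster is monophyletic when some edge
bipartitions the leaves into cluster versus rest.

## The pangenome simulator

`simulate_pangenome()` provides ground truth for every stage. Its design:

* **Sequences** are i.i.d. uniform over the 20 residues at the root;
  divergence is independent per-site substitution to a uniformly chosen
  *different* residue. No indels, duplications or recombination — so ortholog
  pairs align gaplessly and per-site comparison is the exact alignment, which
  is what makes exact identity planting possible.
* **Identities are planted per genome pair**, star-fashion: leaves diverge
  from a group ancestor, group ancestors from a common root. The per-edge
  retention probabilities are solved exactly from the match-probability
  recurrence of the uniform-substitution chain (for retention $s$ on each of
  two leaf edges, pairwise identity is $s^2 + (1-s)^2/19$; the between-group
  retention is found by `uniroot` on the four-edge path), so the realized
  within-group identity is unbiased for the target rather than accumulated
  approximately along the tree. The true tree is still emitted for
  topology-recovery tests.
* **Gene lengths** follow a shifted geometric distribution (minimum 50
  residues) around `mean_gene_length`, mimicking CDS length spread without
  fitting real data. When `mean_gene_length` is at the 50-residue floor all
  genes share that length exactly.
* **Gene content**: each group carries `core_genes` core families, a fraction
  `shared_core_fraction` of which is universal — shared by all groups at the
  between-group identity — while the rest are group-private; accessory genes
  are strain-private. `shared_core_fraction` is the knob that produces the
  characteristic weak between-species gene sharing (default 0.18 of a 0.78
  core, i.e. ~14 % sharing). `core_length_fraction` is planted by deriving
  the accessory genes' mean length from the realized core residue total;
  parameter combinations that would push the accessory mean below the
  50-residue floor are rejected at validation with the violated bound named.
* **Determinism**: one integer seed; a fixed seed reproduces the output bit
  for bit.

Defaults (2 groups × 4 genomes, within-identity 99.5 %, between 85 %, core
length fraction 0.78, ~14 % between-group sharing, mean gene length 300)
emulate the regime reported for a closely related species pair of
lactic-acid bacteria with ~2300 CDS per genome; gene counts are scaled down
(hundreds, not thousands) because the regime, not the genome size, is what
the downstream statistics respond to.

What the simulator does **not** emulate — and what passing tests therefore do
not show about real data: indels and alignment-gap handling in homologs,
paralogy (at most one family member per genome), horizontally transferred
genes at odd identities, length-biased annotation errors, and rate variation
across genes. The alignment and family stages handle such inputs
mechanically, but their accuracy in those regimes is unquantified here.

## Problem sizes used in validation

The test suite and the acceptance script run the pipeline at deliberately
modest sizes chosen as the smallest that still pin down each property: RBH
oracle equivalence on 3 genomes × 30 genes (exhaustive dynamic-programming
oracle, prescreen off); identity/core recovery on 6 genomes × ~270 genes;
the two-species classification scenario on 2 × 4 genomes × ~190 genes; NJ
consistency on 20 random additive matrices of 4–10 taxa. Planted-value
recovery at these sizes is well inside the stated tolerances (±0.5 identity
points, ±3 core points).

## Known limitations

* Reciprocal best hits approximate 1:1 orthology; in-paralogs and recent
  duplications (absent from the simulator) can displace true orthologs.
* The gene-content distance depends on annotation consistency: two genomes
  annotated by different pipelines can differ in |G| for reasons unrelated
  to biology. Reports state CDS-only totals for this reason.
* Core percentages are protein-based and not numerically comparable to
  nucleotide-alignment cores.
* The identity threshold is a declared default, not a universal constant;
  for taxa without a clean bimodal gap, single-linkage delimitation may
  chain clusters and the threshold must be set from the observed identity
  distribution.
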