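---
title: "Methods: classifying, tracing and expressing plant NBS resistance genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying, tracing and expressing plant NBS resistance genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbslineage)
```

## The biological problem

Plant NBS genes encode intracellular immune receptors of the
effector-triggered immunity (ETI) layer. Structurally they are mosaics of
five domain classes: the central NB-ARC ATPase module (letter **N**), the
C-terminal leucine-rich repeats that recognize pathogen effectors
(**L**), and three alternative N-terminal signalling domains — coiled-coil
(**C**), TIR (**T**) and RPW8 (**R**). The family is evolutionarily
volatile: genes duplicate in tandem and across chromosomes, ortholog
types drift (a CNL becomes an NL by losing its coiled-coil), and whole
domains — including the defining NB-ARC — degenerate away. This package
provides the machinery to quantify those dynamics from standard
bioinformatic intermediates (domain-hit tables, coiled-coil score tracks,
all-vs-all protein similarity, collinear blocks, GFF3 gene models), plus a
desk-scale view of how the NBS-LRR subclass responds to a salicylic-acid
style two-condition expression contrast.

External search engines (HMMER, BLAST, MCScanX, coiled-coil predictors,
motif finders, PlantCARE) are deliberately *not* run by the package; their
tabular outputs are the inputs.

## Architecture classification

A gene's architecture is the ordered string of its domain letters.

* **Hit filtering.** Domain hits are kept at `evalue <= 1e-10`. The
  similarity-search stage of this kind of survey conventionally uses that
  cutoff; the HMM stage of published pipelines typically reports "default
  parameters" only, so the same threshold is applied for coherence and is
  configurable (`evalue_max`).
* **Coiled-coil calling** (`detectCC`). Per-residue scores in [0, 1] are
  thresholded at 0.5 (the conventional operating point of deep-learning
  coiled-coil predictors); maximal runs of at least `min_len = 8` residues
  (one heptad plus one position — the shortest signal such predictors can
  support) become C hits.
* **Same-class merging** (`mergeHits`). Hits of one class separated by at
  most `gap_max = 150` residues merge into a single domain unit. The value
  sits between the typical spacing of LRR repeat hits within one LRR
  region (tens of residues) and the spacing of genuinely repeated domains
  (NN, NLNL architectures put same-class units several hundred residues
  apart), so repeat clusters collapse to one letter while true repeats
  survive. Published surveys do not state how they collapsed repeat hits;
  the gap rule is this package's explicit, testable choice and is
  configurable. Letters are ordered by interval midpoint with
  deterministic tie-breaks (start coordinate, then letter).
* **Typing** (`classifyArchitecture`). The type name is the letter string
  itself. Subclass NBS-LRR requires at least one N *and* one L; any N
  makes the gene an NBS gene. Genes whose letters contain no N are
  excluded from the survey table (`typeCountTable` returns them in a side
  table) — they are no longer NBS genes, but one may still appear inside a
  homologous lineage as evidence of NB-ARC degeneration.

The exon-count versus gene-length statistic (`structureCorrelation`) and
the motif-order check (`motifOrderConserved`, a subsequence test against
the canonical conserved order 6–5–3–1–7–2–8–4 with absent motifs allowed)
complete the gene-structure side.

## Homology typing and lineages

Similarity hits are reduced by `selectBestHits`: self hits are dropped,
only the best bitscore per ordered pair is kept, and cross-species
candidates must be reciprocal best hits. Orthology additionally requires
co-membership in a collinear block — synteny, not just similarity, is the
evidence for descent through speciation. Cross-species pairs outside
blocks are excluded entirely rather than demoted, because no published
fallback rule exists for them. The three relation types then partition
all retained pairs:

| relation | species | extra condition |
|---|---|---|
| ortholog | different | pair inside a collinear block |
| homochromosomal duplication | same | same chromosome |
| heterochromosomal duplication | same | different chromosomes |

`pairCensus` counts *genes* (not pairs) once per relation they
participate in; a gene can legitimately appear in both an ortholog count
and a duplication count. Whether published censuses of this kind count
genes or pairs is usually ambiguous; genes-per-relation is this package's
stated reading.

`assembleLineages` chains ortholog pairs between *adjacent* species of
the species chain (the species-tree order) into connected components. A
gene matching two genes in one neighbouring species is a hard error
rather than a silent choice. Flags:

* `complete` — every chain species has a member; an incomplete lineage is
  the signature of gene loss (degeneration).
* `type_conserved` — all members share one type name; lineages failing
  this record type change along the lineage.
* `chromosome_lineage` — member chromosomes mapped back to the first
  species through the majority-vote chromosome correspondence
  (`chromosomeCorrespondence`), derived from collinear-block gene
  memberships with ties broken by total paired-gene count.

A lineage needs at least two members; unpaired genes are simply absent
from the lineage table.

## Promoter cis-elements

Element occurrences within the 2,000 bp upstream window are mapped to
three functional categories through a closed table
(`inst/extdata/cis_category_map.tsv`, editable and replaceable) seeded
with the common PlantCARE vocabulary: hormone-responsive elements
(TCA-element and SARE for salicylic acid, ABRE, CGTCA/TGACG motifs, ...),
stress elements (TC-rich repeats, MBS, LTR, WUN-motif) and growth
elements (CAT-box, O2-site, ...). Unmapped element names fail loudly —
defaulting would silently distort the percentages. Percentages are of
all occurrences (not of genes, and sub-category percentages are of the
grand total, matching how such tables are printed) and are rounded half
away from zero to one decimal, the convention of printed percentages;
base R's banker's rounding would disagree on exact .05 boundaries.

## Expression workflow

FPKM is the closed form `counts * 1e9 / (gene_length * library_size)`
with library size the column sum. DEG calling is deliberately simple: a
Welch unequal-variance t-test on log2(FPKM + 1), Benjamini–Hochberg
adjustment, and the strict rule *up ⇔ fold change > 1.5 and adjusted
p < 0.05* (down symmetric at 1/1.5), with fold change the ratio of mean
FPKMs under a 0.01 pseudo-count. Negative-binomial shrinkage machinery
(DESeq2 and kin) is intentionally out of scope; the point is a
transparent, testable stand-in whose operating characteristics are
measured on synthetic truth rather than a reimplementation of a
published estimator. The practical consequence — documented honestly by
the calibration tests — is that a plain Welch test at three replicates
per condition only has power when replicate noise is low (see the
generator defaults below).

Co-expression modules follow the unsigned weighted-network recipe:
adjacency `|cor|^beta` with `beta = 6` (the classic unsigned default),
topological overlap

$$TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},$$

average-linkage clustering of `1 - TOM`, and a **static** cut at
`cut_height = 0.8` with `min_module_size = 30`; clusters are named by
colour in size order and the remainder is grey. Dynamic tree cutting was
deliberately replaced by a static cut: it is deterministic,
single-parameter and directly testable. The height default deserves a
note: for TOM matrices of realistic desk-scale designs, off-diagonal
overlap values are far from 1, so cutting very close to the tree top
(e.g. at 0.99+) merges everything into one cluster. Planted-block
experiments showed a broad plateau — cuts anywhere in 0.7–0.9 recover
two planted 40-gene blocks exactly, with near-pure membership — so 0.8
was fixed as the default. Module eigengenes are first principal
components of the row-standardized member matrix, unit-norm and
sign-oriented towards the members' mean profile, and module–trait
correlation is plain Pearson correlation (exact t-based p, n − 2 degrees
of freedom) against a treated/control indicator. Correlations are
computed on log2(FPKM + 1) — co-expression on the raw FPKM scale is
dominated by a handful of high-mean genes.

## The synthetic-data generator

`generateGenomes` plants a three-species, 19-chromosome design whose
focal species carries a fixed type table (22 NBS-LRR + 52 non-NBS-LRR
genes across eight types — the shape of a typical orchid survey column),
plus 10 complete and 4 incomplete orthologous lineages on 13 reference
chromosomes, 3 planted type changes, 1 planted NB-ARC deletion, and 3 + 2
same/different-chromosome duplication pairs. Key mechanics:

* Domain layouts respect real scale: NB-ARC units draw 150–300 aa, LRR
  regions are clusters of 2–4 short repeat hits with 10–100 aa gaps (so
  the `gap_max` merge rule is actually exercised), units are separated by
  more than `gap_max` so repeated letters survive, and coiled-coil
  segments exist only in the score tracks, never in the hit table.
* About 10% of genes receive an extra *sub-threshold* domain hit
  (e-value above the cutoff), exercising the significance filter without
  perturbing the recoverable truth; `noise_frac = 0` gives the fully
  noiseless mode in which recovery is provably exact.
* Incomplete lineages delete the **last** species' member. Deleting a
  middle member would sever the chain (orthologs are only called between
  adjacent species), turning one planted lineage into unplaced singletons
  instead of an incomplete lineage.
* Duplication pairs reuse same-type background genes (re-homed onto one
  or two chromosomes) so the focal species' type table stays exactly as
  planted.
* Chromosome correspondences are a random permutation per species;
  collinear blocks carry five filler gene pairs each so the majority vote
  has a clear signal.
* Every output stage draws from its own seeded substream of the master
  seed, so adding an output never perturbs existing files; equal seeds
  give byte-identical files.

`generateExpression` plants a two-condition negative-binomial count
matrix: log-normal gene means (`mean_log = log(1000)`, `sd_log = 0.5`),
dispersion 0.005, a configurable number of up-regulated genes with a
multiplicative treatment effect, and optional correlated blocks — the
first tied to the treatment indicator — for module detection. The noise
defaults describe a deeply sequenced, low-variability replicate design;
they were fixed once, by a power analysis of the Welch caller at the
study design (3 + 3 replicates, 500 genes, 20 planted 4× effects), which
is the regime in which a shrinkage-free test is a sensible stand-in. At
textbook dispersions of 0.1–0.3 the Welch test at n = 3 has essentially
no power at FDR 0.05 — a real limitation of the desk-scale stand-in, not
of the planted truth.

Module-detection experiments use a larger design (2,000 genes, two
40-gene blocks, 10 + 10 samples) for two documented reasons. First,
co-expression networks are not estimable from six samples: with n = 6
the chance |correlation| between unrelated genes is large, and TOM
amplifies it. Second, FPKM's library-size normalization couples genes
compositionally — if planted blocks make up a large share of the
library, every background gene inherits a shared anti-factor and the
background itself clusters; at 80 block genes among 2,000 the artifact
is diluted below detectability. Both effects were observed directly in
planted-block experiments, and both are properties real data share.

### What the generator does and does not emulate

It emulates the *structures* the pipeline reasons about: domain-hit
geometry, collinear blocks, chromosome correspondences, lineage
degeneration, promoter-element category balance, and planted expression
effects. It does not emulate sequence content (no nucleotides or amino
acids are generated), alignment artifacts, fragmented assemblies,
paralog interference within collinear blocks, overdispersed outlier
samples, or batch structure. Passing recovery tests therefore certifies
the pipeline's logic, not the upstream search engines' behaviour on real
genomes.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (GFF3 convention); the
  merge gap between hits is `start2 - end1 - 1`.
* Genes with no exon features parse as single-exon genes with a warning
  (single-exon NBS genes are common); exons with unresolvable parents are
  skipped with a warning; malformed rows name their line number.
* `pearsonR` refuses vectors shorter than 3 or with zero variance;
  `categorizeElements` refuses an empty table (a 0/0 percentage) and
  unmapped element names; `tomSimilarity` refuses asymmetric input,
  nonzero diagonals and out-of-range entries; `callDegs` requires two
  replicates per condition; `computeFpkm` refuses zero library sizes.
* Collinear blocks with zero pairs are dropped with a warning; a pair
  line before any block header is an error.
* The pipeline itself is RNG-free; all randomness lives in the
  generators, keyed by one master seed recorded in the run manifest.

## Problem sizes

The test suite and the acceptance script run, per simulation replicate,
at 500 genes × 6 samples for differential expression (20 replicates),
2,000 genes × 20 samples for module detection (20 replicates), ~250
planted genes across three species for the genome fixtures, 1,000 random
hit sets for the interval-merge oracle and 1,000 random vector pairs for
the correlation oracle — sizes at which every planted property is
measurable with sharp expectations while a full run stays in the
minutes range on one CPU.

## Known limitations

* The Welch-test DEG caller has no dispersion shrinkage; its calibration
  holds in the low-dispersion regime it is documented for.
* The static TOM cut has one global height; designs with modules of very
  different tightness may need per-dataset tuning where dynamic cutting
  would adapt automatically.
* Ortholog detection trusts collinear blocks entirely; lineages broken
  by assembly gaps in real data would surface as (spurious) incomplete
  lineages.
* The chromosome correspondence is a single majority vote per species
  pair; genuinely fissioned/fused chromosomes would need a one-to-many
  mapping.
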