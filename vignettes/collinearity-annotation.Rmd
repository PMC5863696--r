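---
title: "Collinearity-guided orthology and annotation transfer: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collinearity-guided orthology and annotation transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synortho)
```

# The problem

Annotating protein-coding genes in a newly sequenced genome usually means
transferring functions from homologs found by sequence similarity alone.
Similarity is blind to genomic context: a best BLAST hit may be a
paralog, and distant orthologs may be missed entirely. When many related
genomes are available, conservation of genome *organisation* —
collinearity — provides an independent and often stronger signal.
`synortho` implements that idea as a pipeline: conserved alignment
anchors → collinear segments at multiple species depths → scored
ortholog pairs → annotation transfer → comparison and expression-based
validation.

# Markers: multiple-alignment anchors

A multiple whole-genome alignment (MAF) is read as a series of blocks,
each giving aligned intervals in a subset of species. Blocks present in
**all** required species, projected onto the reference, are the
multiple-alignment anchors (MAAs). One block yields one anchor;
overlapping projections are *not* merged, so anchor counts track blocks,
while genome coverage is always computed on the interval union (each
base counted once). The choice of union semantics for coverage is a
deliberate, flagged decision — the alternative (counting overlaps
multiply) would not be a fraction of the genome.

Quality-control statistics mirror what one inspects on real marker sets:
length distribution, coverage, GC enrichment over the genomic
background, per-chromosome placement uniformity, and base composition by
feature class.

Two of these need a modelling choice the data do not dictate:

* **GC comparison.** Per-anchor GC is compared against an equal count of
  random windows, *length-matched* to the anchors (length and GC are
  confounded otherwise) and drawn uniformly with a caller-supplied seed.
  The test is a two-sided Mann–Whitney rank-sum: distribution-free and
  insensitive to the anchors' length heterogeneity.
* **Uniformity.** A one-sample KS test of anchor midpoints against the
  uniform distribution on (0, chromosome length), per chromosome, with a
  minimum of 8 markers. Midpoints, not bases: the question is where
  markers sit, not how long they are.
* **Feature composition.** Overlapping annotations are resolved by the
  fixed precedence CDS > UTR > ncRNA > intron > intergenic, with
  intergenic runs longer than 30 kb relabelled as gene desert. The
  precedence makes the per-base classification deterministic, so the
  class fractions sum to one whenever the classes cover the genome.

# Collinear segments

Given per-genome marker maps (rank-ordered per chromosome) and a set of
candidate homologous marker pairs (MAA projections paired by block
identity; genes paired by hits at E ≤ 1e−5), a collinear segment is a
chain of pairs whose ranks increase strictly on both genomes (or
decrease on one side — inversions are first-class), with at most
`gap_size` intervening non-homologous markers between consecutive
anchors on either side. Defaults follow the marker type: `gap_size = 30`
for MAA markers, 10 for genes, with `anchor_points = 3` and
`prob_cutoff = 0.01` throughout.

The detector returns **all set-maximal chains**: chains whose anchor set
is not strictly contained in another valid chain's set. Maximality is
decided on the structural constraints first; the anchor-point minimum
and the significance filter are applied to the maximal chains ("chains
survive the filters", rather than "filters reshape maximality"). The
test suite holds the detector to an exhaustive independent enumeration
of the same definition on random instances.

**Significance model.** The chain statistic is deliberately simple and
testable: the probability that a `span_a × span_b` rank window contains
at least `k` homologous pairs under a binomial null with per-cell
probability equal to the genome-wide candidate-pair density, Bonferroni
multiplied by the number of windows of that size in the hosting
chromosome pair. Windows are counted within the chromosome pair, not
genome-wide: the chain competes against alternative placements on its
own chromosomes. A Monte-Carlo check (permuting both marker orders
10,000 times) agrees with this tail within two-fold across the
parameter grid exercised in the tests. The p-value is monotone
decreasing in `k` and increasing in density; a fully saturated null
(density 1) returns p = 1, which is the correct degenerate answer — if
everything is homologous to everything, no chain is surprising.

**Levels.** Segments against partner species `s` are labelled `2way-d`
with `d` the divergence rank of `s` in the phylogenetic species order
(reference first). Multi-species `n-way` regions (n ≥ 3) are the
maximal reference regions simultaneously covered by segments with each
of the first n−1 partners — partners are incorporated strictly in tree
order, with the reference as origin — and each base is reported only at
the maximal `n` it attains. Coverage is per-base over unions of
overlapping segments of one species; whether a single contiguous segment
per species should be required instead is genuinely open, and the
per-base-union choice is flagged as such. The level sets are nested by
construction, which the tests assert.

# Ortholog pairs and the OPSS

A pair of genes (reference gene, partner gene) becomes an orthologous
protein-coding gene pair (OPP) iff

1. a homology hit at E ≤ 1e−5 links them (no further identity or
   coverage condition is imposed — the E-value is the only similarity
   criterion), and
2. at least 50% of **both** gene lengths lies inside the two sides of
   one MAA-based collinear segment. The threshold is inclusive (exactly
   half passes) and the condition is read conjunctively; requiring both
   genes is the stricter, symmetric reading.

Two further evidence types are recorded but not required: reciprocal
best hits (best = highest bitscore, ties by smaller E-value then
lexicographic id) and the same 50% co-location in *gene*-based segments.
The composite support score is

`OPSS = M + 0.5 · P + B`

with `M` the degree of the deepest supporting MAA-based level whose
species prefix includes the partner (pairwise support = 2), `P` the
analogue over gene-based segments (0 when unsupported), and `B ∈ {0, 2}`
for the reciprocal-best-hit flag. When several segments support a pair
the **maximum** level is taken, not the sum: the score is meant to say
how deep the strongest collinearity evidence reaches, and summing would
let many shallow segments impersonate deep conservation. A pair with
only pairwise MAA support scores exactly 2, below 3 — the signature of
the weakest acceptable evidence class. One gene may join OPPs with
several species, and many-to-many pairs within one species pair are
kept if each passes the conditions; no uniqueness constraint is imposed.

# Annotation transfer, comparison, validation

Transfer is a relational join: each target gene receives the union of
its orthologs' terms, with provenance (source gene, species, OPSS) per
contribution. Terms annotating fewer than 5 or more than 300 target
genes are then dropped; the filter counts genes in the **target**
annotation after transfer, because its purpose is to remove terms that
are uninformative (too small) or unspecific (too large) *for the target
species*. No ancestor-closure propagation is applied before counting —
the ontology hierarchy enters only through the semantic similarity —
though a closure option exists. The same machinery transfers any
OBO-shaped ontology (e.g. plant structure/stage ontologies) unchanged.

Annotation sets are triplets (P, G, GO) — gene-term pairs, genes, terms
— and are compared with three indices: Jaccard on P (structure-free),
Jaccard on G, and the mean gene-wise Wang semantic similarity
(structure-based). Wang similarity propagates S-values up the DAG
(S = 1 at the term, multiplied by 0.8 per `is_a` and 0.6 per `part_of`
edge, maximum over paths) and scores the shared ancestor mass; term sets
are combined by best-match averaging, the standard symmetric
combination. The gene-wise mean is taken over genes annotated by
**both** sets (a union-based variant is available); with no shared gene
the semantic index is reported missing rather than zero, since absence
of evidence is not dissimilarity.

**Co-expression validation.** For a term's gene set, all within-term
Pearson correlations over the expression profiles are compared to
correlations of random gene pairs by a one-sided two-sample KS test
("observed stochastically greater"); the draw is repeated 100 times and
the mean p is the term's p-value. Zero-variance genes are excluded from
both sides. The null draw uses `max(100, n_pairs)` random pairs rather
than exactly `n_pairs`: the one-sided KS p is discrete in steps of 1/n,
and at the pair counts of typical terms (28 pairs for an 8-gene term)
an equal-n null is measurably conservative (≈1.7–2.8% rejections at the
nominal 5%), while the larger null restores the nominal level (≈3.5%,
within the calibration band the tests enforce). Pearson correlations
are computed on the raw FPKM scale by default, with a log2(x+1) option;
the raw default mirrors the plain description of the procedure.

# The synthetic world

`generateWorld()` builds the study system the tests run on: species
ordered by divergence from a reference, planted collinear blocks of
ortholog families, alignment anchors spread across each block, homology
hits for true orthologs plus borderline decoy paralogs, a layered
GO-like DAG, per-species annotations over families, and an expression
matrix with planted co-expressed term modules.

Design choices worth knowing:

* **One chromosome per block.** Planted blocks sit on their own
  chromosomes (plus one filler chromosome of species-specific genes).
  Two adjacent blocks on one chromosome would chain together at zero
  gap, making "detected = planted" false for structural reasons rather
  than detector defects; the per-chromosome layout makes noise-free
  worlds exactly identifiable, which is the property the tests lean on.
* **Ordinal divergence.** Gene dropout scales linearly with the
  divergence rank, and non-conserved anchors survive only in
  divergence-ordered prefixes — an ordinal caricature of alignability
  decay, with no sequence-level evolution (the pipeline consumes
  markers, not substitutions).
* **Flank anchors are always conserved.** The first and last anchor of
  each block stay in the all-species subset, so segment regions span
  the genes they are meant to support; without this, edge genes fail
  the 50% co-location condition for trivial geometric reasons.
* **Decoys.** Decoy hits link a reference gene to a *different* family
  in the same block at borderline E-values and low bitscores: they pass
  the two essential conditions (so they are accepted) but never win
  reciprocal-best-hit status, and therefore trail true orthologs in
  OPSS — the separation the score is designed to express.
* **Expression.** Planted modules share a latent factor per term
  (factor sd 1, residual sd 0.3, ten tissues, within-module r ≈ 0.9);
  modules are planted on terms with disjoint family sets so each gene
  follows one factor. Values are truncated at zero to stay FPKM-like;
  truncation at these means (5 ± ~1) is negligible.

What the worlds do **not** emulate: sequence evolution (indels,
substitutions), whole-genome duplication, tandem arrays, assembly
artefacts, and expression normalisation effects. Passing tests on these
worlds certify the algorithms' correctness under their stated models —
recovery of planted structure, calibration of the statistics — not
performance on any real genome.

# Problem sizes and numerical choices

The default world (5 species, 200 genes each, 7 blocks) runs the full
pipeline in a few seconds; the test suite uses 100-seed sweeps for
detector-oracle equivalence (40 markers per genome) and planted-block
recovery, 50 seeds for orthology precision/recall, 200 random DAGs
(≤ 30 terms) for the Wang oracle, and 400 seeded draws for the
co-expression calibration band. Tie-breaks are deterministic
throughout: chains sort by reference position, best hits break ties by
E-value then identifier, and every stochastic routine takes an explicit
seed (the pipeline derives per-term seeds from its root seed), so a
fixed seed reproduces every output checksum-identically.

Known limitations: the binomial chain statistic is an approximation to
an unspecified cluster-significance model and is documented as such, not
as a clone of any particular tool; M/P scores use the maximum supporting
level (a sum variant is a one-line change but intentionally not
offered); and with only two species no n-way level exists, so every OPP
there scores at most 2 + 0.5·2 + 2.
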