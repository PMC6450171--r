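---
title: "Methods: fungal-bacterial rhizobiome network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fungal-bacterial rhizobiome network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

# Scope and data model

rhizonet analyses joint fungal-bacterial OTU count tables from trap-plant
bioassays: plant cuttings rooted in test soils act as bait for compatible
root-associated microbes, and amplicon sequencing of the washed roots
(ITS for fungi, 16S for bacteria, with 28S/18S as auxiliary markers)
yields one OTU-by-sample count matrix per marker. Two designs are
covered: several host genotypes replicated in a common pair of soils
(does the plant genotype shape the rhizobiome?), and a single genotype
replicated across many soils (how much does soil origin explain?).
Uninoculated control plants grown in sterilised sand guard against
methodological artifacts.

The package works at the processed-table stage. Read-level processing
(denoising, OTU clustering, chimera removal, taxonomy assignment) is out
of scope; tables, taxonomy and metadata enter as plain TSV. Because the
analyses pool fungi and bacteria into joint networks, fungal/bacterial
identity is carried by a per-OTU domain tag in the taxonomy table, not by
the amplicon marker.

Tables are dense matrices: the designs here are at most a few hundred
OTUs by a few dozen samples, so sparse kernels would buy nothing.

# Normalisation

All multivariate analyses run on Hellinger-transformed abundances:
`sqrt(x / colsum)`, giving every sample unit Euclidean norm. This keeps
Euclidean-geometry methods (correlation, ordination) ecologically
meaningful for closed compositional counts. All-zero samples (failed
libraries) transform to all-zero rather than NaN, so they stay
representable; downstream similarity functions flag them instead of
propagating missingness. Rank-abundance summaries break ties by OTU id
so output ordering is deterministic, and rarefaction uses the analytic
hypergeometric expectation `E[S(d)]` (checked against Monte-Carlo
subsampling in the tests) rather than random subsampling, making the
result a checkable closed form.

# Sample-similarity trees and enrichment hypergraphs

Sample similarity uses two metrics: Pearson correlation and proportional
similarity `PS(p, q) = sum_i min(p_i, q_i)`. Both are summarised as a
maximum spanning tree via the distance `1 - s`, computed with Kruskal's
algorithm; ties are broken by lexicographic edge label so trees are
bit-reproducible across platforms. Constant vectors get `r = 0` (with a
warning) rather than NaN — conservative, and it keeps the tree connected.

Enrichment hypergraphs connect an OTU to a sample (or to a
soil-by-genotype bin) when its reads are over-represented there by a
one-sided Fisher exact test at fixed margins, after Benjamini-Hochberg
FDR control at 0.01. The 2x2 layout partitions the grand read total:
reads of the OTU in the unit / elsewhere vs reads of all other OTUs in
the unit / elsewhere. The test runs on raw integer counts — exact tests
are only valid on integers — and any zero margin returns p = 1 by
convention. Each analysed matrix forms one FDR family: control samples
are a separate family from treatment samples, and in binned mode each
soil is corrected independently. The genotype-specificity quotient of an
OTU is its enrichment-network degree divided by the number of distinct
genotypes its enriched samples span; OTUs enriched in at most 2
genotypes with quotient at least 2 are called genotype-specific.

# Co-occurrence communities

The correlation network drops OTUs observed in fewer than 3 samples,
computes Pearson correlations between all remaining OTU pairs across all
samples of a design, and keeps edges with `|r| >= 0.6`. MCL (Markov
Cluster algorithm) is implemented from scratch: unit self-loops, column
normalisation, then alternating expansion (matrix squaring) and
inflation (elementwise power 2.5 with renormalisation), pruning entries
below 1e-6, until the maximum column change drops below 1e-8 or 200
iterations. MCL needs a non-negative stochastic matrix, so it runs on
`|r|`; the correlation sign is kept as edge metadata only. Attractor
rows of the limit matrix seed the clusters; each node joins the
attractor holding most of its column mass, ties to the lowest label, so
the partition is deterministic. Only the inflation value is a
study-level parameter; self-loop weight, pruning and convergence
thresholds are implementation defaults, exposed as arguments.

Node topology is reported as degree, local clustering coefficient,
topological coefficient (shared-neighbour redundancy: mean of
`J(n,m)/k(n)` over partners sharing a neighbour, `J` counting shared
neighbours plus 1 for adjacency) and unnormalised betweenness with even
splitting over equal-length shortest paths. Degree, clustering and
betweenness delegate to igraph; betweenness is verified against
exhaustive path enumeration in the tests. Communities are classified
mixed / fungal-only / bacterial-only from the taxonomy domain tags.

Soil properties are correlated pairwise across soils (network + MST) and
against every OTU profile at sample resolution — the soil's value is
broadcast to its samples, since OTU abundances vary per sample while
properties are constant within soil; a soil-mean alternative would
discard replicate-level abundance variation. Property-OTU edges at
`|r| >= 0.6` are annotated with the OTU's community, giving per-community
candidate environmental drivers.

# Differential abundance (FCROS)

Differential relative abundance between two sample classes uses the
fold-change rank-order statistic. Preprocessing follows the workflow's
conventions: OTUs present in fewer than 3 samples are dropped,
`log2(x + 1)` stabilises variance (the pseudocount is forced by zeros),
and quantile normalisation (mean-of-order-statistics reference, tie
spans averaged) removes between-replicate distributional noise. For each
of the `n_a * n_b` cross-class sample pairs, per-OTU log fold changes
are ranked within the pair (average ranks on ties) and normalised by
`m + 1`; the per-OTU average uses a 25%-per-tail trimmed mean, which is
the published statistic's robustification against single aberrant
replicates. The f-value is the standard normal CDF of the standardised
average rank, standardised by the median and MAD of the average-rank
distribution — a robust estimate of the null location and scale, so that
genuinely changed OTUs do not inflate it; the two-sided p-value is
`2 * min(f, 1 - f)`. Selection mirrors the study thresholds: over if
`p <= 0.05` and `f >= 0.9`, under if `p <= 0.05` and `f <= 0.1` (the
under cutoff is the symmetric reading of the over cutoff).

# Community statistics

Bray-Curtis dissimilarities (vegan) on the Hellinger table feed PCoA
(Gower double-centering, eigendecomposition; negative eigenvalues
reported, their axes dropped; each axis flipped so its largest loading
is positive, fixing the sign indeterminacy). PERMANOVA is one-way
(vegan's adonis2 with a seeded permutation stream); the designs test
factors separately, interactions are out of scope. PERMDISP computes
distances to group centroids in principal-coordinate space, subtracting
negative-axis contributions from squared distances, then a one-way F.
Its p-value permutes group labels and recomputes centroids and distances
in full each time: this is exact under exchangeability, whereas
permuting only the observed residual distances proved anticonservative
at these group sizes (measured type-I error 0.10-0.17 at nominal 0.05
with 4 samples per group). The observed distances and F agree with
vegan's betadisper to machine precision.

Indicator-species analysis scores each OTU against each soil group and
each union of up to `max_order` groups: specificity A is the summed mean
abundance over the union's member groups divided by the sum over all
groups (the IndVal convention for site-group combinations — under a
"mean over pooled samples" reading a union could never beat its best
member, and combination indicators could not exist), fidelity B is the
presence fraction in the target, and the statistic is `sqrt(A * B)`,
maximised over targets. Significance is by permutation of group labels
(the permuted statistic is also maximised over targets, so the
comparison is like for like), then BH FDR across OTUs. Group-size
correction is not applied; the statistic is invariant to global
rescaling of abundances. Chi-square tests on per-group OTU-detection
counts use the standard Pearson statistic without continuity correction.

# The synthetic-data generator

The generator emulates the processed-table stage of the two designs and
carries its own ground truth, so every stage of the workflow is testable
without any sequencing data. Its defaults are the soil-origin design:
8 soils x 4 replicate plants, 100 fungal + 200 bacterial OTUs, 5 planted
mixed fungal-bacterial communities of 8-15 OTUs, library sizes uniform
over 346-4065 reads per sample (the genotype design uses 68-1950), and
3 low-diversity control samples drawing from a disjoint pool of 12
control taxa.

The model is log-normal-latent + multinomial: each planted community `c`
has one factor per sample, `z[c,s] = alpha[c, soil(s)] + gamma +
noise(sd 0.5)`, where the soil shifts `alpha` have sd 2.0 (or are the
standardised value of a linked soil property, for the two
property-linked communities) and genotype shifts `gamma` (sd 0.8) are
drawn per soil-by-genotype cell, making the genotype effect
soil-conditional as in the study's findings. Member OTUs load on their
factor with positive loadings U(0.8, 1.2) — communities are co-abundant
groups, not contrast groups — on top of N(0, 1) baselines and N(0, 0.4)
per-cell noise; counts are multinomial at the drawn library size, which
induces the compositional coupling real tables have. Community soil
profiles are mutually orthogonalised so each planted community tracks
its own environmental axis; without that, two random 8-soil profiles
occasionally correlate strongly enough that the planted partition itself
becomes ill-defined as ground truth. Soil properties are correlated
Gaussians with deliberately collinear pairs (Ca~Mg, Ca~CEC, sand~clay)
mapped to realistic units.

Three planted signal sets complete the truth: 20 differential OTUs
shifted 4-fold (log2 fc = 2) in the second of two designated soil
classes, with mid-range baselines — a fold change on a taxon below the
detection limit of these library sizes is unmeasurable, and a shift
confined to the extreme top of the abundance distribution is absorbed by
quantile normalisation, so mid-range is where the question is
well-posed; 16 soil-specific indicator OTUs present at solid abundance
in exactly one soil and absent elsewhere, emulating the
presence-structured taxa (soil-restricted ectomycorrhizal fungi,
specific bacterial lineages) that indicator analysis is designed for;
and the control-taxa pool, which shares essentially no realized OTUs
with treatment samples.

What the generator does *not* emulate: sequencing error and chimeras,
PCR and primer bias, phylogenetic correlation among OTUs, zero-inflation
beyond what the multinomial induces, and negative (exclusion)
associations — planted communities are co-abundant only. Passing tests
therefore demonstrate that the machinery recovers the structure this
model plants at realistic depths and sample sizes, not that real 454
data would be equally well-behaved.

# Validation designs and problem sizes

The test-suite checks run at sizes chosen for a single CPU:

* exact-test and spanning-tree oracles: full enumeration over all 2x2
  tables with total <= 40, and all 1296 spanning trees of 100 random
  6-node instances;
* MCL: exact clique recovery, agreement with an independently written
  reference implementation on 50 two-block graphs, idempotence, and an
  inflation-granularity trend over 20 modular graphs;
* planted-structure recovery on the default soil-origin design
  (adjusted Rand index of the correlation + MCL pipeline against the
  planted partition, composition classes against the taxonomy);
* calibration: 1,000 null datasets (soil effects zeroed, so labels are
  exchangeable) at 199 permutations for PERMANOVA and PERMDISP; FCROS
  null mean f over 100 permuted-label datasets (m = 200, 8 vs 8);
  indicator FDR on null-background datasets with planted indicators;
* power: FCROS on the isolated two-class spike-in design (2 soils x 8
  replicates, m = 200, 20 planted 4-fold OTUs, no co-abundance
  communities) — in the soil-structured default the class split is
  confounded with genuine soil effects, so community OTUs are truly
  differential and a "false positive" is not defined there; indicator
  recovery on the default design, 999 permutations (permutation
  granularity: with 299 permutations the smallest attainable p-value
  already exceeds the BH threshold when ~5% of OTUs are true).

The numbered scripts under `analysis/` run the same machinery as a
narrative: simulate both designs, then ordination and PERMANOVA,
similarity trees, enrichment hypergraphs and the quotient rule,
MCL communities with topology and composition, soil-property maps,
FCROS, and indicator analysis, writing their tables under `results/`.

# Known limitations

One-way PERMANOVA only; no interaction designs. The enrichment
contingency layout is the standard reads-in-unit partition (the study's
supplementary definition is not restated in the text, so the layout is a
documented switch point rather than an asserted fact). Indicator
analysis uses the group-size-uncorrected IndVal variant. MCL is dense
(fine at these scales, quadratic memory beyond). PERMDISP uses
centroids, not spatial medians. The pipeline's permutation default (999)
is chosen for interactive turnaround; published-style runs should use
9999 as the drivers do for PERMANOVA.
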