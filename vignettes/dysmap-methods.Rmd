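---
title: "Methods: models, parameters and design choices in dysmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in dysmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dysmap` maps T cell dysfunction programs from three single-cell data
modalities — chromatin accessibility (scATAC-seq fragments), transcriptomes
(scRNA-seq counts) and paired-chain TCR repertoires — and carries the
chromatin-derived pro-apoptotic NF-κB signature into bulk survival cohorts.
This vignette records the models each stage implements, the parameters that
matter, and the choices made where the design was genuinely open.

## Fragment quality control

A fragment record is (chrom, start, end, barcode, duplicate count) with
0-based half-open coordinates; each fragment implies two Tn5 insertion
events, at `start` and `end - 1`. Unique fragments are counted one per
record: records are assumed deduplicated upstream, with the duplicate count
carried for diagnostics only.

The TSS enrichment score of a barcode is the mean insertion density per bp
within ±50 bp of any TSS divided by the mean density in the distal 100-bp
flank windows at ±2 kb, pooled over TSSs. The flank mean is floored at a
pseudocount (default 0.01 insertions/bp) so the ratio is finite for sparse
cells; the floor caps the score for very shallow barcodes rather than
letting noise produce unbounded ratios. TSS windows are pooled unoriented;
orientation-flipping by strand would only matter for asymmetric profiles,
which the score (a symmetric window ratio) cannot detect anyway.

Cells pass QC iff `n_unique_fragments >= 1000` **and**
`tss_enrichment >= 8`. Both thresholds are inclusive — the common tool
convention when a cut-off is quoted without strictness. Doublet exclusion
is accepted as an externally supplied barcode list; it is not computed
here.

## Iterative LSI clustering

Round one builds a genome-wide tile matrix (2.5-kb tiles, insertion
counts, then binarized), weights it by TF-IDF and reduces it by truncated
SVD. The TF-IDF variant is TF(i,j) = x~ij~ / colsum~j~ and
IDF(i) = log(1 + N~cells~ / n~cells~ with feature i); features observed in
no cell are dropped before the SVD. Of 25 computed components, components
2–25 are retained: the first component is strongly collinear with
sequencing depth in binarized accessibility data. Components are
sign-oriented so the largest-magnitude feature loading is positive, making
coordinates solver-independent; a dense SVD replaces the iterative solver
for small matrices, where it is exact.

Clustering runs Leiden modularity optimization on a shared-nearest-neighbor
graph (k = 20 Euclidean neighbors, edges reweighted by the Jaccard overlap
of self-inclusive neighbor sets, pruned below 1/15). Candidate resolutions
are tried in descending order from 0.8, and the first *admissible*
partition is reported. Admissibility requires (a) every cluster to hold at
least `min_size` cells (200 by default; 250 is the convention for T cell
sub-clustering) and (b) the partition to be reproduced exactly, up to label
permutation, by three independently seeded restarts. The stability
condition is this package's addition to the familiar min-size rule: on a
kNN graph of a *homogeneous* cell population, modularity optimization
happily carves arbitrary same-sized pieces that can each exceed `min_size`,
but those cuts land differently on every restart, whereas genuine
population structure is restart-stable. Without the condition, two
well-separated 500-cell populations are sometimes reported as three
clusters; with it, they are recovered exactly. If no resolution is
admissible, the candidate with the fewest undersized clusters is returned
with a `fallback` flag.

Between rounds, peaks are called per crude cluster by a documented Poisson
pseudobulk model: insertions are pooled per cluster, counted in 500-bp
windows sliding by 100 bp, tested against the cluster's genome-wide rate ×
window width (Poisson upper tail), BH-corrected (FDR 0.01), reduced to
fixed 500-bp peaks centered on the window's insertion summit, and
deduplicated by score-ranked iterative overlap removal. The union peak set
applies the same removal across clusters. An externally supplied BED
bypasses the caller entirely. Round two re-runs TF-IDF/SVD/clustering on
the **binarized** peak matrix — binarization mirrors the tile round;
insertion counts are also retained for the motif stage, which needs them.

## Gene activity

A position's weight for a gene is 1 inside the extended gene body (TSS
extended 5 kb upstream, through the TTS, strand-resolved), exp(−d/τ)
outside with τ = 5,000 bp, and 0 beyond 100 kb. τ was set to the upstream
extension scale — the decay form and extension are fixed, the constant is
exposed in the API. A contribution is zeroed if the position lies inside
another gene's extended body or beyond the midpoint between two extended
bodies, a simple symmetric reading of neighbor-boundary filtering. Per-cell
scores are depth-normalized to 10⁴ and log1p-transformed so they behave
like expression values downstream; raw sums are kept in an attribute.
Gene-length scaling is deliberately omitted (flag-gated in some tools,
unspecified here).

Differential accessibility per cluster uses two-sided Wilcoxon rank-sum
tests versus all other cells, log2 fold changes of pseudocount-shifted
means, and BH correction within each cluster; markers pass at LFC ≥ 1 and
FDR ≤ 0.05.

## Motif deviations

For motif m and cell i, X is the cell's insertion count in matched peaks
and E = f~m~·T~i~ its expectation under the null that motif peaks take
their dataset-wide share f~m~ of each cell's total T~i~; the raw deviation
is (X − E)/E, which sums (over cells, count-weighted) to zero by
construction. Bias correction compares against 50 background peak sets
matched on GC content and mean accessibility: peaks are embedded in the
standardized (log mean accessibility, GC) plane, gridded into 50 bins per
axis, and backgrounds are sampled with Gaussian-kernel weights (bandwidth
0.25 standardized units) over bin centers, self-sampling allowed. The
z-score is (Y − mean~b~ Y~b~)/sd~b~ Y~b~ and a motif's variability is the
standard deviation of its z across cells. Degenerate cases are masked, not
imputed: motifs with zero expected counts and cells with zero background
spread give NA with a warning. PWM matching scans log-odds scores against a
uniform 0-order background; the match threshold is the score whose exact
upper-tail probability (computed by discretized convolution at 0.01-bit
resolution) equals the requested p-value (default 5e-5), and a precomputed
match matrix is accepted verbatim.

## Supervised pseudotime

Pseudotime is deliberately supervised: the dysfunction progression's
cluster order is an input, not an inference. Cells of backbone cluster j
are projected onto the unit vector from centroid j toward centroid j+1
(the last cluster projects away from its predecessor), converted to a
within-cluster rank fraction r ∈ [0, 1), and assigned
100·(j − 1 + r)/K. Ranks rather than raw projections make the scale
noise-robust and give each cluster an equal pseudotime span; ties break by
input order, keeping the map deterministic. The construction is invariant
to rigid motions of the embedding. Profiles over pseudotime use 100
quantile bins (≈ equal occupancy), an 11-bin centered moving average
(truncated at the edges; empty bins filled by linear interpolation and
flagged), and per-feature z-scoring for display; the top 10% most variable
smoothed profiles are ordered by the bin of their maximum.

## Expression modules

QC applies the strict filter nFeature > 500 & nFeature < 5000 &
percent.mito < 0.25 & nCount < 50000 (mitochondrial genes identified by the
"MT-" prefix), removes cells with more than one productive chain of the
same TCR locus, and defines the T cell subset as cells with at least one
productive β chain. Clustering reuses the SNN machinery on 25 principal
components of the scaled top-2000 variable genes.

Module detection follows the signed weighted co-expression recipe with the
stated parameters: biweight midcorrelation (9-MAD outlier cut-off, Pearson
fallback for constant-MAD genes), signed adjacency ((1 + bicor)/2)^10,
topological overlap similarity, average-linkage clustering of 1 − TOM, and
eigengene merging at correlation ≥ 1 − 0.15. The adaptive dynamic branch
cut is replaced by a fixed-height cut at 0.95 with min-module-size 10
enforcement: at power 10, within-module TOM distances fall well below 0.95
for correlated modules (r ≈ 0.6 gives ≈ 0.89) while independent genes sit
above 0.99, so the fixed cut separates the regimes; the recovery tests
validate this stand-in. The module eigengene is the first principal
component of the module's standardized expression, sign-aligned with the
module mean.

Dysfunction-module readout: each module gene's per-cluster mean expression
(cluster mean of log-normalized values — mean, not median, as the
unspecified default) is z-scored across clusters with sample sd, so rows
have mean 0 and sd 1 exactly; constant genes are masked. Cluster
distributions of these z-scores are compared by one-way ANOVA with
Holm–Šidák step-down adjusted pairwise contrasts
(adj~(i)~ = running max of 1 − (1 − p~(i)~)^(m − i + 1)).

## Clonality indices

A clonotype is the six-field key (Vα, Jα, CDR3α-nt, Vβ, Jβ, CDR3β-nt) of a
cell with exactly one productive α and one productive β chain. All
entropies are natural-log (nats); the base only rescales the indices.
Expansion: expa = 1 − H/log N~c~ over the cluster's clone-size
distribution, defined as 1 for a monoclonal cluster and reaching 0 when
all clones are singletons. Migration and transition entropies are computed
per clonotype over its dataset-wide tissue or cluster distribution — an
index should reflect a clone's global behavior, not the slice visible in
one cluster — and aggregated per cluster by cell weighting n~k~/n (clone
weighting is the obvious alternative; cell weighting matches the
cell-centric cluster summaries used elsewhere in the pipeline).

## Label transfer

Gene activity scores stand in for expression on the chromatin side. Shared
genes are restricted to the top-variable expression genes, standardized
per modality, and canonical correlation directions are taken from the SVD
of the cross-modality product; cells are L2-normalized in canonical space.
Anchors are mutual nearest neighbor pairs (k = 5), scored by the overlap
of the two cells' 50-nearest chromatin neighborhoods in feature space.
Each chromatin cell then averages the one-hot labels of its 50 nearest
anchors with Gaussian kernel weights (bandwidth = mean distance to the
k-th anchor) multiplied by anchor scores, renormalized to the simplex.
This kernel vote is a documented simplification of the published anchor
weighting; the contract — simplex scores, confident iff max score > 0.5 —
is preserved and validated by recovery tests on paired-noise fixtures.

## Signature survival

The five-gene score is the mean of per-gene z-scores across exactly the
analyzed samples (z-scoring precedes nothing else; samples excluded from
survival analysis never contribute to the standardization). The median
split is inclusive — high ⇔ score ≥ median — matching the printed
convention, with the even-n median at the standard midpoint. Kaplan–Meier
estimation and the two-group log-rank test delegate to the survival
package (product-limit estimator; χ² on 1 df with the hypergeometric
variance, p from the upper chi-squared tail, reported at full precision).
Stage comparisons use Kruskal–Wallis globally and pairwise two-sided
Wilcoxon rank-sum tests with Holm–Šidák adjustment.

## Synthetic data: what it emulates, and what it does not

The generators define the test conditions for the whole package:

- `simulate_fragments`: good cells draw 45% of fragments from their type's
  accessible peaks, 40% near TSSs (Normal, sd 25 bp) and 15% uniform
  background; low-quality cells are uniform background at half depth.
  Fragment lengths mix a shifted exponential (min 30 bp, mean 80 bp,
  weight 0.6) with Normal(200, 30) (weight 0.4), giving the bimodal
  sub-/mono-nucleosomal size profile. Output is coordinate-sorted,
  bgzipped, byte-stable for a fixed seed.
- `simulate_expression`: negative-binomial counts with dispersion 0.5,
  per-type markers, Beta-distributed mitochondrial fractions, and a
  75-gene module whose means rise as 2^(loading·t) along a latent
  pseudotime t ∈ [0, 1].
- `simulate_tcr`: geometric clone-size laws per cluster, optional forced
  cross-cluster clone sharing, arbitrary unique CDR3 tokens.
- `simulate_cohort`: five signature genes loaded (0.8) on one latent
  factor; exponential survival with the hazard multiplied for the
  high-score half; independent exponential censoring calibrated to the
  requested censoring fraction; a stage label optionally correlated with
  the factor.

These fixtures deliberately omit batch effects, doublets, realistic
sequence content, chromatin co-accessibility structure and
expression-chromatin coupling beyond shared type profiles. Passing
recovery tests therefore demonstrates the *mechanics* — that each
estimator recovers the structure it models when that structure is present
— not robustness to every artifact of real libraries.

## Problem sizes and determinism

The validation suite runs at desk scale, chosen to exercise every code
path with clear signal: a 1-Mb single-chromosome genome with 60 genes,
four 500-cell populations at 3,000 fragments/cell for clustering recovery
(ARI 1.0 in the shipped runs), 300 cells at 5,000 fragments/cell for the
QC mixture, 500-cell/200-peak matrices for motif calibration, 1,000 null
and 200 alternative cohort replicates for log-rank calibration and power.
Every stochastic function takes an explicit seed and restores the caller's
RNG state, so all results — including the bgzipped fragment files — are
bit-reproducible.

## Known limitations

The peak caller is a calibrated stand-in, not a reimplementation of any
published caller; absolute peak sets will differ even where clusters
match. The fixed-height module cut can fragment modules with very
heterogeneous within-module correlation. The transfer scoring simplifies
the published anchor weighting. Clonality indices use declared entropy
stand-ins validated by their edge-case identities rather than any
reference implementation. Cross-patient batch integration is out of scope
throughout.
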