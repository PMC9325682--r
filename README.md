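# dysmap

Single-cell chromatin, transcriptome and TCR mapping of T cell dysfunction.

Tumor-infiltrating CD8+ T cells progress toward a dysfunctional (exhausted)
state with a distinctive chromatin landscape, transcriptional program and
clonal structure. `dysmap` implements, as composable R functions, the full
analysis stack needed to map that progression from raw single-cell data:

- **ATAC fragment QC** — per-barcode unique-fragment counts and TSS
  enrichment scores; cells are retained iff they have ≥ 1,000 unique
  fragments *and* a TSS enrichment score ≥ 8.
- **Iterative LSI clustering** — a binarized 2.5-kb tile matrix is
  TF-IDF-weighted (TF = x<sub>ij</sub>/colsum<sub>j</sub>,
  IDF = log(1 + N/n<sub>i</sub>)), reduced by truncated SVD (components
  2–25), and clustered on a shared-nearest-neighbor graph with Leiden
  modularity, selecting the largest resolution whose clusters all hold
  ≥ 200 cells and are restart-stable. Pseudobulk peaks (fixed 500-bp,
  Poisson test, BH-corrected, iterative overlap removal) from the crude
  clusters feed an identical second round on the peak matrix.
- **Gene activity scores** — per-insertion weights: 1 inside the extended
  gene body (TSS − 5 kb through the TTS), exp(−d/5000) outside, truncated
  at 100 kb, zeroed past the midpoint to a neighboring gene; depth
  normalized to 10<sup>4</sup> and log1p-transformed.
- **Motif deviations** — raw deviation Y = (X − E)/E with
  E = f<sub>m</sub>·T<sub>i</sub>, z-scored against 50 GC- and
  accessibility-matched background peak sets; per-motif variability.
- **Supervised pseudotime** — cells of an ordered cluster backbone are
  projected toward the next centroid and ranked; pseudotime spans [0, 100];
  smoothed feature profiles order the top 10% most variable features.
- **scRNA modules** — strict QC (nFeature > 500 & < 5000, mito < 0.25,
  nCount < 50000, multi-chain TCR removal), clustering, top-5 markers, and
  signed co-expression modules: bicor, adjacency ((1 + r)/2)^10,
  topological overlap, average-linkage cut, minModuleSize 10, eigengene
  merge at correlation ≥ 0.85.
- **TCR clonality** — paired-chain clonotypes (Vα, Jα, CDR3α, Vβ, Jβ,
  CDR3β) and entropy-based indices: expansion
  expa = 1 − H/log N<sub>c</sub>, migration and transition entropies in
  nats, clone-frequency ranges, cross-compartment sharing.
- **Label transfer** — CCA anchors between gene-score and expression
  matrices; kernel-weighted one-hot votes give simplex prediction scores;
  cells with max score > 0.5 are high-confidence.
- **Signature survival** — the five-gene pro-apoptotic NF-κB signature
  (FAS, FASLG, TNFSF10, TRAF1, TRAF2): mean per-gene z-score, median split
  (high ⇔ score ≥ median), Kaplan–Meier curves, log-rank χ² on 1 df,
  Kruskal–Wallis/Wilcoxon stage comparisons.

A synthetic-data generator (`make_genome`, `simulate_fragments`,
`simulate_expression`, `simulate_tcr`, `simulate_cohort`) emits every input
format the pipeline consumes — bgzipped fragment files, MTX count triplets,
contig CSVs, survival TSVs — with recorded ground truth, so every stage is
testable end to end without external data.

## Worked example

```r
library(dysmap)

gn  <- make_genome(n_chrom = 1, chrom_len = 1e6, n_genes = 60, seed = 3)
pp  <- make_peak_plan(gn, paste0("T", 1:4), n_shared = 80, n_specific = 25, seed = 2)
sim <- simulate_fragments(gn,
         data.frame(cell_type = paste0("T", 1:4), n_cells = 500, depth = 3000),
         pp, quality_mix = 0, seed = 11)
fr  <- read_fragments(sim$path)

qc   <- fragments_qc(fr, gn)             # 1,000-fragment / TSS-8 filter
keep <- filter_cells(qc)
res  <- iterative_cluster(fr[fr$barcode %in% keep, ], gn,
                          min_size = 200, seed = 5)
res$clusters
#> cluster_assignment: 2000 cells, 4 clusters at resolution 0.8
#>   C1   C2   C3   C4
#>  500  500  500  500
table(sim$truth$cell_type[match(names(res$clusters$cluster),
                                sim$truth$barcode)],
      res$clusters$cluster)
#>       C1  C2  C3  C4
#>   T1 500   0   0   0
#>   T2   0 500   0   0
#>   T3   0   0 500   0
#>   T4   0   0   0 500
```

The four simulated cell populations are recovered exactly (adjusted Rand
index 1.0): round one clusters on genome-wide tiles, peaks are called per
crude cluster and merged (235 union peaks here), and round two re-clusters
on the binarized peak matrix at the selected resolution 0.8.

On the survival side:

```r
cohort <- simulate_cohort(300, hazard_ratio = 3, seed = 5)
signature_survival(cohort)
#> signature_result: 300 samples; 150 high / 150 low
#> log-rank chi-squared = 67.1 on 1 df, p = 2.64e-16
round(chisq_pvalue(6.6), 2)   # 0.01 — p-value for a published chi-squared
```

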