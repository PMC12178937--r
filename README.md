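# regioglia

Regional stress-response analysis of single-cell RNA-seq data.

## What this is for

Paired tissue samples from two regions (labelled `macula` and
`periphery`) are profiled under a control and a stress condition across
several donors, giving four groups (`CM`, `LM`, `CP`, `LP`). regioglia
quantifies *which cell types respond, in which region, and how strongly*:

* **Alteration Score** per cell type *j* over its signature genes *i*:

  `ACscore(j) = Σ_i log2( FC_exp(i) · FC_prop(i) + 1 )`

  where `FC_exp` is the stress/control ratio of mean normalized
  expression and `FC_prop` the stress/control ratio of the detecting-cell
  fraction, both within type *j*. An unchanged gene contributes exactly
  1, so the no-change baseline equals the signature size.
* **Stress-associated relative likelihood** per cell: condition densities
  are smoothed over the transcriptomic kNN graph (k = 7) with the heat
  kernel `exp(-β · L_rw)` (β = 67, random-walk Laplacian), combined per
  donor as `ℓ = d_stress / (d_stress + d_control)` and averaged across
  donors; cells are classified non-changed (ℓ < 0.4), slightly-changed
  (0.4 ≤ ℓ ≤ 0.6) or highly-changed (ℓ > 0.6).
* **Regional differential expression**: Wilcoxon rank-sum DE
  (min.pct 0.2, log2FC threshold 0.2, BH adjustment; exact enumeration
  for groups ≤ 8 cells), `m-HX`/`p-HX` categories (linear FC > 1.5,
  adj. p < 0.05), light-induced up/down flags (|FC − 1| > 0.09), top-k
  lists, Venn region counts, marker-normalized ratios.
* **QC and doublets**: feature-count bounds (200/6000),
  mitochondrial (15 %) and hemoglobin (5 %) ratio filters with inclusive
  boundaries, and artificial-doublet detection (pN 0.25, pK 0.09,
  20 PCs).
* **Synthetic data with ground truth**: a negative-binomial generator
  with donors, region-specific cell-type composition, marker programs,
  planted stress programs and injected doublets stands in for the
  undeposited source data and powers the whole test suite.

## Worked example

Simulate a four-donor study (2,000 cells × 800 genes) with a stress
program planted only in peripheral Müller glia (MG), then score MG in
each region:

```r
library(regioglia)

cfg <- generator_config(
  n_genes = 800, n_cells_per_group = 500,
  stress_programs = data.frame(type = "MG", region = "periphery",
                               n_genes = 50L, fold = 2),
  seed = 42)
sim <- generate_study(cfg)
sim$study
#> expression_study: 2000 cells x 800 genes
#> groups: CM=500 CP=500 LM=500 LP=500

norm <- normalize_log1p(sim$study)
sigs <- select_signature_genes(norm, sim$study$cell_meta, types = "MG")
m <- sim$study$cell_meta
for (rg in c("periphery", "macula")) {
  sel <- which(m$region == rg)
  fc <- compute_fold_changes(norm[sel, ], sim$study$counts[sel, ],
                             m[sel, ], sigs)
  print(cbind(region = rg, alteration_score(fc)))
}
#>      region type n_genes    score score_per_gene
#> 1 periphery   MG      19 25.38756       1.336188
#>   region type n_genes    score score_per_gene
#> 1 macula   MG      19 18.49316      0.9733243
```

The 19-gene MG signature scores 25.4 in the periphery, where the program
was planted, versus 18.5 in the untouched macula — the no-change
baseline for a 19-gene signature is 19, so peripheral MG sits clearly
above it (per-gene 1.34) and macular MG at it (0.97). The per-cell
likelihood layer follows the same API:

```r
emb <- pca_embedding(norm, select_hvg(norm, 400), 20)
graph <- build_knn_graph(emb, k = 7)
res <- relative_likelihood(graph, m, beta = 67)
cats <- classify_likelihood(res)          # 0.4 / 0.6 cutoffs
summarize_by_celltype(res, cats, m)
```

With a diffuse fold-change program at this desk scale the heat kernel
smooths likelihoods close to 0.5 (no cell crosses the 0.6 line); the
test suite demonstrates the sharp case — a stress-only subpopulation
reaches mean ℓ = 1.0 while unaffected types stay near 0.5.

A full run (simulate → QC → doublets → HVG → pseudobulk correlation →
ACscore → likelihood → DEG), writing CSV/JSON outputs and a run report:

```r
report <- run_pipeline(run_config(
  generator = list(n_genes = 800, n_cells_per_group = 500),
  qc = list(min_features = 30),     # desk-scale gene count
  hvg = list(n = 400),
  seed = 1, out = "out/"))
```

or from the shell: `exec/regioglia run-all --seed 1 --out out/`.

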