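# trtniche

Multi-omic analysis of the tumor-reactive CD8+ T cell niche in liver
metastasis of colorectal cancer, as a reusable and tested R pipeline.

Tumor-reactive CD8+ T cells accumulate in liver metastases yet remain
dysfunctional there. The computational case for that claim rests on five
analyses that `trtniche` implements end to end, each exercisable on a
synthetic cohort with planted ground truth:

- **pTRT classification** (`ssgsea_cell_scores()`, `classify_ptrt()`):
  per-cell single-sample gene-set enrichment over ~100 tumor-reactivity
  signatures. For a cell with $N$ ranked genes and set $S$, the score is
  the running-sum integral
  $ES = \sum_i [P_{hit}(i) - P_{miss}(i)]$ with hit weights
  $(N - r_i + 1)^\alpha$; a CD8+ T cell is potentially tumor-reactive
  (pTRT) when its z-normalized score reaches $z \ge 2$ in $\ge 10\%$ of
  signatures. A 500-gene random control (`random_control_sets()`) guards
  against artifacts.
- **Cell–cell communication** (`permutation_pvalues()`,
  `differential_network()`): law-of-mass-action strengths
  $P = LR/(K_h + LR)$ from trimean group summaries (frequency-normalized
  by construction), label-permutation p-values, and differential
  liver-metastasis vs primary-tumor networks with pathway contributions
  (SPP1 → CD44 and FN1 → integrin axes).
- **Macrophage trajectory** (`build_cell_graph()`,
  `compute_pseudotime()`, `morans_i()`, `subcluster_branch()`): diffusion
  pseudotime over a kNN graph, Moran's I
  $I = \frac{n}{W}\frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
  {\sum_i (x_i-\bar x)^2}$ gene ranking, and the KC → IC → SPP1
  subclustering that isolates an intermediate macrophage state
  co-expressing SPP1, TGFBR1, IL6R, CSF1R, VSIG4 and CD163.
- **Spatial proximity** (`threshold_phenotypes()`, `assign_regions()`,
  `proximity_summary()`): threshold phenotyping of segmented
  multiplexed-imaging cells, αSMA+ region assignment, exact
  nearest-neighbor distances, the 100 µm proximity rule, and paired
  αSMA+/− t-tests with NK/Treg negative controls.
- **Cross-compartment correlation** (`pseudobulk_mean()`,
  `cross_compartment_correlation()`): per-patient pseudobulk linking
  primary-tumor TGFB1/IL6/TLR2/TLR4 to metastatic FN1 and macrophage SPP1
  by simple linear regression.

The synthetic-data module (`cohort_config()`, `make_cohort()`,
`make_macrophage_continuum()`, `make_spatial_cohort()`) defines the study
conditions — 10 patients, six paired tissue compartments (MT, MN, PT, PN,
PBMC, LN), negative-binomial counts — and plants every effect the stages
above are meant to recover, with truth labels for testing.
`run_pipeline()` orchestrates all stages under one seed and writes a
deterministic report.

## Worked example

Simulate a cohort, classify pTRT cells, and compare IC-state frequencies
between liver and colon:

```r
library(trtniche)
library(dplyr)

cfg <- cohort_config(seed = 7, n_patients = 6, cells_per_tissue = 200,
                     n_genes = 600)
cohort <- make_cohort(cfg)
sigs <- make_signature_collection(cfg)

ann <- cohort$annotation
cd8 <- ann$cell_id[ann$coarse_type == "CD8T"]
expr_cd8 <- normalize_expression(subset_expression(cohort$expr, cells = cd8))
ptrt_sigs <- gene_set_collection(sigs$sets[grepl("^ptrt_sig_", names(sigs$sets))])

scores <- normalize_scores(ssgsea_cell_scores(expr_cd8, ptrt_sigs))
calls <- classify_ptrt(scores, ann)
summarize_ptrt_frequency(tissue_ptrt_frequency(calls, ann))
#> # A tibble: 6 × 3
#>   tissue mean_frequency n_patients
#>   <chr>           <dbl>      <int>
#> 1 MT             0.0979          6
#> 2 LN             0.0688          6
#> 3 PT             0.0208          6
#> 4 MN             0.0208          6
#> 5 PN             0.0125          6
#> 6 PBMC           0.0104          6
```

The metastatic liver (MT) carries the highest fraction of tumor-reactive
CD8+ T cells, followed by the draining lymph node — the frequency ordering
the classification stage is built to expose. The IC macrophage state is
liver-enriched:

```r
icf <- ic_coexpression_frequency(cohort$expr, ann)
glance(icf)
#> # A tibble: 1 × 5
#>   comparison     n_pairs mean_diff statistic p_value
#>   <chr>            <int>     <dbl>     <dbl>   <dbl>
#> 1 liver vs colon       6    0.0944      4.74 0.00514
```

Per patient, 9.4 percentage points more liver macrophages/monocytes
co-express the six IC markers than colon ones (paired t-test, p = 0.005).
Each result type has an `autoplot()` method (frequencies, Moran tables,
correlations, proximity summaries) and fitted objects support
`tidy()`/`glance()`.

The full pipeline runs from one config:

```r
report <- run_pipeline(default_pipeline_config(seed = 1, outdir = "out"))
write_report(report, "out/report.json")
```

A thin command-line wrapper lives at `inst/cli/trtniche.R`
(`Rscript inst/cli/trtniche.R run --config cfg.yaml`).

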