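---
title: "Models and methods behind trtniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trtniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trtniche)
library(dplyr)
```

# The scientific question

In colorectal cancer with liver metastasis, tumor-reactive CD8+ T cells
accumulate in the metastatic liver yet fail to control the tumor. `trtniche`
packages the computational side of that observation into a tested pipeline
with five analytical stages plus a fully specified synthetic cohort:

1. **pTRT classification** — per-cell ssGSEA over a large panel of
   tumor-reactivity signatures, a stringent multi-signature cutoff, and a
   random-gene negative control.
2. **Ligand–receptor communication** — law-of-mass-action interaction
   strengths between annotated cell groups with permutation significance,
   and a differential network between conditions (liver metastasis vs
   primary tumor).
3. **Macrophage trajectory** — diffusion pseudotime over a kNN cell graph,
   Moran's I gene ranking, and a three-way subclustering that isolates an
   intermediate (IC) macrophage state between Kupffer-cell (KC) and SPP1+
   states.
4. **Spatial proximity** — region-stratified nearest-neighbor statistics on
   segmented multiplexed-imaging cells (αSMA+ fibrotic regions vs
   background, 100 µm rule, paired t-tests).
5. **Cross-compartment correlation** — per-patient pseudobulk linking
   primary-tumor cytokines (TGFB1, IL6, TLR2, TLR4) to metastatic FN1 and
   macrophage SPP1 by simple linear regression.

Every stage has a planted analog in the synthetic cohort, so each claim the
pipeline can make is backed by a recovery test against known truth and a
type-I-error test against a matched null.

# Per-cell enrichment scores and the pTRT call

For one cell with $N$ measured genes ranked by decreasing expression, a set
$S$ with $|S| = m$, and hit weight $w_i = (N - r_i + 1)^\alpha$ (average
ranks $r_i$ for ties; positions take a deterministic lexicographic
tiebreak), the enrichment score is the full running-sum integral

$$ES = \sum_{i=1}^{N}\left[\frac{\sum_{j \le i,\, j \in S} w_j}
{\sum_{j \in S} w_j} - \frac{\#\{j \le i,\, j \notin S\}}{N - m}\right].$$

The score is rank-based, so any monotone per-cell transform (library-size
scaling included) leaves it unchanged. `alpha = 0.25` is the default
weighting; `alpha = 0` is exposed because it admits closed forms used in
the tests ($ES = \pm N/2$ for a single top/bottom gene). The implementation
is a vectorized closed form over hit positions; the test suite verifies it
against a literal position-by-position running sum to $10^{-9}$.

Scores are z-normalized per signature across cells (population SD), and a
CD8+ T cell is called **pTRT** when $z \ge 2$ in at least 10% of the
signatures. There is no canonical value for either knob in this family of
analyses, so both are explicit arguments (`cutoff_z`, `min_sets`); the
defaults are this package's choice and all recovery results are reported
under them. Cells with zero library size are excluded
from scoring; signature genes missing from the matrix are dropped with a
warning; a signature with no measured genes scores `NA`.

The negative control follows the standard design: 500 genes drawn
uniformly from the measured universe, scored identically, and compared
across tissues by one-way ANOVA on patient-by-tissue means.

# Communication strengths

Group expression is summarized by Tukey's trimean
$(Q_1 + 2Q_2 + Q_3)/4$ with linear-interpolation (type 7) quantiles —
a per-group statistic, so duplicating a group's cells (changing its
frequency) leaves strengths unchanged up to quantile interpolation. This is
the frequency normalization the communication model requires. Multi-subunit
ligands and receptors are summarized by the geometric mean, so one absent
subunit nullifies the obligate complex. The interaction strength is the
Hill form

$$P = \frac{L \cdot R}{K_h + L \cdot R}, \qquad K_h = 0.5$$

on the log-normalized scale. Significance comes from permuting group labels
among cells: $p = (1 + \#\{P_{perm} \ge P_{obs}\})/(1 + n_{perm})$ with
$n_{perm} = 100$ by default, which makes the smallest attainable p-value
$1/101$ and the estimator conservative (never anti-conservative) under the
null — the calibration test checks this with a one-sided KS statistic on
pooled null p-values. The differential network counts significant edges and
sums their strengths per sender–receiver pair, condition A minus condition
B; pathway contributions aggregate edge-level differences.

# Trajectory analysis

The cell graph is a union-symmetrized kNN graph ($k = 15$) on the top 20
principal components of the log-normalized matrix. Union symmetrization
(an edge exists if either endpoint lists the other) was chosen over mutual
kNN because the pseudotime contract requires the root component to span
nearly all cells, and mutual kNN routinely fragments noisy data. Ties in
the neighbor search break lexicographically by cell id, so duplicated
profiles yield reproducible graphs.

Pseudotime is the diffusion distance to the root in a 10-component
diffusion map of the symmetrically normalized graph, with the
accumulated-transition scaling $\lambda_k/(1-\lambda_k)$ on the
eigenvectors. That scaling matters: trajectory modes sit near
$\lambda \approx 0.9$ and are amplified roughly tenfold, while noise modes
near $\lambda \approx 0.45$ are suppressed — with plain $\lambda$ weights
the noise modes dominate the distance and recovery degrades badly. The
root is the cell maximizing the KC program score by default (`"max-kc"`),
or any explicit cell or score vector; rooting at the opposite end simply
reverses the ordering, which the tests assert. Branch labels come from a
deliberately simple spine splitter (components left after removing the
shortest root-to-terminus path); the generator's truth is one-dimensional,
so single-branch behavior is the tested surface.

Moran's I over the graph,
$I = (n/W)\, \sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x) / \sum_i (x_i - \bar x)^2$
with binary symmetric weights, ranks genes by smoothness along the
trajectory; a constant gene is defined as $I = 0$, and the permutation null
has mean $-1/(n-1)$, which the test suite confirms by simulation. Branch
subclustering is seeded k-means (10 restarts) on marker-panel z-scores
concatenated with pseudotime; clusters are labeled KC / IC / SPP1 by argmax
of the KC score, IC score and SPP1 expression, with pseudotime order as the
tiebreak.

IC co-expression uses the strict conjunction: a macrophage/monocyte
co-expresses the IC program when all six markers (SPP1, TGFBR1, IL6R,
CSF1R, VSIG4, CD163) have positive log-normalized expression — i.e., at
least one count — the simplest reproducible co-expression rule; the
threshold is an exposed argument.

# Spatial statistics

Phenotypes are conjunctions of marker-at-least-cutoff terms (boundary
counts as positive); per-marker thresholds are study-specific, so they
are mandatory configuration and the synthetic panel is built
so that a single cutoff of 4 separates populations exactly. Region
assignment is even-odd point-in-polygon with the boundary inside and
first-listed precedence for overlaps. Densities use shoelace areas, with
the αSMA− area defined as field area minus αSMA+ area. Nearest-neighbor
distances are exact (blocked vectorized evaluation, verified against a
double loop); the proximity rule counts query cells within 100 µm of their
nearest target. Query cells are stratified by region class but target
cells are **not** region-filtered — a macrophage just inside a region
keeps its true nearest CD8+ T cell even if that cell sits outside — which
avoids boundary truncation bias. Paired αSMA+/− comparisons are classical
two-sided paired t-tests on per-sample summaries, with the degenerate
conventions $t = 0, p = 1$ for identical pairs.

# Cross-compartment correlation

Pseudobulk is the mean of log-normalized values per patient (not a count
sum), so library-size differences between patients do not masquerade as
biology. The correlation stage is deliberately plain: Pearson r plus
ordinary least squares, matching the "simple linear regression" design of
the figure panels it emulates, with paired t-tests for two-compartment
expression contrasts. Gene-symbol mapping follows the standard reading:
TGF-β → TGFB1, IL-6 → IL6, TLR-2/4 → TLR2/TLR4.

# The synthetic cohort: what it emulates and what it does not

`cohort_config()` fixes the study conditions: 10 patients × 6 paired
compartments (MT, MN, PT, PN, PBMC, LN) × 400 cells, negative-binomial
counts with shared dispersion 0.3 and log-normal baseline means, patient
random effects (SD 0.1 on the log-mean), and a fixed coarse-type mix
(40% CD8 T, 20% macrophage, 10% monocyte, 10% NK, 10% Treg, 10% stromal).
Planted structure, each recoverable by exactly one downstream stage:

- **pTRT cells** at per-tissue frequencies ordered MT (10%) > LN > PT >
  MN > PN > PBMC (0.2%), each overexpressing a 50-gene reactivity program
  at log-fold-change 1.5. Signatures sample 15 program genes plus 5 decoys.
- **SPP1→CD44 axis**: MT macrophages carry `lr_effect`-fold (default 4×)
  SPP1 and MT pTRT cells 4× CD44. Constitutive macrophage SPP1/FN1 sits at
  sub-saturating levels (an SPP1+ subpopulation rather than uniform high
  expression) so the Hill strength stays in its sensitive range.
- **IC state** in 20% of liver vs 4% of colon macrophages/monocytes,
  elevating all six IC markers jointly.
- **Cytokine→FN1/SPP1 slopes**: a per-patient latent cytokine level
  (SD 0.4) elevates TGFB1/IL6/TLR2/TLR4 in the primary tumor's producing
  compartments (myeloid and stromal cells — the cell types the biology
  assigns these cytokines to, and a necessary restriction for lymphocyte
  exchangeability across tissues); MT stromal FN1 and MT macrophage SPP1
  respond with slope 0.5 plus Gaussian noise (SD 0.15). Responding genes
  sit at baselines where the log1p pseudobulk is effectively linear in the
  planted log-mean, so OLS recovers the slope without attenuation.
- **Macrophage continuum** (300 cells × 300 genes): latent time
  $t \sim U(0,1)$; KC markers fall logistically (midpoint 0.35), SPP1
  rises logistically (midpoint 0.8), TGFBR1/IL6R/collagen genes peak at
  $t = 0.5$; a third of the gene universe carries smooth random logistic
  programs, as real differentiation continua do — without that broad
  covariance no graph method can recover the ordering from 13 markers
  among hundreds of i.i.d. genes. True states: KC ($t < 0.35$), IC
  ($0.35 \le t \le 0.7$), SPP1 ($t > 0.7$).
- **Spatial samples** (15 fields of 2000 × 2000 µm): 2–4 non-overlapping
  αSMA+ rectangles placed uniformly *including* clipped border overlap, so
  the positive and negative classes share one positional distribution and
  the attraction-free null is exact (interior-only placement leaves the
  border strip entirely αSMA−, which biases nearest-neighbor comparisons).
  Macrophages inside αSMA+ move halfway (`spatial_attraction = 0.5`)
  toward their nearest CD8+ T cell; NK and Treg cells are never displaced
  and serve as negative controls.

`null_cohort_config()` zeroes every planted effect, making tissues, cell
types and patients exchangeable — the basis of the type-I-error tests.

What the generator does **not** emulate: dropout beyond NB sampling,
UMAP geometry, TCR clonality, cell segmentation errors, marker spillover,
batch effects, or realistic patient-level biological heterogeneity beyond
a modest random effect. Passing recovery tests therefore demonstrates that
the pipeline's statistics do what they claim under their own assumptions,
not that those assumptions hold in any particular real data set.

# Numerical choices and degenerate inputs

- Gene symbols are uppercased on load (human/mouse case differences are
  erased deliberately); duplicate ids are errors.
- MTX orientation is autodetected from the sidecar lengths; 1-based on
  disk, matrix-native in memory.
- Quantiles are type 7 throughout (the trimean worked examples fix this);
  z-normalization uses the population SD.
- Permutation p-values use the $+1$ estimator; zero-strength edges get
  $p = 1$ by tie counting.
- Paired tests on identical pairs return $t = 0, p = 1$; a constant
  nonzero shift returns $p = 0$ with the matching sign.
- k-means is seeded with 10 restarts; kNN ties and Moran ties break
  lexicographically — reproducibility is preferred over randomization
  everywhere, and `run_pipeline()` fans one global seed out to per-stage
  seeds (`seed + stage index`) so stages can be rerun in isolation.

# Problem sizes used by the test suite

Recovery criteria that name the default cohort run at the full
10 × 6 × 400 design (pTRT classification, tissue ordering, the 500-gene
control ANOVA). Null-calibration loops that only measure type-I error run
on reduced designs chosen as the package's own testing sizes: exchangeable
commnet nulls at 3 patients × 120 cells on one compartment (pooling ≥ 2000
edge tests), IC-frequency calibration at 100 cells per tissue over 100
seeds, and cross-compartment recovery at a two-compartment cohort with a
120-gene universe. Power and direction claims use 17–18 of 20 seeds as
their acceptance bar, mirroring the corresponding recovery criteria.

# Known limitations

- The trajectory stage substitutes diffusion-distance pseudotime for a
  principal-graph method; the generator's truth is one-dimensional, so
  branch-point inference is intentionally minimal.
- The communication stage pools cells within a condition; a per-patient
  paired-test variant would need per-patient graphs and is approximated
  here by the pooled permutation design.
- Hill strengths saturate for very highly expressed ligand–receptor pairs;
  differential strengths between saturated edges are small and noisy by
  construction, which is why recovery claims target the planted edge and
  pathway rather than arbitrary contrasts.
- The 500-gene random control assumes the gene universe is much larger
  than any planted program; with toy universes below ~1000 genes the
  control overlaps the reactivity program heavily and the ANOVA null
  degrades.
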