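# pmtstats

Statistics for detecting a genotype-associated pericyte-to-myofibroblast
transition (PMT) in single-cell transcriptomics, with companion
tissue-image statistics and a synthetic-data generator that provides ground
truth for calibration and power analysis.

## The problem and who this is for

Pericytes are the contractile mural cells wrapping brain capillaries. Under
disease-associated signaling they can detach from vessels and adopt a
myofibroblast-like identity that co-expresses contraction (*ACTA2*) and
extracellular-matrix (*FN1*, collagens) gene programs, passing through an
NG2+/αSMA+ intermediate state. Asking whether a risk genotype biases mural
cells toward this transition requires several statistics that are not
off-the-shelf. This package implements them for analysts working with
single-nucleus RNA-seq cohorts and stained tissue images:

- **Program scoring** — the binned-control module score
  (per-cell mean of program genes minus the mean of expression-matched
  control genes sampled from the same average-expression bins), the
  **co-expression score** `min(contraction, ECM)`, and strict marker gating
  of intermediate cells (both markers `> 1.5` log-normalized).
- **Trajectory statistics** — weighted penalized B-spline fits of a score
  along pseudotime, one per lineage (basis dimension 7, curvature penalty,
  GCV smoothing), compared by

  ΔAUC = AUC(pericyte→myofibroblast lineage) − AUC(pericyte→pericyte lineage)

  with a permutation null that swaps each cell's lineage-weight pair with
  probability ½ (default n = 1000), and a two-sided exceedance p-value.
  A subject-level permutation test for genotype bias in lineage weights.
- **Cohort statistics** — a binomial logit GLM of subject-level cell-state
  proportions on genotype + natural cubic spline of age (3 df) + sex +
  dataset, fit by an explicit IRLS with Wald odds-ratio CIs; greedy 1:1
  propensity matching within dataset with a standardized-mean-difference
  balance report; randomized-quantile residual diagnostics.
- **Image statistics** — three-state classification of cells
  (vascular NG2+/αSMA− pericyte; NG2+/αSMA+ intermediate; nonvascular
  NG2−/αSMA+ myofibroblast), per-cell median vessel distance from a
  Euclidean distance transform, the fraction of fibronectin-positive area
  within 2.5 µm of αSMA-positive area, a linear-trend test across ordered
  states, and a one-sample test against 50%.
- **Synthetic data** — generators for cohorts, lineage weights,
  negative-binomial counts with trajectory-linked gene programs, and
  labelled tissue images with ground-truth states.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a simulated
cohort (40 subjects, ~2,000 cells, 300 genes; risk genotype biased toward
the myofibroblast lineage with log-odds 1.5 and program amplitude 1.5):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_score_programs.R
Rscript analysis/03_trajectory_tests.R
Rscript analysis/04_proportion_model.R
Rscript analysis/05_spatial_statistics.R
```

Output of the trajectory step:

```
delta-AUC permutation test (swap_weights):
  AUC myo = -0.09029, AUC peri = -0.3434, delta = 0.2531
  p (two-sided, 1000 permutations) = 0
lineage bias (genotype 1 - 0): 0.2137, p = 0 (2000 perms)
```

The co-expression score rises along the myofibroblast lineage but not the
pericyte lineage, so the ΔAUC of 0.25 is larger in magnitude than every one
of 1,000 weight-swap permutations (exceedance p = 0; the add-one-smoothed
p ≈ 0.001 is reported alongside). The lineage-bias statistic says
risk-genotype subjects carry, on average, a 0.21 higher normalized
myofibroblast-lineage weight than reference subjects, and no subject-level
label permutation reached that difference. The spatial step classifies
noise-free synthetic tissue with 100% accuracy and recovers the
pericyte < intermediate < myofibroblast vessel-distance ordering
(mean linear contrast ≈ 30 µm, p ≈ 2e-6 at 6 samples).

Equivalent functionality is available in one call:

```r
library(pmtstats)
manifest <- run_pipeline(pipeline_demo_config("demo_out", seed = 7))
```

which writes TSV/JSON outputs plus a manifest of parameters, per-stage
seeds and output hashes; identical configs give hash-identical runs.

## Package layout

- `R/` — generators (`synth_config`, `generate_dataset`,
  `generate_tissue_image`), scoring (`module_score`, `coexpression_score`,
  `gate_intermediate`, `qc_filter`, `normalize_cp10k`, `rank_genes`),
  trajectory statistics (`fit_weighted_spline`, `trajectory_auc`,
  `delta_auc_test`, `lineage_bias_test`), cohort statistics
  (`fit_logistic_irls`, `fit_proportion_glm`, `predict_proportions`,
  `propensity_match`, `residual_check`), image statistics
  (`classify_cell_states`, `vessel_distance`, `proximity_fraction`,
  `state_trend_test`, `fraction_vs_chance_test`), and orchestration
  (`run_pipeline`).
- `analysis/` — the numbered narrative drivers shown above.
- `vignettes/pericyte-myofibroblast-workflow.Rmd` — the models, their
  assumptions, parameter choices, and known limitations.
- `tests/testthat/` — unit, property and acceptance tests.
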