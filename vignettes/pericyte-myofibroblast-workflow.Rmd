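---
title: "Detecting a pericyte-to-myofibroblast transition: models, statistics, and design choices"
author: "pmtstats authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a pericyte-to-myofibroblast transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmtstats)
```

## The scientific problem

In the aging brain vasculature, pericytes -- the contractile mural cells
wrapping capillaries -- can detach from vessels and acquire a
myofibroblast-like identity that simultaneously expresses contraction
(e.g. ACTA2) and extracellular-matrix (e.g. FN1, collagens) gene programs,
passing through an NG2+/alpha-SMA+ intermediate state. Detecting such a
transition in single-nucleus RNA-seq, and asking whether a risk genotype
biases cells toward it, requires several statistics that are not off-the-shelf:
a program score with expression-matched controls, a lineage-resolved
trajectory comparison with a permutation null, a subject-level proportion
model, cohort matching, and companion image statistics for stained tissue.
`pmtstats` implements each of these against a synthetic-data generator with
known ground truth, so every statistic's calibration and power can be
measured rather than assumed.

## The synthetic cohort generator

`synth_config()` fixes the study conditions; `generate_dataset()` chains the
three generator stages.

**Cohort** (`generate_cohort`): two genotype groups (0 = reference, 1 =
risk) with `n_subjects_per_genotype` subjects each; age uniform on
`age_range` (default 60--95 years, a typical postmortem aging cohort), sex
Bernoulli(1/2), dataset categorical with three levels (emulating a
multi-study design), and per-subject cell yields uniform on
`cells_per_subject_range`.

**Lineage structure** (`generate_lineage_weights`): each cell has latent
myofibroblast-lineage membership with probability
`plogis(alpha + beta * genotype)`. The intercept `alpha` is fixed at 0
(a 50/50 split at baseline): neither a larger nor a smaller baseline
changes what the downstream statistics test, and 0 keeps both lineages
well-populated at every cohort size. `effect_beta_genotype` is the
generator's single lineage-bias dial; 0 gives the exchangeable null.
Curve weights are Beta(8, 2) for member cells and Beta(2, 8) otherwise
(complementary pairs summing to 1), giving the soft, overlapping lineage
assignments that curve-fitting tools emit rather than hard labels.
Pseudotime is uniform on [0, 1]: the trajectory statistics consume only an
ordering and weights, so a fitted-curve time axis would add realism without
changing what is tested.

**Counts** (`generate_counts`): gene `g` in program `P` has log mean
`mu_g + amplitude * dir_P * t_eff`, where
`t_eff = pseudotime * w_myo / (w_myo + w_peri)` is effective progress along
the myofibroblast branch. Contraction, ECM, myofibroblast and TGF-beta
programs rise along it (`dir = +1`) and the pericyte identity program falls
(`dir = -1`); TGF-beta rises because that signaling axis is the driver of
the transition this workflow targets. Baseline log means are uniform on
`baseline_log_mean_range` (default [-2, 1.5], i.e. mean counts roughly 0.14
to 4.5, a realistic single-nucleus depth). Counts are negative binomial
with one shared `size` parameter (`nb_dispersion`): gene-wise dispersion
would be more faithful to real data but adds nothing when the object under
test is the statistic, not the estimator of dispersion. A per-cell
LogNormal(0, 0.3) size factor makes depth normalization non-trivial.

What the generator does *not* emulate -- batch effects needing integration,
doublets, ambient RNA, gene--gene correlation beyond the shared trajectory
-- bounds what passing tests show: they certify the statistics on data
satisfying their own assumptions, not robustness to artefacts that upstream
tools (integration, doublet removal) are expected to handle.

## Program scores with binned controls

`normalize_cp10k()` is the standard per-cell depth normalization
`ln(1 + count / total * 10^4)`; `qc_filter()` applies strict ("more than" /
"less than") per-cell thresholds on detected features, total counts and
mitochondrial/ribosomal fractions, identifying those genes by configurable
identifier prefixes (defaults `MT-`, `RPL`/`RPS`) since annotation
conventions vary.

`module_score()` re-implements the binned-control program score: all genes
are cut into `n_bins = 24` equal-count bins by mean expression; each
program gene draws `n_ctrl = 100` controls from its bin (without
replacement when the bin suffices, with replacement otherwise); the score
is the per-cell mean over program genes minus the mean over the pooled
controls. These defaults are the published defaults of the widely used
implementation of this score. Two properties are worth knowing. First,
the score is location-equivariant: a global constant cancels between
program and controls. Second, program genes are not excluded from their
own control pools, so a program occupying a large fraction of its bins
biases the score toward zero; the tests therefore use fixtures in which
program genes are a small fraction (1/40) of each bin, and
`exhaustive_controls = TRUE` provides a sampling-free reference
implementation for comparison.

`coexpression_score()` is the per-cell minimum of two scores -- high only
when both programs are active, which separates a genuine dual-program
myofibroblast state from either canonical smooth-muscle state alone.
`gate_intermediate()` marks cells whose normalized expression of two
markers (defaults ACTA2 and CSPG4) strictly exceeds 1.5. The boundary is
deliberately strict: the cutoff convention quotes no behaviour at equality,
and `> 1.5` makes a cell at exactly 1.5 negative. `rank_genes()` orders
genes by `sign(log2FC) * -log10(p)` with lexicographic tie-breaks; zero
fold changes rank at zero, and `p = 0` is rejected with instructions to
floor p-values rather than silently producing infinities.

## Trajectory statistics

`fit_weighted_spline()` fits a score against pseudotime by penalized
weighted least squares on a cubic B-spline basis of dimension 7 (the basis
size this workflow standardizes on), with interior knots at weighted
pseudotime quantiles so the basis adapts to where each lineage actually has
weight. The roughness penalty is the exact integrated squared second
derivative (computed per knot interval by Simpson quadrature, which is
exact because the second derivative of a cubic spline is piecewise
linear). We chose this over the simpler coefficient-difference penalty
because on non-uniform knots only the derivative penalty leaves constants
*and* linear trends exactly penalty-free -- a property the test suite
asserts to 1e-6. The smoothing parameter is selected by generalized
cross-validation over 25 log-spaced points from 1e-4 to 1e4; the selected
fit is verified to attain the grid minimum.

`trajectory_auc()` integrates the fitted curve by the trapezoid rule on a
200-point grid (refining the grid changes smooth fits by far less than any
tolerance used downstream).

`delta_auc_test()` is the central statistic: fit the score twice, once per
lineage's weights; integrate both over the *shared* pseudotime range (the
intersection of the supports of the two weight vectors -- zero-weight cells
do not extend a lineage's support); and take delta-AUC = AUC(myofibroblast)
- AUC(pericyte). The null is built by independently swapping each cell's
weight pair with probability 1/2 and refitting (1000 permutations by
default). This is the minimal exchange destroying only the lineage--score
association: each cell keeps its pseudotime and total weight, and under the
hypothesis "no lineage difference" the two weights are exchangeable, so the
permutation distribution is exact by construction. The p-value is the
plain two-sided exceedance proportion -- it can be 0 -- with an
add-one-smoothed companion reported but never used for decisions. Each
permutation draws from a stream derived from `(seed, permutation index)`,
so results do not depend on evaluation order. An alternative
`scheme = "shuffle_score"` (permute the score across cells) is exposed for
sensitivity analysis; it tests a stronger null (no score--position
association at all) and is not the default. Note that the permutation
p-value is *stable*, but not exactly invariant, under monotone rescaling of
pseudotime: the quantile knots adapt, but the AUC is an integral over the
time axis and therefore depends on its parameterization.

`lineage_bias_test()` asks the genotype question: summarize each cell by
`w_myo / (w_myo + w_peri)`, average within subject, difference the group
means, and permute genotype labels at the *subject* level (respecting the
within-subject clustering of cells) for a two-sided exceedance p.
Equivalence with the published differential-lineage test this replaces is
not claimed; it is a documented permutation analogue.

## Subject-level proportion model

`fit_proportion_glm()` models per-subject counts
`cbind(numerator, denominator - numerator)` with a binomial logit GLM on
genotype, a natural cubic spline in age with 3 degrees of freedom (boundary
knots at the age range, interior knots at the tercile quantiles; linear
beyond the boundaries), sex and dataset, with treatment coding and
lexicographic reference levels. The IRLS fitter is written out explicitly
(`fit_logistic_irls()`), iterating to a relative deviance change below
1e-8; the test suite requires its coefficients to agree with brute-force
Nelder--Mead maximization of the exact binomial log-likelihood to 1e-5 and
with the reference GLM implementation to 1e-8. Confidence intervals are
Wald (`exp(beta +- 1.96 * SE)` from the final weighted information matrix)
-- the conventional choice when odds ratios with 95% CIs are reported
without further qualification. Rank-deficient designs error naming the
aliased columns, and |coefficient| > 15 triggers a separation warning
rather than silent explosion. `predict_proportions()` evaluates new
subjects with the training knots and factor coding and refuses unseen
categorical levels by name.

`propensity_match()` fits the propensity of carrying the risk genotype on
the matching covariates (age, sex, AD status, cell yield by default) within
each dataset and greedily pairs each treated subject, in descending
propensity order, to its nearest unused control by logit-propensity
distance -- the conventional defaults of nearest-neighbor 1:1 matching
without replacement, with no caliper. Matching never crosses datasets and
never reuses a control; a dataset with fewer controls than treated subjects
is an error stating the shortfall, not a silent partial match. The balance
report gives each covariate's standardized mean difference before and
after. Greedy matching is not globally optimal; on small instances the
tests compare its total distance with exhaustive optimal assignment.

`residual_check()` is a simplified randomized-quantile-residual diagnostic:
simulate `n_sim = 250` response sets from the fitted model; each subject's
residual is the randomized rank of its observed count among its
simulations, exactly Uniform(0, 1) under a correct model; a
Kolmogorov--Smirnov test against uniformity flags misspecification such as
overdispersion. Dispersion- and outlier-specific tests of the full
diagnostic toolbox this stands in for are out of scope.

## Image statistics

`generate_tissue_image()` draws a vessel tube and places elliptical cells
with state-dependent distance bands from the vessel surface (defaults, in
micrometres: pericytes 0--1, intermediates 4--10, myofibroblasts 15--45 --
adjacent, near, and parenchymal at the default 0.5 um pixel size) and
state-dependent NG2/alpha-SMA intensity means with Gaussian noise; ground
truth is returned. `classify_cell_states()` applies the three-state rule:
mean cell intensity strictly above each channel threshold defines marker
positivity; "vascular" means minimum pixel distance to the vessel mask at
most 2.5 um (mirroring the proximity radius used for the fibronectin
statistic; configurable); then vascular NG2+/aSMA- is a pericyte,
NG2+/aSMA+ is an intermediate regardless of location (the classification
rule attaches no location qualifier to the double-positive state), and
nonvascular NG2-/aSMA+ is a myofibroblast. Everything else is
unclassified and excluded from the proportion denominator. Thresholds are
supplied explicitly in all tests; a per-channel Otsu fallback exists for
exploratory use.

`vessel_distance()` is the median (even counts: mean of the central pair)
of the Euclidean distance transform over the cell's pixels, in um.
`proximity_fraction()` dilates the target-positive mask with a disk of
pixel radius `round(radius_um / pixel_size)` and reports the fraction of
source-positive pixels covered -- with defaults, the fibronectin area
within 2.5 um of alpha-SMA-positive area. `state_trend_test()` applies the
per-sample linear contrast (-1, 0, +1) across (pericyte, intermediate,
myofibroblast) mean distances and t-tests the contrasts against zero -- the
post-hoc linear-trend component of a repeated-measures design; the omnibus
repeated-measures ANOVA itself is intentionally not implemented.
`fraction_vs_chance_test()` is the one-sample t-test against 50%, with
explicit degenerate handling: zero variance exactly at the null gives
p = 1, and zero variance elsewhere returns p = 0 flagged
`degenerate = TRUE` so callers cannot mistake it for a regular t-test
result.

## Orchestration and determinism

`run_pipeline()` executes the stages (simulate, score, gate, trajectory
tests, proportion model, matching, spatial) in dependency order from one
config (list or YAML), validating referenced inputs before any stage runs.
Every stage's random stream is seeded by `derive_seed(global_seed,
stage_name)` -- a deterministic integer hash -- so adding or toggling a
stage never perturbs another stage's draws. All tabular outputs are TSV,
all statistical results also JSON, and the manifest records parameters,
seeds and MD5 hashes of every output; two runs from the same config are
hash-identical. A failing stage is recorded, downstream stages are
skipped, and the run errors after the manifest is written. The pipeline's
matching stage makes 1:1 matching feasible per dataset -- datasets missing
a genotype group are dropped, and where treated subjects outnumber controls
the excess treated are trimmed deterministically before matching; the
underlying `propensity_match()` keeps its strict error contract for direct
callers.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen so each statistical property
is measured with meaningful resolution: delta-AUC calibration uses 200
null cohorts of 200 cells with 200 permutations each (the suite) and 100
such cohorts in the standalone acceptance script; power uses 50 (suite) or
30 (script) replicates of 500 cells with up to 1000 permutations; GLM
recovery uses 200 cohorts of 100 subjects; matching optimality uses
8-subject instances where exhaustive assignment is enumerable; image checks
use 220x220 px images with 24 cells. The vignette states these as the
package's own choices of simulation size.

## Known limitations

- Exactly two lineages; multi-branch trajectories are out of scope.
- One shared negative-binomial dispersion; no gene-wise mean--variance
  trend.
- The lineage-bias permutation test is an analogue of, not a re-derivation
  of, the published differential-lineage-assignment test.
- Greedy matching can be suboptimal on adversarial propensity
  configurations; the balance report, not optimality, is the contract.
- Module scores may be biased toward zero when a program dominates its
  expression bins (see above).
- The image generator produces axis-aligned vessels and elliptical cells;
  it exists to give the image statistics exact ground truth, not to mimic
  micrograph texture.
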