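---
title: "Connectome-based predictive modeling with cpmkit: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling with cpmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cpmkit)
```

# The method

Connectome-based predictive modeling (CPM) asks whether a whole-brain
pattern of functional connectivity can predict a dimensional behavior score
in subjects the model has never seen. The unit of brain input is a
connectome: a symmetric $K \times K$ matrix whose entry $(i, j)$ is the
Fisher z-transformed Pearson correlation between the task time courses of
atlas nodes $i$ and $j$. The feature space is the vector of the
$K(K-1)/2$ unique off-diagonal entries ("edges"); for the full 268-node
parcellation that is 35,778 edges, far more than any feasible sample size,
which is why CPM compresses them before fitting anything.

One cross-validation run proceeds fold by fold:

1. **Edge selection.** Within the training subjects only, every edge is
   correlated with the behavior. Edges with $p < \alpha$ form the
   *positive network* (correlation $> 0$: higher connectivity goes with
   higher scores) or the *negative network* (correlation $< 0$).
2. **Network strength.** Each subject is reduced to two numbers: the sum
   of their edge values over the positive network and over the negative
   network.
3. **Linear model.** Behavior is regressed on the strengths
   (`combined`: both predictors; `positive_only` / `negative_only`: one),
   and the model predicts the held-out subjects from their strengths.

Assembling the out-of-fold predictions gives one predicted score per
subject, evaluated by Spearman's $\rho$ against the observed scores (no
distributional assumption on a bounded, skewed questionnaire total) and by
$\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_i(\mathrm{actual}_i -
\mathrm{predicted}_i)^2}$.

Because a single random fold assignment adds Monte-Carlo noise, the whole
procedure is repeated (default 100 times) and the run with the **median**
$\rho$ is reported. Out-of-fold predictions are not independent across
subjects, so parametric p-values for $\rho$ would overstate the degrees of
freedom; significance instead comes from a permutation test (below).

# Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `n_folds` | 10 | tenfold CV; leaves ~90% of subjects to select edges on |
| `n_iterations` | 100 | enough repeats for a stable median run |
| `selection_alpha` | 0.01 | the conventional CPM edge-selection threshold; configurable and echoed in every output |
| `selection_statistic` | `pearson` | protocol convention; `spearman` (Pearson on ranks) and `partial_pearson` (covariate-adjusted) available |
| `model_form` | `combined` | two-predictor model; single-network forms reproduce the positive/negative decomposition |
| `consensus_fraction` | 1.0 | an edge must be selected in *every* fold of the median run to enter the consensus network |
| `n_perm` | 1000 | permutation iterations; scaled-down values are valid with the matching floor $1/(n_{perm}+1)$ |
| long-range cut | 60 mm | centroid-distance convention for the long/short partition; always reported with results |

# Design choices where the design was open

**Median-run selection.** With an even repeat count the "median" is
ambiguous; `run_cpm()` takes the lower-middle order statistic so that a
concrete run — with concrete fold models and networks — exists to localize.
The scalar reported as the median $\rho$ can therefore differ from the
interpolated median by at most the gap between the two middle runs.
Degenerate runs (all folds empty, prediction correlation undefined) are
excluded from the ordering with a message.

**Covariate adjustment.** When confounds (head motion, age, sex, symptom
scores, medication) must be controlled, `partial_pearson` selection
replaces each edge–behavior correlation by the partial correlation given
the covariates, *computed within the training fold only* — held-out
subjects' covariates never touch training, preserving the leakage-free
contract. Adjusting selection is the mechanism we adopt because selection
is where the brain–behavior association enters the model; residualizing
the behavior vector instead is possible with `partial_correlation()` but
is not the default, and the mode used is recorded in the output.

**Consensus definition.** Whether a reported network is the intersection
across folds, the union, or a frequency threshold is a genuine degree of
freedom; `consensus_fraction` exposes it, defaulting to 1.0 (intersection),
the strictest and most reproducible choice.

**Permutation scheme.** Each of the `n_perm` shuffles breaks the
behavior–connectome correspondence (covariates stay attached to their
subjects, so a covariate-adjusted null stays covariate-adjusted) and
re-runs one cross-validation with fresh folds. One run per permutation —
not the full 100 repeats — because under the null a single run is
exchangeable with the observed statistic, and the full grid costs 100×
more for no change in validity; `n_iterations_per_perm` raises it if
wanted. The p-value uses strict inequality,
$p = (\#\{\rho_{null} > \rho_{obs}\} + 1)/(n_{perm}+1)$: ties count toward
the null not exceeding, and the floor $1/(n_{perm}+1)$ is attainable but
never undercut. Reusing the observed fold assignment instead of fresh
folds is available via `refold = FALSE`.

**Model comparison.** Two models evaluated against the *same* observed
behavior yield dependent correlations; their difference is tested with
Steiger's z for dependent correlations sharing one variable, using
Fisher-transformed correlations and the pooled-estimate covariance
correction. All three correlations entering the test are Spearman — the
same metric the models are evaluated with — and the p-value is two-tailed.
`compare_predictions()` computes the cross-model correlation from the
stored prediction vectors rather than asking for it.

# Numerical choices and degenerate inputs

- Correlations are clipped to $|r| \le 1 - 10^{-7}$ before the Fisher
  transform, so identical time courses give a large finite z (~8.4)
  instead of infinity, keeping edge-wise statistics finite downstream.
- The diagonal is stored as 0 and never enters the feature space
  (self-connectivity is undefined under the transform); edge order is
  fixed to the row-major upper triangle so masks and saved models are
  portable.
- Zero-variance edges are excluded from both selection masks; zero-variance
  nodes make the whole matrix undefined and raise an error naming the node.
- A fold whose selection is empty in both tails predicts the training
  mean — permutation runs routinely hit this and must stay well defined.
- Constant or collinear strength predictors are dropped with a warning and
  the model refit on what remains.
- Ranks use midranks (average ties), matching the integer, heavily tied
  nature of questionnaire totals.
- Subjects missing the target behavior are dropped listwise with the count
  logged; missing values are never imputed.
- The long/short-range $\chi^2$ test defaults its expected proportions to
  those of *all* atlas edges rather than 50/50 — the null that the
  predictive network draws edges without regard to length — since a 50/50
  null is only meaningful if the atlas itself is length-balanced; both
  modes are available.

# What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults describe the study design the package targets:
69 subjects; a six-item irritability questionnaire total (integer 0–12,
observed 0–9) drawn as a rounded, clipped gamma with shape 0.75 and scale
2.47, chosen so the *discretized* distribution hits the target moments
(mean 1.79, SD 2.04); age uniform on 8–22 years; motion lognormal with
mean 0.07 mm; two conditions per subject (frustration / nonfrustration);
and a sparse set of planted edges whose association with behavior exists
only in the frustration condition — the dissociation the analysis is
designed to detect.

Signal is planted **directly on the Fisher-z scale**: a planted edge is
`baseline + beta * z(score) + noise`, with
$\beta = \sigma_{noise}\, r /\sqrt{1 - r^2}$ so the population
edge–behavior correlation equals `effect_r` exactly. Generating z-values
directly (rather than simulating time series) gives exact control of
effect sizes, which is what parameter-recovery validation needs. The
corresponding limitation is explicit: the generator does not simulate
hemodynamics, autocorrelated fMRI noise, spatially correlated edges,
motion artifacts, or task structure. Passing tests therefore demonstrate
that the *pipeline* is correct and calibrated under its own statistical
assumptions — not that real task-fMRI data satisfies those assumptions.

A motion-like confound can be wired in two places at once: motion couples
to behavior (Gaussian copula, `behavior_motion_r`) and to a designated
confound edge set (`confound_strength`), in both conditions, since head
motion is not condition-specific. A dataset with confound edges and no
signal edges carries its entire edge–behavior association through motion —
the construction used to validate covariate adjustment.

# Validation studies and their problem sizes

The test suite validates the pipeline at three levels, with sizes chosen
to make each check statistically meaningful at desk scale:

- **Oracle equivalence**: selection, metrics, partial correlation and the
  Steiger statistic are compared against independently coded brute-force
  oracles (per-edge `cor.test` loops, normal equations, rank transforms,
  the published z formula) on random instances with up to 200 edges.
- **Parameter recovery**: one fixed 200-subject, 60-node study with 40
  planted positive edges at `effect_r = 0.4`, condition-specific. The
  frustration model should recover the planted set (sensitivity ≥ 0.8,
  false positives ≤ 1%) with median $\rho \ge 0.5$, while the same
  pipeline on the nonfrustration matrices finds nothing. 200 subjects
  rather than 69 because consensus-network recovery at intersection
  stringency needs the selection step to be stable across folds; at n = 69
  recovery is partial, which is a property of the method at that sample
  size, not an implementation defect.
- **Null calibration**: 100 signal-free 69-subject datasets, 200
  permutations each; the permutation test should reject at the nominal 5%
  rate within binomial bounds. The observed statistic in this study uses a
  single cross-validation run, making observed and null values exactly
  exchangeable under the null — the condition for exact calibration. (The
  median of many repeats is *less* variable than a single run, so using it
  against single-run nulls is mildly conservative; calibration is checked
  in the exchangeable regime.)

Two behaviors worth knowing about when interpreting results. First, the
cross-validated $\rho$ of a *fixed* null dataset is not centered at zero:
a finite sample has spurious whole-sample edge–behavior correlations, and
cross-validation partially re-validates them internally, so null
$\rho_{median}$ varies across datasets with an SD near 0.15 at n = 200.
This is precisely why inference is by permutation within the dataset, not
by comparing $\rho$ to zero. Second, the permutation p under rank-based
selection is invariant to order-preserving transforms of the behavior at
the level of each fold's strength ranking, but assembled cross-fold
predictions mix fold-specific intercepts, so the invariance is approximate
(tested with a tolerance of a few permutation grid steps).

# Known limitations

- The linear strength model is the method's own assumption; nonlinear or
  regularized alternatives are out of scope.
- Consensus networks come from the median run only; edges selected in most
  but not all folds are invisible at the default `consensus_fraction`.
- The generator's independence of edges given the score is idealized; real
  connectomes have rich spatial covariance that will generally *inflate*
  the count of correlated-but-unplanted edges selected.
- With heavily tied integer scores at small n, Spearman $\rho$ is coarse;
  permutation inference absorbs this, but point estimates are grainy.

# A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(n_subjects = 69, K = 60, n_signal_pos = 40,
                       effect_r = 0.4, seed = 1)
ds <- generate_dataset(spec)
cfg <- cpm_config(seed = 1)
fit <- run_cpm(ds$edges$frustration, ds$phenotypes$child_ari, cfg)
perm <- permutation_test(ds$edges$frustration, ds$phenotypes$child_ari,
                         cfg, fit, n_perm = 200, perm_seed = 2)
fit
perm
summarize_network(fit$consensus_pos, ds$atlas)
```

The same analysis runs from a single YAML config via `run_pipeline()`,
which writes predictions, consensus edge lists, the null distribution and
a reproducibility manifest, and `report_run()` prints the standard
summary line (`rho`, RMSE, permutation p with its iteration count and
tail, network sizes, localization partitions).
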