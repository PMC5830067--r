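---
title: "PLS class modeling of percentage immunophenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS class modeling of percentage immunophenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plscm)
```

## The problem and the model

The package addresses two-group discrimination when the data are a few dozen
subjects described by hundreds of variables that all live on one scale —
typically T-cell subset frequencies (percentages) measured by flow
cytometry. An example is separating HIV elite controllers whose CD4 counts
decline (cases) from those who remain stable (controls), with each subject
described by 350 subset frequencies. Ordinary regression is hopeless at
n « p; partial least squares (PLS) handles it by extracting a small number
of latent variables (LVs) — linear combinations of the observed variables —
that explain covariance with the response.

PLS *class modeling* (PLS-CM) goes one step beyond a bare classifier. The
class membership is coded as a binary response (0/1), a PLS regression is
fitted, and the *calculated response* (the model's predicted value) of each
subject is treated as a one-dimensional statistic. A normal distribution is
then fitted per class to these calculated responses, which turns
classification into hypothesis testing: for a threshold t, the upper tail of
the class-0 density is the type I error probability α (rejecting "the
subject is class 0" when true) and the lower tail of the class-1 density is
the type II error probability β. Sweeping t traces a risk curve (α, β); the
threshold where α = β gives the equal-error operating point, reported as
sensitivity = specificity = (1 − α) × 100.

### Uncentered PLS

`fit_pls()` deliberately applies **no preprocessing** by default: no
centering and never any autoscaling. Because all variables are percentages,
autoscaling would inflate noise variables to the same magnitude as the
discriminative ones; and leaving the data uncentered keeps the analysis on
the natural scale of the measurements. The algebra is standard NIPALS with
both blocks deflated, simply run on the raw matrix, with all sums of squares
taken about the origin. A consequence worth understanding: the first LV
essentially points from the origin toward the vector of variable means, and
with typical subset frequencies (baselines of a few percent to a few tens of
percent against within-class scatter of a few percent) it explains more than
90% of the X-block sum of squares while carrying little class information.
Discrimination lives in the later LVs. `center = TRUE` is available, mainly
so the implementation can be cross-checked against conventional PLS
software; explained variance is then measured about the mean instead.

Numerical conventions: component weights are initialised from the
cross-product of the X residual with the y residual and normalised to unit
length; the inner iteration tolerance is 1e-12 with a 500-iteration cap
(with a univariate response convergence occurs in one pass — the loop is a
safeguard); each component's sign is fixed so its largest-magnitude weight
entry is positive, which removes the NIPALS sign indeterminacy and makes
fits bitwise reproducible; the composite regression vector is
`b = W (PᵀW)⁻¹ q`. A zero-norm column under `center = FALSE`, or a zero
residual direction, raises an explicit degenerate-direction error rather
than a silent NaN.

### VIP selection and the two-stage fit

Variable influence on projection (VIP) summarises each variable's
importance across components, weighting each component by the response
variance it explains:

VIP_j = sqrt( p · Σ_a SSY_a (w_{ja})² / Σ_a SSY_a ),

with unit-norm weight vectors, so Σ_j VIP_j² = p exactly and "VIP > 1" means
"above average". The per-component SSY weighting is the standard (Wold)
definition. `two_stage_fit()` implements the fit–select–refit workflow: a
stage-1 model on all variables, selection of those with VIP **strictly
greater** than the threshold (default 1), and a stage-2 model on the
selected columns only. One pass, no recursive elimination. The stage-1 and
stage-2 dimensions can be set explicitly or chosen by the knee rule below.

### Choosing the number of LVs

`select_n_components()` offers two deterministic rules. The knee rule keeps
components while each adds at least 5 percentage points of explained
response variance (the last component meeting the bar is the chosen
dimension; on a ledger of y-partials `38.1, 26.2, 16.9, 3.4` it picks 3).
The alternative `loo_cv` minimises leave-one-out squared prediction error.
The 5-point default is a judgment call — the underlying optimisation goal
("maximise explained variance in both blocks") is qualitative — so the
pipeline also accepts explicit dimensions, which is how a published choice
of 3 or 4 LVs is reproduced.

### Class densities, risk curves, operating point

`fit_class_densities()` uses the in-sample calculated responses, per-class
sample mean and SD (n−1), and attaches Shapiro–Wilk p-values; Shapiro–Wilk
is the small-sample default among normality tests, and a p-value at or
below 0.10 raises a *warning*, not an error, because the normal model
remains computable and the analyst should see it rather than be stopped.
The equal-error threshold has the closed form

t\* = (μ₀σ₁ + μ₁σ₀) / (σ₀ + σ₁),

the point where the standardized distances to the two class means agree, so
α = β = Φ(−|μ₁ − μ₀|/(σ₀ + σ₁)). The risk-curve grid spans
`[min(μ) − 4·max(σ), max(μ) + 4·max(σ)]` (512 points by default) and the
numeric root of |α − β| agrees with t\* to grid resolution — both routes are
computed and compared in the tests, since either could legitimately be used
to read off the operating point. Raw probabilities are carried everywhere;
integer-percent rounding happens only in reports. A sample exactly at the
threshold is assigned to class 1 — an arbitrary but fixed tie rule.

### Score-plane rotation

A two-LV score plot can often be rotated so that a single vertical line
separates the classes. The construction rule for the angle is not part of
the published analyses we emulate (their angles are data-dependent
outcomes), so the package defines one: `find_separating_rotation()` grid
searches counterclockwise angles in [0°, 180°) at 0.5° steps and returns
the angle maximising the margin — the gap between the class extremes on the
rotated first coordinate — with the separating value at the gap midpoint.
Half a turn suffices because a vertical separator is invariant under 180°
rotation with sides swapped. If no angle separates, the max-margin angle is
returned with `perfectly_separated = FALSE`.

### Univariate layer

`mann_whitney()` is two-sided throughout; for pooled samples of at most 12
observations without ties the p-value is exact by full enumeration of label
arrangements, otherwise a midrank, tie-corrected normal approximation with
continuity correction is used. `screen_variables()` applies it per variable
with **no multiple-testing correction** — this mirrors the screening
practice of the analyses the package emulates and is prominently noted in
the documentation: at α = 0.05 over 350 variables, ~17 false positives are
expected under the global null, and the selected/unselected ×
significant/nonsignificant partition should be read with that in mind.
`loading_pvalue_association()` rank-correlates a per-variable magnitude
with the univariate p-values; "loading" is ambiguous in common usage, so the
default magnitude is the absolute composite regression coefficient, with
the raw weights and X-loadings available behind a switch.
`classify_cd4_slope()` is the minimal reading of "linear regression
analysis": an OLS slope with a classical t-test at α = 0.05, "case" if and
only if the slope is significantly negative (a significantly *positive*
slope is still a control).

## The synthetic cohort generator

No patient-level data are available, so `generate_cohort()` provides the
statistical structure every stage needs:

values = baseline + factor contribution + class shift + noise, clipped to [0, 100].

* **Baselines** per variable from U(5, 40)% — subset frequencies from a few
  percent to a few tens of percent; drawn once and shared by all subjects,
  which is what gives the uncentered matrix its dominant mean-offset
  direction (LV1 > 90% of X).
* **Within-class noise** SD per variable from U(1, 5)%, a realistic
  measurement-plus-biology scatter for subset frequencies.
* **Correlation** from 6 latent factor blocks contributing 30% of
  within-class variance (`factor_strength`), emulating the strong
  parent/child correlation structure of gating-derived subsets without
  modeling compositional sum rules explicitly (a stated non-goal).
* **Planted signal**: 30 informative variables get a class-1 mean shift of
  `effect_size` (default 1.5) within-class SDs, random sign.
* **Sizes**: 22 vs 14 by default (a cases-vs-controls design), 36 vs 14
  under `preset = "pls1"` (a patients-vs-healthy design).

Gaussian-with-clipping was chosen over a logit-normal model because it
keeps the planted effect sizes transparent; the clipped fraction is
monitored and a configuration whose draws clip more than 10% of cells
raises a warning. A single seed fans out into per-block substreams
(baselines, noise SDs, factor structure, informative set, factor scores,
noise) so that changing one block's parameters does not shift the others'
draws. What the generator does **not** emulate: compositional constraints
between parent and child subsets, skewed or zero-inflated frequency
distributions, batch effects, and measurement ties. Tests passing on this
generator therefore demonstrate that the *pipeline* recovers planted
structure under its own assumptions, not that real cohorts satisfy those
assumptions.

`generate_trajectories()` plants a −66 cells/µL/yr decline for cases (the
magnitude typical of immunological progressors) against flat controls, with
visit-level noise, for exercising the CD4-slope classifier.

## In-sample optimism and the validated operating point

The paper-faithful class model is fitted on in-sample calculated responses,
and `run_plscm()` keeps that as its default. At n ≈ 36 and p = 350 this is
very optimistic: a PLS component can chase noise that correlates with the
class code, so even a pure-noise cohort yields well-separated in-sample
densities. For that reason `simulate_plscm()` — whose job is to answer
"does the pipeline find planted signal, and does it stay quiet when there
is none" — defaults to `validation = "loo"`: the *entire* two-stage
pipeline (dimension choice if automatic, VIP selection, stage-2 fit) is
re-run with each subject held out, the held-out responses are collected,
and a second set of class densities and operating point is computed from
them. Under the null the validated sensitivity hovers just above 50%
(the equal-error statistic uses |μ₁ − μ₀| and is therefore floored at 50),
while at a planted effect of 3 within-class SDs it exceeds 95%; the
in-sample point is reported alongside for comparison.

## Problem sizes used in the test suite

Property checks run on small seeded matrices (8–14 subjects, 5–9
variables) against independent oracles: a textbook NIPALS written
separately, the Krylov-subspace closed form for centered univariate PLS
coefficients, the closed-form Wilcoxon null distribution, and brute-force
residual re-measurement for the variance ledger. Recovery and calibration
claims use the generator at its default 36 × 350 design: 20 seeds for
selection recall and for the validated-sensitivity curve (with full LOO,
i.e. 36 pipeline re-fits per seed), and 20–30 seeds for the null
calibration of the screen. These sizes give stable averages while keeping
the whole suite around a minute of compute.

## Known limitations

* The normal class model is the method's own assumption; heavy-tailed
  calculated responses only produce a warning.
* No multiple-testing correction in the univariate screen, by design
  (fidelity to the emulated practice).
* The rotation search is a grid search; with a 0.5° step the returned
  angle is only locally optimal to that resolution.
* The generator's percentage model clips at the bounds; configurations
  with baselines near 0 or 100 and large effects distort planted shifts
  (monitored, warned).
* `select_n_components()` ties are broken toward the smaller dimension;
  the knee rule depends on its 5-point cutoff.
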