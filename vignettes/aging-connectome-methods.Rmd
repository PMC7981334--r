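---
title: "Modelling aging effects on functional connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aging effects on functional connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cross-sectional two-age-group designs show two distinct phenomena in
functional connectomes: older adults' connectomes differ *on average* from
younger adults' (a shift in mean functional connectivity, FC), and older
adults' connectomes differ more *from each other* (a growth in between-person
FC variance). `fcaging` separates these two components per connection,
quantifies their consequences for connectome similarity, and relates their
nodal aggregates to aging effects in dopamine D1 receptor availability
(binding potential, BP, from PET) and gray matter density (GMD, from
structural MRI).

# The location-scale age model

For a feature $j$ (an FC connection, or a region for BP/GMD) and subject $s$
with age $a_s$ referenced to 20 years and motion trait $\mathrm{FD}_s$ (mean
framewise displacement, mm):

$$y_s = z_s + \rho\,\mathrm{FD}_s, \qquad
  z_s \sim N\!\big(\mu(a_s),\, \sigma(a_s)\big),$$
$$\mu(a_s) = \alpha_\mu + \beta_\mu a_s, \qquad
  \log \sigma(a_s) = \alpha_\sigma + \beta_\sigma a_s.$$

The age reference makes $\alpha_\mu$ and $e^{\alpha_\sigma}$ directly
interpretable as the mean and SD of a 20-year-old; $\beta_\mu$ is the annual
change in the mean and $e^{\beta_\sigma}$ the annual multiplicative change in
the SD. The log link keeps $\sigma$ positive for any parameter values.

**Assumptions.** Gaussian feature values (FC enters Fisher-z transformed for
this reason), linear age trends in mean and log-SD over the sampled age
range, an additive motion effect that is constant across ages, and
independence across subjects. Because the design is cross-sectional, "aging
effects" are age-group differences: cohort effects and selective sampling are
not separable from within-person change.

**Estimation.** Maximum a posteriori, i.e. penalized maximum likelihood with
independent normal priors centered at 0. The negative log posterior for one
feature is

$$\sum_s \left[ \log \sigma(a_s) +
  \frac{(y_s - \rho \mathrm{FD}_s - \mu(a_s))^2}{2\sigma(a_s)^2} \right]
  + \sum_k \frac{\theta_k^2}{2 s_k^2},$$

minimized by BFGS with analytic gradients, initialized at the OLS solution
(intercept/age-slope/FD coefficient from a linear fit, $\alpha_\sigma$ at the
log of the maximum-likelihood residual SD, $\beta_\sigma = 0$), plus four
seeded jittered restarts and a final polish run; the best objective wins,
ties going to the first solution found. With flat priors,
$\beta_\sigma \equiv 0$ and $\rho \equiv 0$, the optimum coincides with OLS
and the ML residual SD — this closed-form oracle is enforced to $10^{-6}$ in
the tests.

**Priors.** Default scales: $N(0, 10)$ on $\alpha_\mu$ and $\alpha_\sigma$
(essentially flat for z-scale data), $N(0, 0.1)$ on $\beta_\mu$,
$\beta_\sigma$ and $\rho$. Zero-centered symmetric priors avoid biasing the
*direction* of aging effects; the slope scales are an order of magnitude
wider than plausible annual changes in z-scale FC, so they regularize
degenerate fits without materially shrinking identified effects. All scales
are configurable (`age_model_priors()`), and `flat_priors()` gives plain
maximum likelihood.

**Identifiability.** Features with no between-subject value variance are
flagged `degenerate`; cohorts with a single distinct age are flagged
`unidentifiable` (slopes are then determined only by their priors — the MAP
splits the unidentified intercept-plus-slope sum by prior precision, leaving
slopes near but not exactly 0). Both are excluded from sign-fraction
summaries only via their status flag; parameters are always returned.

**Interpretation choices.** $\rho$ is estimated per feature: a single global
motion coefficient across tens of thousands of connections would require a
joint fit that buys little and costs much. The FD covariate is the
post-scrubbing subject mean, the value the pipeline reports per subject.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the estimator and the downstream analyses are validated.

**Cohort** (`cohort_spec()`): 30 + 30 subjects; younger ages
$N(24.2, 3.4^2)$, older $N(70.8, 2.7^2)$, truncated above 18 years so the
age-20 reference stays meaningful; a per-subject motion trait (mean FD) of
$0.12 \pm 0.05$ mm (younger) and $0.18 \pm 0.05$ mm (older), reflecting the
usual tendency of older adults to move more.

**Edge ground truth** (`edge_effect_config()`), drawn per connection:

| parameter | default | rationale |
|---|---|---|
| $\alpha_\mu$ | $N(0.3, 0.3^2)$ z | typical Fisher-z FC levels |
| $\beta_\mu$ | $N(-0.001, 0.002^2)$ z/yr | ≈69% of edges negative; a 50-year gap shifts FC by about $-0.05$ z on average |
| $\alpha_\sigma$ | $N(\log 0.1, 0.2^2)$ | between-subject SD ≈ 0.1 z at age 20 |
| $\beta_\sigma$ | $N(0.002, 0.004^2)$ /yr | ≈69% of edges positive; SD grows ≈ 10% over 50 years on average |
| $\rho$ | $N(0, 0.1^2)$ z/mm | motion inflates short-range and suppresses long-range FC, so edge-wise motion effects are sign-mixed around 0 |

The slope scales were chosen from power reasoning before any acceptance runs:
with 60 subjects in the two-cluster age design (age SD ≈ 23.5 y) and
$\sigma \approx 0.1$, the sampling SE of $\hat\beta_\mu$ is ≈ 0.00055 and of
$\hat\beta_\sigma$ ≈ 0.0039, so true-effect SDs of 0.002 and 0.004 give
expected truth–estimate correlations of ≈ 0.96 and ≈ 0.7 — a regime where
recovery is demonstrable but not trivially easy. The zero-centered $\rho$
default matches the zero-centered prior; a systematically non-zero mean
motion effect would, with the FD–age correlation of this cohort and a weakly
identified $\rho$, leak into $\beta_\mu$ — users simulating that regime
should widen the $\rho$ prior accordingly.

**Cross-modal coupling.** A latent standard-normal nodal aging factor can be
mixed into edge $\beta_\mu$ (weight `fc_coupling`) and into nodal BP/GMD
$\beta_\mu$ (weights `bp_coupling`, `gmd_coupling`), preserving each
marginal distribution while inducing correlated nodal aging effects across
modalities. The study default (0.6 / 0.6 / 0.3) yields nodal FC–BP
correlations in the 0.3–0.6 range at 60 nodes.

**BOLD time series** (`simulate_timeseries()`): multivariate normal series
whose population correlation matrix is $\tanh$ of the target z matrix.
Edge-marginal targets need not be jointly realizable, so the target is
projected to the nearest correlation matrix (`Matrix::nearPD`) and the
projection distance is reported. AR(1) white-matter and CSF signals are mixed
into every ROI; motion is a random-walk jitter plus seeded spikes that both
step the motion trace (so FD flags them) and inject a shared signal burst
into all ROIs (so scrubbing and GSR have something real to remove).

**PET curves** (`simulate_tac()`): the reference (cerebellar) curve is a
bi-exponential bolus; the target follows the simplified reference tissue
model (SRTM) with known DVR, solved in closed form as a sum of exponentials
and averaged exactly over each acquisition frame. The default schedule is 18
frames (9 × 2, 3 × 3, 3 × 4.2, 3 × 5 min; 54.6 min total).

**What the generator does *not* emulate:** hemodynamic response shapes, task
structure, spatial autocorrelation and parcellation geometry, distance
dependence of motion artifacts, PET attenuation/scatter/reconstruction, and
any longitudinal within-person dynamics. Passing tests therefore demonstrate
correctness of the estimators and analyses under the stated generative model,
not robustness to every artifact of real scanner data.

# Pipeline and numerical choices

* **Order of operations**: nuisance regression → band-pass → correlation on
  scrubbed frames (scrubbing acts as frame selection at the correlation
  step). The stage order inside integrated preprocessing toolboxes is not
  uniquely standardized; this order is a documented package choice.
* **FD** uses backward differences, rotations converted by a 50 mm head
  radius, first frame 0. Motion files carry translations in mm, rotations in
  radians.
* **Scrubbing** removes each flagged frame, 1 before and 2 after, windows
  clipped at the ends. Inclusion rules are applied exactly as stated per
  protocol: task runs need *at least* 300 surviving volumes, short
  resting-state runs *more than* 130.
* **Confound model**: intercept, 6 motion parameters, their backward-difference
  derivatives (first row 0), the squares of those 12, WM and CSF; with GSR,
  the global mean as well (the plain mean only — no derivative or square).
  Collinear columns are dropped with a warning.
* **Band-pass** is a zero-phase frequency-domain ideal mask over
  0.009–0.1 Hz (DC removed). The contract is stated in passband/stopband
  terms, so an IIR implementation would also satisfy it. Note that ideal
  masks ring: residual spike energy is smeared over neighboring frames, which
  is one reason scrubbing windows extend beyond the spike itself.
* **Fisher transform**: $r$ is clamped at $\pm(1 - 10^{-7})$ before
  $\mathrm{arctanh}$, so duplicated ROIs produce a large finite z rather than
  infinity. The diagonal is stored as 0 and excluded from every analysis.
* **Similarity and MDS**: similarity is the Pearson correlation of
  upper-triangle z vectors; dissimilarity for MDS is $1 - r$, the minimal
  monotone transform (configurable by passing dissimilarities directly).
  Classical (Torgerson) MDS double-centers squared dissimilarities and
  truncates negative eigenvalues to zero; when fewer positive eigenvalues
  exist than requested dimensions, the extra coordinates are zero and a
  warning is emitted. Group-contrast t tests are Welch tests on
  pair-similarity sets; pair similarities sharing a subject are not
  independent, so these tests are descriptive summaries of a common
  procedure, not exact inference.
* **Connection removal**: edges are ranked by absolute value with ties broken
  by edge index for reproducibility; the random baseline takes a seed.
* **Logan analysis**: frame activities are treated as located at frame
  midpoints; integrals are trapezoidal from $(0, 0)$; window membership is by
  midpoint in $[18, 55]$ min. The non-invasive form without the $k_2'$
  intercept-correction term is the default (a `k2_ref` argument adds the
  term for sensitivity analyses). On proportional curves the slope equals the
  activity ratio to machine precision; on noiseless SRTM curves with the
  default kinetics ($R_1 = 1$, $k_2 = 0.15$/min, BP = 1.5) the estimate sits
  within 5% of the true DVR, with the small negative bias characteristic of
  graphical methods at finite equilibration times.
* **Determinism**: every generator takes a seed, restores the caller's RNG
  state, and the workbench derives stage seeds from one global seed, so a
  `study_config` fully determines all numerical output (the run manifest
  records per-stage checksums).

# Problem sizes

The packaged synthetic study uses 60 subjects and 60 nodes (1,770
connections), the scale at which the similarity structure is stable and the
whole pipeline — generation, 1,770 MAP fits, similarity and removal curves,
3,600 Logan fits, nodal fits for BP and GMD, and the cross-modal models —
runs interactively on one core. Parameter-recovery checks use 500 connections
at the 60-subject design; consistency checks across repeated noisy
realizations use smaller graphs. All sizes are configuration, not constants.

# The workbench interface

This package is used from R: `run_synthetic_study()` executes the stages in
dependency order with one global seed, `validate_inputs()` checks tabular
inputs against their contracts without aborting, and the I/O helpers
(`write_connectome()`, `write_motion()`, `write_table_tsv()` and readers)
define the plain-TSV interchange formats. These functions, with this
vignette, are the package's operational surface; no shell entry point is
shipped.

# Limitations

Cross-sectional group differences bound what any of these estimates can say
about within-person aging. The Welch tests on pair similarities ignore pair
dependence. The heteroscedastic MAP fit assumes Gaussian residuals; heavy
tails would bias $\beta_\sigma$ upward in older groups. Logan DVR carries a
noise-dependent negative bias; the package reports $R^2$ and point counts so
users can screen fits. The generator's nearest-correlation projection slightly
perturbs extreme target structures (the projection distance is reported for
exactly this reason).
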