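---
title: "Models and methods: PPI estimation and test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: PPI estimation and test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppirel)
```

## The scientific problem

A psychophysiological interaction (PPI) coefficient quantifies how much
an experimental condition changes the coupling between a seed region's
BOLD signal and a target region. If such a coefficient is to serve as an
individual-level marker -- for instance, fronto-amygdala coupling during
emotional face processing as a candidate predictor of treatment response
-- it must be *reliable*: a subject measured twice should get similar
values. This package implements the full measurement chain (task design,
HRF convolution, per-run PPI GLM) together with a two-way mixed-effects
intraclass-correlation (ICC) battery that quantifies between-day and
within-day reliability, and a synthetic-study generator in which the
*true* reliability is known analytically, so every stage of the chain can
be validated end to end.

## Task designs

Three emotional face-processing designs are encoded by `task_spec()`:

* **EI** (emotion identification): event-related; 60 face trials (20
  happy, 20 fearful, 20 neutral) over a 4:03 run. Stimulus duration and
  inter-trial timing are not part of the design's definition here, so the
  package defaults to 2-s stimuli with uniformly jittered inter-trial
  fixation rescaled to fill the run; both are configurable fields of the
  spec, and the trial order and jitter are reproducible from a seed.
* **FM** (face matching): blocked; five 30-s blocks (three shape-matching,
  two face-matching, six 5-s trials each) over 5:55, laid out
  deterministically with equal inter-block fixation.
* **GC** (gender classification): blocked; twelve 16-s blocks of eight 2-s
  face stimuli (happy/fearful/neutral, four blocks each) over 6:24.

Acquisition uses a long TR of 3.132 s; the number of volumes is the
smallest count covering the run. The microtime resolution defaults to
TR/16, and scan-resolution regressors are sampled at scan onsets (no
slice-offset modelling: preprocessing is out of scope here).

The task contrast is *faces > fixation* for EI and GC (an indicator over
face events) and *faces > shapes* for FM (+1/-1 over the two block
types). The psychological code is contrast-coded **before** mean-centering
and centered over the full run, the zero-centered convention appropriate
for PPI interaction terms.

## The generative model

`simulate_run()` produces one subject-run at scan resolution:

$$s(t) = a\,x(t) + \varepsilon_s(t), \qquad
  y(t) = \beta_0 + \lambda\, s(t) + \gamma\, x(t)
  + b\,[s(t) - \bar s]\,\psi(t) + m(t)^\top\theta + \varepsilon_y(t)$$

where $x$ is the double-gamma-convolved task regressor, $\psi$ the
centered psychological code, $m$ six motion nuisance series (smooth
random walks), and $\varepsilon$ AR(1) noise with coefficient $\phi$ and
stationary SD $\sigma$. The interaction is injected at the BOLD level --
exactly the term the default estimator models -- so that the estimator is
*conjugate by construction*: with target noise off, the fitted
interaction coefficient equals the injected $b$ to numerical precision.
An optional neural-level mode instead forms the interaction on the
microtime boxcar before convolution, for studying the mismatch between
the two PPI formulations (see below). No cardiac/respiratory confound is
simulated: physiological noise is a concern chiefly for resting-state
coupling measures, much less so for task-locked PPI terms.

The per-cell coupling coefficient decomposes as

$$b_{i,d,r} = \mu + u_i + v_{i,d} + w_{i,d,r}, \quad
  u_i \sim N(0, \sigma_s^2),\;
  v_{i,d} \sim N(0, \sigma_d^2),\;
  w_{i,d,r} \sim N(0, \sigma_r^2),$$

so the latent single-measures consistency ICC of any battery cell is
available in closed form (`true_icc()`): e.g. between-day on run averages
is $\sigma_s^2 / (\sigma_s^2 + \sigma_d^2 + \sigma_r^2/2)$, and within-day
is $(\sigma_s^2 + \sigma_d^2)/(\sigma_s^2 + \sigma_d^2 + \sigma_r^2)$.
Average-measures values follow by the Spearman-Brown step-up
$k\rho / (1 + (k-1)\rho)$ over the $k = 2$ sessions of a battery matrix;
the F-based confidence bounds map between the two parameterisations by
the same transform, so CI coverage statements are identical either way.

### Default study conditions

The default `study_config()` emulates a 29-subject study, two scan days,
two runs of each of the three tasks per day, three seed regions (left and
right amygdala, sgACC) against a dorsomedial frontal/cingulate target.
Defaults that the design left open were fixed once, on field-typical
grounds:

* Variance components $\sigma_s^2 = 0.09$, $\sigma_d^2 = 0.03$,
  $\sigma_r^2 = 0.045$: a between-day run-averaged true ICC of about
  0.62 and within-day about 0.73, inside the moderate-to-excellent range
  that task-fMRI coupling studies typically report.
* Mean couplings per task/seed patterned so that EI has a robust positive
  group effect for all three seeds, GC a negative amygdala effect with a
  null sgACC, and FM no effect anywhere -- reproducing the qualitative
  gating pattern (which seeds get "Not analysed") of the motivating
  study design.
* Seed AR(1) noise SD 0.5 with $\phi = 0.3$; target noise SD 0.3; subject
  amplitudes $a_i \sim N(1, 0.1^2)$; behavioural accuracy 0.91 (EI) and
  0.94 (GC), feeding the GC error regressor.
* Each seed region is an independent seed-target channel. A shared
  target would make single-seed PPI fits mis-specified by construction
  (the other seeds' interaction terms are collinear with the fitted one
  when noise vanishes), confounding reliability behaviour with model
  mismatch; independent channels keep every cell exactly estimable.
  Real-data ingestion accepts a shared `target` column.

## Estimation

`fit_ppi_run()` extracts the seed course (voxel mean or unit-variance
first eigenvariate, optionally restricted to activation-suprathreshold
voxels; a seed with no suprathreshold voxel raises a typed condition and
the subject is flagged excluded for that seed), builds the design
`[interaction, seed, task, 6 motion, (error), (drift), intercept]`, and
fits by OLS. Key numerical choices:

* **BOLD-level vs neural-level PPI.** The default forms the interaction
  directly on the observed seed course. The optional `neural` mode
  deconvolves the seed to a microtime neural series by ridge-regularised
  least squares (the scan-to-microtime system is underdetermined, so a
  positive penalty is required; the DC level is absorbed by a jointly
  fitted unpenalised intercept, since a causal HRF cannot generate the
  signal's baseline at early scans), multiplies by the microtime
  psychological code and reconvolves. Both modes are legitimate PPI
  formulations in the literature; both are shipped and the mode is
  recorded in the output, with no claim that either is "the" reference
  implementation.
* **Rank deficiency.** With all noise switched off the seed is exactly
  proportional to the task regressor; the fit falls back to the
  minimum-norm pseudo-inverse solution with a warning. The interaction
  column never participates in such collinearity, so its coefficient
  remains uniquely determined -- which is why noise-free recovery is
  still exact.
* **Error regressor.** Built only for GC and only when the subject made
  at least one error (convolved incorrect-trial events).
* **Drift.** A discrete-cosine high-pass basis (`dct_highpass()`, default
  cutoff 128 s) is available but off by default: the synthetic data carry
  no scanner drift unless requested.
* **No prewhitening.** Estimation is plain OLS; AR modelling of residuals
  is out of scope.

## Group statistics and the reliability battery

Per task and seed: a one-sample t on subject-level run-averaged betas
(the overall PPI effect), Cohen's d in two variants (ROI-mean, and
voxelwise-averaged across the target ROI -- identical when voxel noise is
zero), and a 2x2 day-by-run repeated-measures ANOVA in which each
one-degree-of-freedom effect is the squared paired t of the corresponding
within-subject contrast, with listwise deletion of incomplete subjects.
The Fisher-z sample-size helper reproduces the conventional n = 26 for
80% power to detect r = 0.5 at two-tailed alpha = 0.05 under the
no-correction, nearest-rounding convention; the `plus3` correction and
ceiling rounding are available, and the convention in force is an
explicit argument.

`reliability_battery()` computes five ICC cells per task/seed: between-day
on per-day run averages, between-day on run 1 only, on run 2 only, and
within-day (run 1 vs run 2) for each day. The ICC family is fixed to
two-way mixed-effects *consistency* (session effects fixed and absorbed,
subject effects random): single measures
$(BMS - EMS)/(BMS + (k-1)EMS)$ and average measures $(BMS - EMS)/BMS$,
with $F = BMS/EMS$ on $(n-1, (n-1)(k-1))$ df, one-tailed p (the
alternative is ICC > 0, the reliability convention), and 95% CIs through
the standard F-quantile bounds with $\alpha/2$ per tail (lower bounds may
legitimately be negative). Both measures are always computed and
reported side by side because study reports frequently mix the two
conventions; the battery's headline defaults to average measures, and
every cell records which convention filled it. Interpretation bands are
the conventional poor (< 0.4) / moderate-to-good (0.4-0.75, bounds
included) / excellent (> 0.75).

Gating is on by default: a task/seed whose overall group PPI effect is
not significant (p >= 0.05 on the 4-run averages) is marked
"not analysed" rather than given an ICC, since reliability of a
non-effect is not interpretable; the gate and its alpha are options.
Each battery cell drops incomplete subjects independently, so a missing
day-2 run does not discard a subject's within-day-1 comparison; drops
are counted per cell. A constant matrix has no defined ICC and the cell
is marked not computable; a perfect-consistency matrix (EMS = 0) returns
ICC exactly 1 with a degenerate CI and a flag.

## What the tests do and do not show

The synthetic generator emulates the *statistical structure* of a
multi-session task-fMRI study -- layout, task timing, HRF dynamics, AR(1)
noise, motion nuisance, variance components of the coupling -- but not
scanner artefacts (spikes, drift fields, susceptibility dropout),
slice-timing effects, physiological confounds, or whole-brain spatial
structure. Green tests therefore demonstrate that the estimation and
reliability machinery is correct and calibrated *given* data of this
form; they do not certify reliability magnitudes for any real scanner or
population, and the headline ICCs of any particular empirical study are
not reproducible without its scans.

Problem sizes used by the validation suite were chosen to make
Monte-Carlo error small relative to the tolerances checked: 2000
simulated 29-subject null studies for test size, 500 runs for estimator
bias, 200 subjects for ICC point recovery, 1000 replicates at n = 29 for
CI coverage, and 200 random matrices against the brute-force ICC oracle.

## A worked example

```{r example, eval = FALSE}
cfg <- study_config(n_subjects = 29)
res <- pipeline_run(cfg, out_dir = "ppi-report", rng_seed = 42)
subset(res$reliability, analysed,
       select = c(task, seed, cell, icc, ci_low, ci_high, p, band))
```

The run writes `betas.csv` (one PPI beta per subject x task x seed x day
x run), `stats.json` (group tests), `reliability.csv` (the battery) and
`decisions.json` (every analysis default in force) under the output
directory, all stamped with the master seed; re-running with the same
seed reproduces the outputs byte for byte.

## Known limitations

* OLS only; temporal autocorrelation inflates no test here because the
  synthetic noise enters both generator and estimator consistently, but
  real-data p-values at the run level would be anticonservative without
  prewhitening.
* The event-related design's trial timing is a configurable convention,
  not an empirical reconstruction.
* Deconvolution-mode estimates carry a small ridge-induced attenuation
  (about 3% at the default penalty on blocked designs).
* Absolute-agreement and one-way ICC families are deliberately not
  offered; the battery is consistency-only.
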