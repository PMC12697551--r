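---
title: "Calibrating covariate-dependent reference intervals with split conformal prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating covariate-dependent reference intervals with split conformal prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcal)
library(dplyr)
```

## Setting and validity

A reference interval for a continuous phenotype is a covariate-dependent
band $C(X) = [L(X), U(X)]$ intended to contain a healthy observation with
probability $1 - \alpha$, with the miscoverage split evenly across tails:
for a new observation $(X_{n+1}, Y_{n+1})$ from the target population we
require

$$P\{Y_{n+1} \le L(X_{n+1})\} \le \alpha/2
  \quad\text{and}\quad
  P\{Y_{n+1} \ge U(X_{n+1})\} \le \alpha/2 .$$

We call an interval with these properties *valid* at level $\alpha$. The
per-tail form is stricter than only controlling the total outside fraction:
a band that always misses low and never misses high can have the right
total false positive rate while being useless for detecting abnormally low
values.

The difficulty in practice is that the band is fitted on *reference* data
(one study, scanner, and preprocessing pipeline) and applied to a *new*
sample whose conditional distribution $Y \mid X$ differs — in neuroimaging
this happens whenever acquisition or preprocessing changes. The fitted
quantile curves then stop being the target population's quantiles and
validity fails, sometimes spectacularly.

## The calibration step

Suppose we have the fitted naive band
$\tilde C(X) = [\hat q_{\alpha/2}(X), \hat q_{1-\alpha/2}(X)]$ and a
calibration sample $(X_i, Y_i)$, $i = 1, \dots, n_C$, drawn from the same
population as future observations (and exchangeable with them). Define
per-tail conformity residuals

$$E_i = \hat q_{\alpha/2}(X_i) - Y_i, \qquad
  R_i = Y_i - \hat q_{1-\alpha/2}(X_i),$$

so a record inside the band has both residuals negative. The calibration
constants are the split-conformal empirical quantiles

$$\hat c = E_{(k)}, \qquad k = \lceil (1 - \alpha/2)(n_C + 1) \rceil,$$

taken separately on $\{E_i\}$ and $\{R_i\}$ (the $k$-th order statistic).
The calibrated band is

$$\hat C(X) = [\hat q_{\alpha/2}(X) - \hat c_{\alpha/2},\;
               \hat q_{1-\alpha/2}(X) + \hat c_{1-\alpha/2}].$$

Exchangeability of the calibration residuals with the new observation's
residual gives the per-tail guarantee above, with the usual split-conformal
upper bound: each tail's miscoverage also exceeds
$\alpha/2 - 1/(n_C + 1)$ when the residuals are continuous. Nothing is
assumed about the reference distribution, the model family behind
$\hat q_\tau$, or the size of the reference data — and the reference data
themselves are not needed, only the two bound functions. That makes the
procedure compatible with privacy-constrained chart sharing: the package's
gridded CSV format carries the bounds (and, for calibrated charts, the
constants and their provenance) with no subject-level information.

Implementation notes, all of which matter in edge cases:

* **Tail-level convention.** `reform_calibrate(tail_level = "half_alpha")`
  (the default) computes each constant at level $1 - \alpha/2$, which is
  what the per-tail validity definition requires. A `"full_alpha"` option
  computes them at $1 - \alpha$ instead; it yields narrower bands that
  target $\alpha$ per tail and is provided for comparison with that older
  convention.
* **Order-index overflow.** When
  $k > n_C$ — e.g. a 99% band with $n_C \le 199$ under the default
  convention — no finite order statistic attains the requested level. The
  default (`overflow = "max"`) falls back to the largest residual and
  counts the event in `overflow_events`; `overflow = "infinite"` returns an
  unbounded adjustment, preserving the guarantee at the price of a vacuous
  bound. In this regime the calibrated band inherits the full variability
  of the sample extremes, which is why large calibration sets are advised
  for 99% intervals.
* **Ties.** The $k$-th order statistic is deterministic; no randomized
  tie-breaking. The guarantee assumes continuous residuals, which holds for
  continuous phenotypes.
* **Crossed bounds.** Because the two constants are estimated separately, a
  heavily miscalibrated naive band can produce $\hat L > \hat U$ somewhere.
  The package warns (probing a 101-point age grid per sex), records the
  fact in the interval's provenance, and retains the crossed bounds —
  clamping them would silently break the guarantee. Membership
  classification treats values on a bound as outside, and under crossed
  bounds nothing is inside.

`residual_diagnostics()` summarises both residual clouds (moments,
quantiles, fraction positive, histograms). The constant-shift adjustment is
ideal when the reference-to-target difference is an additive shift per
tail; large one-sided residual masses or strong age trends in the residuals
indicate that the calibrated band will be valid but possibly far from the
target population's true quantiles — validity and quantile recovery are
different goals, and this method promises only the former.

## Naive interval models

`fit_lss()` estimates a four-parameter Box-Cox $t$ distributional
regression: the phenotype's location $\mu(x)$ (identity link) and log-scale
$\log \sigma(x)$ are each a cubic B-spline smooth of age (10 interior knots
at age quantiles, second-order difference penalty, weight $\lambda = 1$)
plus a fixed sex offset; the skewness power $\nu$ and tail degrees of
freedom $\tau$ are constant. The penalized log-likelihood (including the
positivity truncation normaliser) is maximised by BFGS from a deterministic
initialisation (penalized least squares for $\mu$; residual coefficient of
variation for $\sigma$; $\nu = 1$, $\tau = 10$); convergence is declared at
a relative objective change of $10^{-8}$ or 200 iterations, and the
objective at initialisation is stored so descent is checkable. Interval
bounds are the fitted conditional BCT quantiles at $\alpha/2$ and
$1-\alpha/2$; bound evaluation outside the training age range extends the
spline as a constant.

`fit_aqr()` fits one conditional quantile curve by minimising the penalized
check loss with the same basis, via majorisation-minimisation (iteratively
reweighted penalized least squares with weights
$1/(4\max(|r_i|, 10^{-6}))$). The penalty weight defaults to `"auto"`:
a Schwarz-type criterion $n \log(\bar\rho_\tau) + \tfrac{\log n}{2}\,
\mathrm{df}$ over the grid $10^{-1}, \dots, 10^5$. We chose a
criterion-selected default after observing that any fixed unit penalty
undersmooths extreme quantile curves once $n$ reaches the thousands (the
check loss grows with $n$ while the penalty does not), producing boundary
wiggle of several hundredths where flat data should give a flat curve. A
95% band is formed from two independently fitted curves at $\alpha/2$ and
$1 - \alpha/2$; crossings are detected and warned about, not repaired,
mirroring how off-the-shelf quantile fitters behave.

Both fitters refuse fewer than 50 observations by default and surface all
failures as classed `refcal_fit_error` conditions.

## Comparator methods

*Refitting* (`refit_interval()`) abandons the reference chart and fits a
naive band in the calibration sample alone. *Harmonization*
(`fit_harmonizer()`) estimates a shared smooth-age + sex mean model with
per-batch location shifts, and per-batch scale either as a scalar SD ratio
(`scalar_scale`) or as covariate-dependent log-scale offsets via a Gaussian
location-scale GAM (`covariate_scale`); `apply_harmonizer()` then maps a
record onto the reference scale by
$y^* = m_{\mathrm{ref}}(x) + (y - m_b(x))\, s_{\mathrm{ref}}(x)/s_b(x)$.
The "reference" is the batch-average (pooled) model by default, or a
designated batch; batches unseen at fit time are rejected rather than
imputed, and no empirical-Bayes pooling across outcomes is used (single
outcome). *Batch-adjusted modelling* (`fit_batch_lss()`) fits the pooled
BCT regression with per-batch offsets in location and log-scale shrunk by a
ridge penalty (weight 50, corresponding to a prior SD of roughly 0.1
phenotype units — a deterministic stand-in for normal random effects); the
band for the target batch uses that batch's offsets. These represent the
three families the calibration method is usually compared against;
location-scale harmonization in particular matches means and variances but
not tails, which is exactly where reference intervals live.

## The synthetic generator

Real multi-site lifespan datasets of this kind are access-restricted, so
the package generates its own:

$$Y = \mu(\text{age}, \text{sex}) + \delta_b
      - \Delta\,[\text{group}=\text{CASE}]
      + \gamma_b\,\sigma(\text{age})\,\varepsilon,$$

with defaults $\mu = 3.8 - 0.012\,a + 4\times 10^{-5} a^2 +
0.05\,[\text{M}]$ (millimetre-scale, gently declining, as for cortical
thickness), $\sigma(a) = 0.12 + 0.0006\,a$, age uniform on 20–95,
45% male, disease effect $\Delta = 0.3$ with cases drawn from ages 55–95.
Noise $\varepsilon$ is standard normal by default, with Student-$t$ and a
standardised Box-Cox-$t$ family (`(B - 1)/0.2`, $B \sim
\mathrm{BCT}(1, 0.2, \nu, \tau)$) for heavy tails and skew. Batch effects
are additive shifts $\delta_b$ and scale multipliers $\gamma_b$. Three
presets encode the study designs the evaluation targets:
`exp1_large_shift` (reference +0.3 / ×1.5 versus test — a different-study,
different-field-strength situation), `exp2_small_shift` (+0.08 / ×1.1), and
`exp3_multisite` (22 reference sites with deterministic normal-score shifts
of SD 0.1 and log-scale spread 0.15, one test site, disease subgroup).
These values are configuration choices made once to emulate realistic
magnitudes; they are not estimates from any dataset.

What the generator does *not* emulate: longitudinal correlation,
non-uniform age pyramids, covariate shift between calibration and
validation, or measurement floor/ceiling effects. Passing tests on this
generator therefore demonstrate the distribution-free guarantee and the
relative behaviour of methods under location-scale and skew shifts — not
performance on any particular real cohort.

Randomness is controlled by one master seed; every trial derives its own
stream through a fixed integer recurrence (`derive_seed()`, always below
$2^{31}$), so any single trial can be reproduced in isolation.

## The resampling harness

`run_experiment()` sweeps (reference size × calibration size × level ×
method) over seeded trials: each trial simulates a reference and a test
population, splits the test batch's healthy records into calibration and
validation (validation takes everything not drawn for calibration), fits
the naive band on the drawn reference set, applies every configured method,
and scores per-tail and total FPR on the shared validation records — plus
the positive rate on disease-group records when present. Method failures
become `status = "fit_error"` rows and are excluded-but-counted by
`summarize_trials()` (median and IQR per group). `wilcoxon_vs_target()` and
`wilcoxon_paired()` provide the standard significance checks; for 25 or
fewer nonzero differences the exact signed-rank null is enumerated by
convolution over midranks (so tied differences are handled exactly),
otherwise the normal approximation with continuity correction is used —
the choice of variant is this package's convention.
`fpr_window_filter()` restricts positive-rate comparisons to trials where
every method held its FPR within $\alpha \pm 0.2\alpha$.

Harness policy for the refit arm: refitting must run at calibration sizes
(40–160) far below what a 10-knot basis with unit penalty can support, so
the harness passes a lower minimum $n$ (20), an interior-knot budget of
$\min(10, \max(2, \lfloor n/40 \rfloor))$ and penalty weight 100. This
mirrors the strong default shrinkage that established distributional
regression fitters apply, and leaves refitting with its characteristic
behaviour: erratic and inflated at $n_C = 40$, adequate from about 160.

Problem sizes in the shipped tests and acceptance script were chosen to
keep a full run at desk scale: 500 trials with $n_C = 400$ and 1000
validation records for the coverage checks (Monte-Carlo SE on a mean FPR of
about $6\times10^{-4}$ at the 95% level), 200 trials for the directional
comparisons. At these sizes the conformal coverage bounds
$[\alpha - 2/(n_C+1) - 3\,\mathrm{SE},\ \alpha + 3\,\mathrm{SE}]$ are sharp
enough to detect a method that is even a few thousandths off target.

## Design choices that were genuinely open

* **Exchange format.** No standard exists for shipping fitted reference
  intervals, so the package defines one: a single CSV of
  (sex, age, lower, upper) rows on an age grid, `#`-metadata header with
  level, provenance, units and calibration constants. Values are printed
  with 17 significant digits and re-read with a correctly rounded parser,
  so write → read → evaluate reproduces bounds bit-exactly at grid nodes;
  between nodes the rebuilt interval is piecewise linear in age (101-point
  default grid keeps interpolation error far below measurement noise), and
  evaluation beyond the grid (plus a configurable margin) is an error
  rather than an extrapolation.
* **Boundary convention.** A value exactly on a bound is outside. This
  matches the $\le/\ge$ inequalities of the validity definition and makes
  the degenerate all-residuals-zero case conservative.
* **Smooth specification.** "A smooth age term with default settings" is
  under-determined; this package fixes cubic B-splines, 10 interior knots
  at age quantiles, second-order difference penalty, $\lambda = 1$ for the
  likelihood fitter and criterion-selected $\lambda$ for the quantile
  fitter, and documents them as its convention rather than a reproduction
  of any particular software's defaults.
* **Random effects by ridge.** Batch offsets shrunk by a fixed quadratic
  penalty replace integrated-likelihood random effects: deterministic,
  fast, and exhibiting the same shrinkage behaviour the comparison relies
  on; with the penalty weight sent to infinity the model collapses to the
  no-batch fit (a tested property).
* **Harmonization target.** When intervals fitted on the reference scale
  are applied to harmonized data, records are mapped to the (first)
  reference batch's scale; the pooled convention is the default everywhere
  else. The anchoring of the harmonized scale is a convention, not a fact
  about the data.

## Known limitations

Validity is marginal over age and sex, not conditional: a calibrated band
can still be mis-centred within an age decade while holding its overall
rate. The per-tail constants are single numbers, so covariate-dependent
distribution shifts are absorbed only on average. At the 99% level with
$n_C \le 199$ the default convention always overflows to the extreme
residual, with the attendant outlier sensitivity. The location-scale-shape
fitter holds $\nu$ and $\tau$ constant across covariates, and the quantile
fitter's two tails are estimated independently. None of these limitations
affect the finite-sample guarantee; they affect how close the calibrated
band is to the target population's true quantiles.
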