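---
title: "Growth-curve and fluorescence analysis of plate-reader time series"
author: "platekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve and fluorescence analysis of plate-reader time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platekit)
```

# The problem

Plate readers measure optical density (OD) and fluorescence in each well of a
96-well plate every few minutes for a day or more. Turning those raw traces
into quantities a microbiologist can interpret — specific growth rates, lag
times, gene-expression levels per cell — requires a chain of corrections and
a derivative estimate, each with an honest error bar:

1. OD is proportional to cell number only while the culture is dilute; at
   high density, multiply-scattered light escapes the detector and the
   reading saturates.
2. The medium itself absorbs and fluoresces; its contribution must be
   subtracted.
3. Cells fluoresce even without any fluorescent protein; this
   autofluorescence must be removed before GFP (or mCherry) levels mean
   anything.
4. The specific growth rate is a *derivative* of a noisy curve, and naive
   finite differences amplify noise catastrophically.

`platekit` implements this chain as composable steps on a three-table data
model (raw, processed, summary), with a run log for reproducibility, a
synthetic-plate generator with known ground truth, multi-plate averaging,
and Monod-curve fitting.

# The data model

A `plate_dataset` holds a *raw* table (exactly as loaded, never modified), a
*processed* table (transformed by each correction in turn) and, after
`get_growth_stats()`, a *summary* table with one row per
(experiment, strain, condition). Rows are tidy:
(experiment, well, strain, condition, time, signal, value). Wells are
annotated from an 8 x 12 contents grid whose cells read
`"STRAIN in CONDITION"`; the strain label `null` marks media-only wells, an
empty cell an unused well. (The grid-cell syntax is this package's
convention — any parseable convention would do; this one reads naturally and
survives CSV round trips.) Times are normalised to hours at load, and every
analysis call is appended to a plain-text run log.

# OD calibration

A dilution series of a dense culture provides pairs (measured OD, expected
OD), where expected OD is the dilution factor times the reference culture's
OD in arbitrary units. `fit_calibration()` fits a squared-exponential GP
with measured OD as input, evaluates the posterior mean on a 512-point grid,
projects it onto the monotone cone by isotonic regression (a correction
curve must be non-decreasing, but nothing in a GP enforces that), and
rescales by a single constant so that corrected and measured OD coincide at
0.3. The rescaling removes the arbitrary unit of the reference culture —
multiplying all expected ODs by any constant leaves the curve unchanged —
and restores the linear low-OD regime. Outside the calibrated range the
curve continues linearly: through the origin below (so blanks that
fluctuate around zero keep their sign and mean), with the terminal slope
above; both extrapolations warn. Fewer than 5 points, flat series, or
series in which measured OD does not increase with dilution factor are
rejected. A synthetic default series emulating haploid yeast in glucose is
shipped so `correct_od()` works without a user file; it is generated data,
labelled as such, not an instrument export.

# Media and autofluorescence corrections

`correct_media()` subtracts, per condition and signal, the
Savitzky-Golay-smoothed mean trace of that condition's media-only wells
from every well — including the media wells themselves, whose corrected
traces should then fluctuate around zero. The filter defaults (window 11
points, order 3, shrunk for shorter series) pass any cubic trend untouched
while removing most point noise. Wells are assumed to share one plate
clock, which is true within a plate.

Two autofluorescence corrections are provided, both anchored to an untagged
strain grown in the same conditions (at least 2 replicate wells enforced; 7
recommended for the untagged strain and 5 for tagged strains, since the
untagged data corrects everything else):

* **Linear unmixing** (`correct_gfp()`), for GFP: emissions are measured at
  525 nm (GFP's band) and 585 nm (mostly autofluorescence). With
  $r_a$ the untagged strain's emission ratio 585/525 as a function of OD and
  $r_g$ GFP's own (measured, constant) ratio, each replicate's corrected
  fluorescence is
  $$f_{corr} = \frac{r_a f_{525} - f_{585}}{r_a - r_g}.$$
  $r_a$ is estimated as the *ratio of the two smoothed emissions* versus OD,
  not the smoothed pointwise ratio: the pointwise ratio of noisy emissions
  is biased upward exactly where the signal is weakest ($E[1/x] > 1/E[x]$),
  and on synthetic plates that bias leaks a systematic ~1% spurious
  fluorescence into every corrected trace. The ratio of smoothed emissions
  is unbiased; this choice is verified by the untagged-strain zero-mean
  check below. The correction errors out when $|r_a - r_g| < 0.05\,r_a$
  anywhere it is evaluated, since the denominator would amplify noise
  unboundedly. `r_g` defaults to 0 and should be set to the measured value
  when available.

* **OD matching** (`correct_auto_by_od()`), for any fluorophore: the
  untagged strain's fluorescence, smoothed versus its OD, is interpolated
  to each tagged well's OD and subtracted. Tagged ODs outside the untagged
  range use the nearest value, with a warning.

Errors are variances over replicate wells; per-cell fluorescence divides
each replicate's corrected value by that replicate's OD before averaging.
Negative corrected values are retained — clipping would bias the
`untagged_consistency()` check, which corrects the untagged strain by the
same machinery and flags a time-averaged mean more than two standard errors
from zero.

# Growth-rate inference

The growth curve is the natural logarithm of OD (so rates are e-folding
rates in h⁻¹), and the specific growth rate $\mu(t) = d\ln OD/dt$. A single
GP is fitted to the pooled ln-OD points of all replicate wells of a group;
$\mu$ and $d\mu/dt$ come from the analytic derivative posteriors, never
finite differences.

Numerical and modelling choices that matter:

* **Kernel.** Matern 5/2 by default: the weakest standard smoothness
  assumption under which both $\mu$ and its derivative exist (sample paths
  exactly twice differentiable). Squared-exponential and neural-network
  kernels are available; the neural-network kernel supports only first
  derivatives.
* **Hyperparameters** (amplitude, length scale, noise sd) maximise the log
  marginal likelihood in log space with L-BFGS-B over 5 seeded random
  restarts; bounds default to $[10^{-4}, 10^4]$ times the data scale for
  amplitude and length scale and $[10^{-3}, 1]$ times the target sd for the
  noise. Above 250 points the search runs on an even stride through the
  data (cost is cubic in n); the final posterior conditions on everything.
  A jitter ladder ($10^{-10}$ to $10^{-6}$ of the mean diagonal) guards the
  Cholesky.
* **Heteroscedastic noise.** Measurement noise is roughly constant in OD,
  so ln-OD noise grows as OD falls — by an order of magnitude over a growth
  curve. With three or more replicate wells, the per-timepoint variance of
  ln OD across replicates is smoothed in the log domain and used as a
  relative noise profile in the GP; without it, the noisy early points
  visibly distort the fit.
* **Log-measurement debias.** The log of a noisy positive measurement is
  biased down by half its relative variance; the estimated profile adds
  this back, since otherwise the depressed early points steepen the
  apparent early slope.
* **Prior mean.** A least-squares line is subtracted before fitting and
  restored afterwards. A zero-mean GP shrinks the derivative posterior
  toward zero at the edges of the data window — exactly where a logistic
  culture's maximal growth rate sits.
* **Degenerate inputs.** Non-positive ODs after corrections are floored at
  half the smallest positive OD of the group, with a reported count; all
  non-positive, or fewer than 4 usable timepoints, is an error. Data before
  `t_min` (default 0) can be excluded; the first measurements of a run are
  often unreliable while the plate equilibrates.

`summarise_growth()` reports, per group: the maximal growth rate (grid
maximum of the posterior mean of $\mu$ on a 200-point grid), the local
maximal growth rate (the largest interior maximum, detected as a +/−
crossing of $d\mu/dt$ excluding the first and last two grid points, with
ties broken to the earliest time; reported missing when $\mu$ only peaks at
a boundary), the lag time (the t-axis intercept of the tangent to ln OD at
the time of maximal growth, measured from the initial ln-OD level, clamped
at zero — the classical tangent construction), and the maximal OD. The lag
and interior-maximum definitions are this package's declared, testable
choices; the field uses several.

**Errors** combine two seeded bootstrap components in quadrature: joint
posterior draws of $(f, f')$ — measurement noise propagated through the
fit — and a case bootstrap over replicate wells re-derived under the
fitted kernel — between-well variability the pointwise noise model cannot
see. On 21 synthetic logistic plates this combination gives 2-sigma
coverage of 0.90 for the maximal growth rate where posterior draws alone
give 0.81. Because the refitted hyperparameters adapt to the noise level
(noisier data is smoothed harder), these errors shrink *sub-linearly* when
the measurement noise halves — the measured ratio is about 0.75, not 0.5.

`stats_on_signal()` runs the same machinery on any signal (for example
corrected fluorescence per OD), with the log transform optional.

# Multi-plate analysis

Experiments merged with `merge_experiments()` keep their provenance.
`add_common_time()` builds a grid spanning the overlap of the experiments'
time ranges (spacing defaults to the median sampling interval) and
interpolates each well linearly onto it — linear, not GP, interpolation:
at plate-reader sampling density the O(spacing²) error is negligible, it is
monotone, and it does not double-smooth curves that will be smoothed again
downstream. No extrapolation ever. `average_over_experiments()` then gives
each plate one vote: replicate wells are pooled into a per-experiment mean
first, experiments averaged second (plate-to-plate variability is what the
sd reports, with an n−1 denominator; a single plate yields a missing sd,
never 0). `add_numeric_column()` parses the numeral attached
to a unit token out of condition labels ("0.35% raf" with token "% raf"
gives 0.35; in compound labels the numeral immediately preceding the token
wins; failures are counted and reported, never fatal).

# Monod kinetics and the glucose proxy

Mid-log growth rate versus limiting-nutrient concentration follows
$$\mu(S) = \mu_{max}\, S / (K_S + S).$$
`fit_monod()` does (optionally 1/sd²-weighted) least squares. Because the
model is linear in $\mu_{max}$ given $K_S$, $\mu_{max}$ is profiled out
exactly and only $\log K_S$ is searched — a 64-point grid bracket over
$[\ln \min S - 3,\, \ln \max S + 3]$ refined by golden-section search —
making the fit deterministic, positive by construction, and exact to
machine precision on noise-free data. Confidence intervals come from
seeded residual-resampling bootstrap. Fewer than three distinct
concentrations is an identifiability error.

`glucose_proxy()` estimates residual glucose from OD assuming a fixed
amount of glucose imported per division:
$$g(t) = g_0 \,(OD_{max} - OD(t)) / (OD_{max} - OD_{min}),$$
equal to the initial concentration $g_0$ at the start and zero at the
plateau. The OD extremes are taken from a Savitzky-Golay-smoothed copy of
the series by default so a single noise spike cannot set an endpoint. The
estimate is deliberately crude — a monotone re-parameterisation of time —
and is meant for plotting expression against approximate glucose, not for
kinetics. A helper converts percent w/v to mM (raffinose, anhydrous
504.4 g/mol, by default: 1.0% is 20 mM).

# The synthetic-plate generator

`synth_plate_spec()` + `generate_plate()` emit a data file and contents
grid in the documented dialect together with the full latent truth (every
well's OD and growth-rate function, true corrected fluorescence, spectral
constants). The default plate emulates a Monod experiment: 10 carbon
concentrations (0.05-2% w/v) in columns 1-10, seven replicate rows, a
media-only row H, 24 h at 10-minute sampling; per-well growth is logistic
with rate $\mu_{max} S/(K_S+S)$ at $\mu_{max} = 0.82\,h^{-1}$, $K_S = 1\%$,
inoculum OD 0.05, and carrying capacity rising with the sugar supplied.
The instrument response defaults to the invertible saturation
$2(1 - e^{-x/2})$ — strong enough that skipping calibration is visibly
wrong — plus a media baseline of 0.04 OD and Gaussian noise (sd 0.01 OD).
The `gfp` preset adds two emission channels with OD-proportional
autofluorescence (ratio $r_a = 2$), GFP at 60 units per OD with
$r_g = 0.1$. A fixed seed gives byte-identical files.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: evaporation and condensation, spatial plate
gradients, well-to-well optical cross-talk, non-Gaussian outliers,
drifting instrument gain, and biological heterogeneity beyond iid noise.
Real blanks drift; real replicates disagree for reasons other than shot
noise. The tests demonstrate that the algorithms recover known truth under
the stated noise model, not that any instrument obeys that model.

One instructive artefact the generator does reproduce: with a single
media-only well per condition, the blank's smoothed noise is subtracted
coherently from every replicate, and for slow-growing cultures near the
inoculum OD this correlated perturbation dominates the growth-rate error.
That is a real experimental-design lesson (use several blanks), and it is
why the end-to-end round-trip test budgets a wider tolerance for its
lowest-concentration condition.

# Problem sizes used by the test-suite and verification runs

Simulation-heavy checks run on plates of 7 replicate wells sampled every
30 minutes for 24 h (343 pooled points per GP fit): 12-18 seeded logistic
plates for growth-rate recovery (median relative error of the maximal
growth rate under 5% at noise sd 0.01 OD), 50 seeded plates for the
untagged zero-mean fluorescence check, 50 seeded trials of the two-plate
Monod design (10 concentrations x 14 replicate rates, noise 0.02 h⁻¹;
both parameters within 10% in at least 90% of trials), and bootstrap sizes
of 60-100 draws. These sizes were chosen so the whole suite completes in a
few minutes while leaving each statistical assertion comfortable margins.

# Known limitations

* A single stationary length scale must serve the whole curve. Where growth
  switches on abruptly (a hard lag-to-exponential transition), the kernel
  rounds the corner and the peak growth rate is biased downward by roughly
  10-20% on synthetic plates with a discontinuous lag; real transitions are
  smoother, but sharp features are still flattened.
* Monod parameters estimated from one pair of plates are ill-conditioned:
  when the highest concentration only reaches about twice K_S, mu_max and
  K_S trade off along a ridge and small systematic rate errors move both
  substantially. The bootstrap intervals are wide exactly when this
  happens; believe them.

* Exact GP inference only: cost is cubic in the number of points (the
  hyperparameter search subsamples above 250 points, the posterior does
  not). Plates pooled far beyond ~2000 points per group will be slow.
* The GP noise model is independent between timepoints; slowly varying
  correlated errors (e.g. condensation clearing) are absorbed into the
  signal, not the noise.
* One fluorophore at a time; no multi-fluorophore spectral unmixing.
* The plate-reader dialect is the documented block format plus programmatic
  assembly via `plate_dataset()`; vendor binary/spreadsheet exports must be
  converted upstream.
* Hyperparameter uncertainty is not propagated into posterior bands; the
  replicate-well bootstrap compensates empirically (coverage 0.90 on the
  synthetic benchmark) but is not a substitute for a full marginal.
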