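---
title: "Steady-state PERG analysis: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state PERG analysis: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pergss)
```

## The measurement and its analysis

The pattern electroretinogram (PERG) is the retinal response to a
contrast-reversing checkerboard, dominated by ganglion-cell activity. At
high reversal rates (here 12.5 and 18.75 reversals per second) the
response becomes steady-state: a quasi-sinusoidal oscillation at the
reversal frequency, analyzed in the frequency domain rather than as
discrete peaks. Reduced steady-state PERG amplitudes — strongest for
fine check patterns — have been reported in major depression, making the
PERG a candidate objective marker of reduced retinal contrast gain.

This package implements the complete analysis chain for a two-group
(patients vs. matched controls), fully crossed repeated-measures design:
4 check sizes (0.8°, 1.6°, 3.2°, 16°) × 2 reversal rates × 2 eyes, with
12 subjects per group. Because such cohort recordings are not publicly
available, the package pairs the analysis with a synthetic-data
generator that emulates the cohort's statistical structure, so every
stage is testable against known ground truth.

## Signal model and preprocessing

A recording for one subject/eye/condition is a block of fixed-length
sweeps (0.96 s at 500 Hz, i.e. 480 samples). The simulated sweep is

$$v(t) = A \sin(2\pi f t + \varphi) + a + b\,t + \varepsilon(t)
  \;[+\ \text{artifact spike}],$$

with $f$ the reversal rate, $\varphi = -2\pi f\,\tau/1000$ for response
time $\tau$ in ms, iid Gaussian sample noise $\varepsilon$, per-sweep
affine drift, and (with a configurable probability) one large
single-sample artifact. Only the fundamental is simulated: the analysis
reads a single frequency bin, so harmonics would add nothing the
pipeline can see, and a single sinusoid is the minimal structure that
exercises every stage. The sampling rate is a package choice (vendor
hardware rates vary); 500 Hz gives integer samples per sweep and a
Nyquist far above the 40 Hz band of interest.

Preprocessing follows the conventional order: artifact rejection,
stimulus-synchronized averaging, low-pass filtering, detrending.

* **Artifact rejection** removes any sweep whose maximum absolute
  voltage exceeds 120 µV. The criterion is deliberately the simplest
  reading of an amplitude threshold; a peak-to-peak variant is available
  but not default.
* **Averaging** is the pointwise mean. Sweeps contain an exact integer
  number of stimulus cycles (12 or 18), so averaging is phase-preserving.
* **The low-pass filter** is an ideal mask in the discrete Fourier
  domain: components strictly above 40 Hz are zeroed, everything else is
  untouched. A brick-wall mask is reproducible bit-for-bit, idempotent,
  and cannot distort the analysis bins, unlike IIR/FIR realizations with
  ripple and phase delay. Its known weakness — ringing around non-aligned
  interference — is immaterial here because the readout is confined to
  one exact bin.
* **Detrending** removes an affine baseline $a + b t$. A subtlety: a
  finite sinusoid segment is not orthogonal to a ramp, so the plain
  least-squares affine fit absorbs up to ~0.4 % of the response
  amplitude. The pipeline therefore estimates the trend jointly with
  sine/cosine regressors at the analysis frequency (`protect_hz`),
  which still annihilates affine drift exactly but leaves bin-aligned
  response content untouched. `detrend_linear()` used standalone
  defaults to the plain fit (zero mean, zero slope output).

With the default order (filter, then detrend) a residual of order
10⁻³ µV can remain when strong affine drift is present, because the
filter truncates the drift's high-frequency tail before the trend fit;
detrend-first (`detrend_first = TRUE`) removes pure affine drift
exactly. For noiseless, drift-free signals the composite chain is
amplitude-preserving at the analysis bin to machine precision — this is
asserted in the test suite.

## Spectral readout

The response is the DFT component at bin $k = f \cdot T$ (12 or 18 for
$T = 0.96$ s): amplitude $2|X_k|/N$ in µV (peak convention — the number
a steady-state ERG report quotes), phase as the equivalent sine phase in
$(-\pi, \pi]$. No window/taper is applied: the sweep holds an integer
number of cycles, so rectangular analysis is leak-free at the analysis
bin. The noise estimate is the mean amplitude of the two directly
adjacent bins, which carry no response. Noise correction defaults to
magnitude subtraction floored at zero (`linear`); a power-domain
variant (`power`, $\sqrt{A^2 - N^2}$) is provided because the
literature's estimator family admits both; the choice is recorded in
the run log. Note that noise correction is conservative: it subtracts
the (Rayleigh-distributed) noise floor from every amplitude, biasing
amplitudes downward by the same small amount in both groups (visible
as a mean −0.04 µV offset in the default simulation).

## Phase to response time

A phase measured at frequency $f$ determines latency only modulo the
stimulus period (80 ms at 12.5 rps, 53.3 ms at 18.75 rps). The package
resolves the ambiguity with a single window rule: report the unique
$t_0 + k\,P$ inside $[w, w + P)$ with default $w = 30$ ms. Reported
steady-state PERG times (~40–57 ms) fall comfortably inside this window
for both rates, and uniqueness makes the rule total and deterministic.
Per-condition windowing is used rather than cross-condition phase
continuity chains; continuity unwrapping is a possible extension for
pathological data but is not needed in the simulated regime.

## Synthetic cohorts

The generator has two layers. The cohort layer draws per-subject,
per-eye, per-condition *true* amplitudes and times:

$$y_{s,e,c} = \mu_{g(s),c} + u_s + w_{s,c} + \eta_{s,e,c},$$

with group × condition means $\mu$ defaulting to published group-level
summary tables (µV and ms), a subject random effect $u_s$ shared across
all conditions (inducing within-subject correlation; SD 0.3 µV / 1.5
ms), a cell deviate $w$ shared by both eyes, and eye-level jitter $\eta$
(SD 0.2 µV / 1 ms). The printed per-cell SDs are treated as the *total*
between-subject SD, so the cell deviate's SD is
$\sqrt{\mathrm{SD}^2 - \mathrm{SD}_{\text{subject}}^2}$ (floored at a
small positive value). Amplitudes are floored at 0.05 µV — they are
magnitudes. The subject-effect SDs are a package choice: the source
tables publish only marginal SDs, and no covariance structure is
reported; the chosen values give the within-subject correlation
(≈ 0.2–0.4 across cells) typical of steady-state evoked amplitudes.
The sweep layer then realizes each true (amplitude, time) pair as raw
sweeps under the signal model above.

What the generator does *not* emulate: harmonic content, non-stationary
noise, eye blinks with structured shape (artifacts are single-sample
spikes — sufficient for a max-|v| rejection rule), luminance/contrast
physics, or any dependence of latency variability on amplitude. Passing
tests therefore certify the *analysis machinery* — not that real PERG
recordings satisfy the generator's assumptions.

## Inference layer

Eyes are averaged per subject and condition (a single available eye
passes through). The core test is a split-plot (mixed) repeated-measures
ANOVA implemented from sums of squares: group is between-subject,
check size and rate are within-subject, and each effect is tested
against its own stratum error (subjects within groups for the group
effect; effect × subject-within-group for each within effect and its
group interaction). Greenhouse–Geisser $\varepsilon$ is computed per
within effect from the pooled within-group covariance of its orthonormal
contrast scores and applied multiplicatively to both dfs; for 2-level
effects $\varepsilon = 1$. The implementation is deliberately first-
party — the decomposition *is* the method here — and is cross-checked in
the tests against base `aov()` error strata and `car::Anova`'s
univariate repeated-measures output.

Post-hoc group contrasts per condition use the raw difference of group
means (equal to the estimated-marginal-mean contrast in a balanced
design) with **one pooled SE** for all conditions, obtained by pooling
all four error strata into a single mean square, and t tests on the
summed error df. This matches the single printed SE per results table in
the replicated design; the exact pooling used by the original analysis
software is not documented, so the choice is explicit, logged in the run
output, and confined to one function. Effect sizes are Hedges-corrected
Cohen's d on the pooled SD, signed control-minus-patient so positive
values mean patient reductions; familywise error is controlled with
Bonferroni–Holm at $\alpha = 0.05$. Wilcoxon rank-sum/signed-rank
helpers (exact for small untied samples) cover the pooled comparisons.

The check-size ratio — amplitude at 0.8° over amplitude at 16°, a
normalization borrowed from early-glaucoma screening — is computed per
subject and rate with a 0.05 µV denominator floor (flagged when it
engages), then analyzed with a one-within-factor split-plot ANOVA
(group × rate) and per-rate contrasts.

## Numerical and calibration choices

* Degenerate inputs: all-equal responses give SS = 0 everywhere,
  reported as F = 0 with p = 1; zero within-effect contrast covariance
  returns $\varepsilon = 1$ (sphericity is moot).
* All randomness flows from explicit integer seeds; identical
  config + seed reproduces every output byte-for-byte.
* The replication suites run at the study's size (n = 12 per group):
  200 replicate cohorts for null calibration (group-test rejection
  0.05 ± 0.04) and for recovery of a uniform 20 % patient deficit, and
  100 cohorts for the ratio mechanism (a deficit that shrinks with
  check size at 18.75 rps but is flat at 12.5 rps must produce a larger
  ratio effect size at the higher rate, first on generator ground truth
  and then on expectation over the estimated effect sizes). These sizes
  give Monte-Carlo standard errors small enough for 3-SE assertions
  while keeping a full test run in well under a minute per suite.

## Limitations

Group-level F statistics and p-values from the original cohort are not
reproducible from scratch — they depend on 24 human recordings that were
never deposited. What is reproducible, and what the acceptance layer
recomputes, are the worked examples that depend only on printed inputs
(effect sizes from printed means/SDs/differences; Holm decisions on
printed p-values), the internal consistency of the signal chain, and
the statistical behaviour of the inference layer under the generator's
known ground truth. The sweep-level defaults (noise SDs, drift, 500 Hz)
are chosen for testability, not fidelity to any particular amplifier.
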