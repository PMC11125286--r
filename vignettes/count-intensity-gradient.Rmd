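---
title: "Methods: the count-adapted intensity gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the count-adapted intensity gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igradient)
```

## The metric and its assumptions

The intensity gradient (IG) summarises how a person's wear time is
distributed across the intensity spectrum.  Epoch-level intensity values —
activity counts per 15 s epoch, or epoch-averaged ENMO in mg — are
accumulated into intensity bins, and the IG is the slope of an ordinary
least-squares regression of `ln(minutes in bin)` on `ln(bin midpoint)`
over the bins with non-zero time.  The implicit model is that
time-at-intensity decays approximately as a power law, so the log–log
relation is linear; the fitted `R²` reports how well that holds, and the
slope is meaningful only as a summary of the fitted line, not as a
physical constant.  Slopes are negative for any realistic profile; a
steeper slope means time concentrated at low intensities.

Plain OLS on occupied bins is used deliberately: no bin weighting, no
robust loss, no pseudo-time for empty bins by default.  The estimator is
therefore sensitive to sparsely occupied high-intensity bins (a bin with a
single epoch contributes `ln(0.25)` regardless of how improbable that
occupancy was), which is exactly why the bin resolution matters when the
metric moves between units — the package's central concern.

## Bin schemes and numerical conventions

Three schemes partition `[0, ∞)`: `acc` (160 × 25 mg), `count_fine`
(160 × 25 counts) and `count_adjusted` (40 × 100 counts), each with a
terminal open bin starting at 4000 units.  Conventions, chosen where the
field's descriptions are ambiguous:

* **Half-open bins** `[lower, upper)`; the value 4000 exactly falls in the
  terminal bin.  Published band descriptions ("an additional bin for
  values > 4000") would orphan the single value 4000; a total partition
  requires closing the gap on one side and we close it upward.
* **Bin coordinate = midpoint**, `lower + width/2`, with terminal midpoint
  `4000 + width/2`.  The first bin's coordinate is therefore strictly
  positive and its logarithm defined.  The terminal midpoint understates
  an open bin's content by construction; it affects a fit only when the
  terminal bin is occupied.
* **160 closed bins + 1 terminal** (161 total), since 160 × 25 spans
  exactly `[0, 4000)` and the terminal bin must be additional.
* **Natural logarithms.**  The slope is base-invariant; the intercept is
  not, and is reported on the natural scale.
* **Empty bins are excluded** from the fit (`ln 0` undefined).  A
  `pseudo_minutes` argument adds a small constant to every bin instead,
  off by default, for sensitivity analyses only.
* The count cutpoint bands for 15 s epochs (SED < 25, LPA 26–573,
  MPA 574–1002, VPA ≥ 1003) skip the integer 25 as printed; the classifier
  assigns it to LPA (SED iff count ≤ 24), the conservative choice for
  sedentary time.  `classify_epochs(0:5000)` in the test suite verifies
  the partition and the band edges.
* Wear intervals are half-open `[on, off)` and an epoch belongs to wear
  iff its **start time** lies inside an interval.  Whether boundary epochs
  partially covered by a log entry should count is not observable from
  epoch data; the start-time rule is this package's convention.
* Missing epochs inside a recording are an error, never imputed.

## Processing chain

**ENMO.**  Per sample, `max(0, sqrt(ax² + ay² + az²) − 1) × 1000` mg,
averaged over consecutive 15 s epochs, trailing partial epoch dropped.
Truncation happens at the *sample* level by default (matching the
documented behaviour of the standard raw-processing pipeline); a flag
truncates after averaging instead, and the two differ whenever sub-gravity
and super-gravity samples share an epoch.  An optional simplified
recalibration fits per-axis gain and offset by alternating least squares
over stationary windows (per-axis SD < 0.013 g over 10 s); it is a
deliberately lightweight stand-in for full ellipsoid auto-calibration,
requires at least three distinct orientations, degrades to a no-op with a
warning otherwise, and never increases the stationary residual.

**Lag alignment.**  Paired devices worn simultaneously can disagree on
epoch indexing by a constant integer lag (observed in practice up to 229
epochs).  `detect_lag()` scans shifts in `[-max_lag, max_lag]`
(default 300 epochs = 75 min, chosen to exceed that worst case) and
maximises the Pearson correlation over wear-true overlap; ties break
toward the smallest `|k|`, then negative `k`.  The historical practice of
aligning by eye against logged rest periods is split into a reproducible
pair: `rest_anchored_reference()` picks the device that actually records
zeros during logged rests, and cross-correlation estimates the shift.
`apply_lag()` keeps series length, fills exposed epochs with zero and
marks them non-wear so they drop out of paired analyses.

**Agreement statistics.**  Differences are always `y − x` (pass the
reference device as `x`).  The repeated-measures Bland–Altman limits use
variance components from a one-way random-effects ANOVA of the differences
with subject as the factor (`sd_total² = σ²_between + σ²_within`, with the
unbalanced-design coefficient `n0`); the bias is the pooled mean
difference (subject-mean weighting is an alternative the field leaves
unspecified; pooled was chosen and documented).  With one pair per subject
the estimator reduces exactly to the classic formula — a tested
invariant.  A MOVER-style interval around each limit is provided as an
approximation; the headline outputs are the bias and 1.96-based limits.
ICC uses the absolute-agreement, single-measurement two-way form
(McGraw & Wong's ICC(A,1)) with F-based confidence limits; under absolute
agreement the mixed-model estimate and interval are computed with the same
formulas as the random-model ones, so the model choice is carried as a
label.  The repeated-measures correlation is the common-slope ANCOVA
estimate with `df = N − n_subjects − 1`.  Paired t, Shapiro–Wilk and
variance-F gates wrap the base R tests, with explicit handling of
zero-variance differences (`t = 0, p = 1` for identical vectors; an
infinite `t` with `p = 0` and a flag for constant non-zero differences).

## What the synthetic generator emulates — and what it does not

A simulated day is a shuffled sequence of sedentary epochs (counts 0–24,
85% exact zeros), low-light epochs (25–99) and activity bouts.  Defaults
encode the free-living study conditions the package is validated under:
732 wear minutes/day starting at 07:00, 70% sedentary, light fraction
0.114 (so that roughly 14% of epochs in the first 100-count bin are light
activity), three wear days per participant, twenty participants.

**Ground truth.**  `beta_true` (default −2) is the exponent of the *bout*
time-at-intensity distribution.  Bout intensities sit on the 25-count
bin-midpoint grid between 100 and 1200 counts, and bout epochs are
allocated across that grid proportionally to `intensity^beta_true` with
stochastic rounding, then chopped into geometric-length runs
(mean 8 epochs).  Two support choices make the exponent genuinely
recoverable by the occupied-bin OLS estimator rather than true only in
expectation: the support starts above the first 100-count bin, because a
power law reaching into that wide first bin cannot be consistent with both
the 25-count and the 100-count binning at once (the wide bin integrates
too much curvature — the residual adjusted-scheme bias is below 0.05 in
`[-2.5, -1.5]`); and it ends at 1200 counts so that three wear days place
at least a handful of epochs in every supported bin — with sparser tails
the exclusion of empty bins censors exactly the low-time bins and biases
the slope shallow.  Free-living hip counts at 15 s rarely exceed that
ceiling; the in-lab preset (`inlab_config()`, 60 min, sustained bouts,
little sedentary time) raises it to 4000 since structured sprints do.

**Devices.**  A shared latent intensity drives both devices — the minimal
structure that yields high correlation during consistent in-lab activity
and lower correlation in free-living data, where low-intensity time
dominates.  Device `a` (reference) has gain 1; device `b` gain 0.9, so the
between-device regression slope lands near 0.9.  Each has proportional
noise (3% / 5%), device `b` records spurious small counts at rest with
probability 0.02 (so rest anchoring has something to choose on) and lags
by `lag_epochs` (default 3).  Count saturation is 20000.  The raw 30 Hz
stream for device `b` emits, per epoch, gravity plus one sinusoid at a
stride-type frequency (0.5–1.2 Hz, inside the flat region of the count
filter's passband) with amplitude `1.5e-3` g per count, so bout counts map
above the 0.05 g dead band; epochs below ~33 counts are invisible to the
re-emulated device *by design*, mirroring the hardware's detection floor.
The count emulator itself is a documented approximation — mean-centring,
2nd-order Butterworth band-pass 0.25–2.5 Hz applied forward-backward,
rectification, 0.05 g dead band, 2.5 g clip, per-epoch integration at 128
counts per g·s — and is never claimed to match the proprietary algorithm;
only its qualitative structure (DC rejection, dead band, clipping,
monotonicity) is asserted.

**Determinism.**  Every day is a pure function of
`(seed, participant, day)` via derived substreams, and simulation restores
the caller's RNG state.

**Not emulated:** physiological activity profiles or energy expenditure;
idle-sleep-mode artefacts; clock drift (time-varying lag); temperature
effects on calibration.  Passing tests on this generator therefore show
that the *estimators* behave as specified under known ground truth — not
that any particular cohort's values will be reproduced.  Cohort-level
results depend on undeposited participant data and are out of scope.

## Problem sizes and runtime choices

The validation suite uses the study-scale defaults throughout: 20
participants × 3 days × 2928 epochs for recovery checks, 200 noisy
replicates for lag recovery (SNR 10), 100 random series for the
scheme-nesting identity, and 2000 replicates for the paired-t type-I
calibration.  These sizes keep the whole suite under half a minute while
leaving Monte-Carlo noise an order of magnitude below every tolerance
asserted.

## Known limitations

* The IG depends on epoch length; everything here assumes 15 s epochs and
  no sensitivity analysis across epoch lengths is included.
* The adjusted-scheme recovery carries a small structural bias (≤ 0.05 for
  exponents in `[-2.5, -1.5]`) because a 100-count bin is represented by
  its midpoint; this is a property of the metric's convention, not of the
  estimator.
* The MOVER intervals around the limits of agreement use a delta-method
  variance for the total SD; for very small subject counts they are
  approximate.
* `emulate_counts()` is a stand-in for a proprietary algorithm and should
  never be used to compare against real ActiLife output.
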