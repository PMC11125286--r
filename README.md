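# igradient

Count-adapted intensity gradient for accelerometer physical-activity data.

## The problem

Decades of physical-activity research were collected on accelerometers that
store only proprietary per-epoch *activity counts* (ActiGraph GT1M and
kin), not raw accelerations.  Modern cutpoint-free metrics — in particular
the **intensity gradient (IG)** — were developed for the ENMO metric
(Euclidean norm minus one g, in mg) derived from raw 30 Hz signals, so they
could not be applied to historical count archives directly.  This package
implements the IG for count data, together with everything needed to
validate the adaptation against paired-device recordings: epoch
summarisation, wear-log masking, Evenson cutpoint classification,
inter-device lag alignment, repeated-measures agreement statistics, and a
synthetic paired-device generator with known ground truth.

It is aimed at physical-activity and epidemiology researchers who hold
epoch-level count datasets (children/adolescent cohorts especially) and
want a full-spectrum intensity metric rather than cutpoint minutes.

## The metric

Wear time is accumulated into intensity bins and the IG is the slope of

```
ln(t_j) = IG · ln(m_j) + b
```

an ordinary least-squares fit of log accumulated minutes `t_j` against log
bin-midpoint intensity `m_j` over occupied bins.  Slopes are negative;
steeper (more negative) slopes mean activity concentrated at low
intensities.  Three bin schemes are provided:

| variant          | units  | closed bins | width      | terminal bin |
|------------------|--------|-------------|------------|--------------|
| `acc`            | mg     | 160         | 25 mg      | ≥ 4000 mg    |
| `count_fine`     | counts | 160         | 25 counts  | ≥ 4000 counts|
| `count_adjusted` | counts | 40          | 100 counts | ≥ 4000 counts|

At equal 25-unit resolution, count data occupy several times as many bins
as ENMO data from the same wear period, which flattens the count IG; the
40 × 100-count *adjusted* scheme restores an occupied-bin count comparable
to the ENMO scheme, and with it the agreement between the two metrics.

## Worked example

Three simulated wear days for one participant, IG computed three ways from
the device streams:

```r
library(igradient)
cfg  <- sim_config(seed = 42)
days <- lapply(1:3, function(d) simulate_day(cfg, participant = 1, day = d))

counts <- days[[1]]$device_b
counts$values <- unlist(lapply(days, function(d) d$device_b$values))
counts$wear   <- rep(TRUE, length(counts$values))
enmo <- days[[1]]$enmo_b
enmo$values <- unlist(lapply(days, function(d) d$enmo_b$values))
enmo$wear   <- rep(TRUE, length(enmo$values))

compute_ig(bin_time(counts, make_bin_scheme("count_fine")))
#> <ig_result> count_fine: IG = -1.8266 (intercept 12.550, R2 = 0.920, 46 bins)
compute_ig(bin_time(counts, make_bin_scheme("count_adjusted")))
#> <ig_result> count_adjusted: IG = -2.2456 (intercept 16.582, R2 = 0.947, 12 bins)
compute_ig(bin_time(enmo, make_bin_scheme("acc")))
#> <ig_result> acc: IG = -2.3112 (intercept 13.723, R2 = 0.909, 12 bins)
```

The fine count scheme spreads the same wear time over 46 occupied bins
against the ENMO scheme's 12, and its slope is markedly shallower (−1.83
vs −2.31); the adjusted scheme occupies a comparable number of bins and
lands within 0.07 of the ENMO-based IG.  Supporting diagnostics and the
classic processing chain:

```r
bin_occupancy_ratio(bin_time(counts, make_bin_scheme("count_fine")),
                    bin_time(enmo, make_bin_scheme("acc")))
#> [1] 3.833333
first_bin_composition(counts)   # LPA share of the first 100-count bin
#> [1] 0.1563402
summarise_day(apply_wear_log(days[[1]]$device_a, days[[1]]$wear_log))
#>   participant_id device_id        day   SED LPA MPA VPA total_pa mvpa wear_minutes
#> 1            P01  GT1M-sim 2024-06-01 510.5 208  11 2.5    221.5 13.5          732
detect_lag(days[[1]]$device_a, days[[1]]$device_b, max_lag = 300)
#> <lag_result> lag = 3 epochs (r = 0.9983) vs reference GT1M-sim
```

Agreement between devices or between IG variants uses
`bland_altman()` (repeated-measures variance-components limits),
`icc_absolute_single()` (ICC(A,1) with F-based confidence intervals) and
`rm_corr()` (repeated-measures correlation); `compare_devices()` and
`compute_ig_study()` wire whole studies together, and
`inst/cli/igradient.R` exposes `simulate` / `fixtures` /
`compare-devices` / `compute-ig` subcommands over the package's delimited
text formats.

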