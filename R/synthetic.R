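#' Configuration for the synthetic paired-device generator
#'
#' Describes one simulated wear protocol: a day is a shuffled sequence of
#' sedentary epochs (counts 0-24, mostly exact zeros), low-light epochs
#' (counts 25-99) and activity bouts.  Bout intensities sit on the 25-count
#' bin-midpoint grid between `bout_min_intensity` and `bout_max_intensity`,
#' and bout epochs are allocated across that grid in proportion to
#' `intensity^beta_true` (with stochastic rounding), so the *time*
#' accumulated at each bout intensity follows a power law with exponent
#' `beta_true` — the generator's ground-truth intensity gradient.  Two
#' support choices make `beta_true` genuinely recoverable by the
#' occupied-bin log-log fit: the support starts above the first 100-count
#' bin (a power law reaching into that wide bin cannot match the 25-count
#' and 100-count binnings at once), and it ends where a few wear days still
#' populate every bin with at least a handful of epochs — free-living hip
#' counts at 15 s rarely exceed the default 1200 ceiling anyway.
#'
#' Two devices observe a shared latent intensity: device `a` (the
#' reference, GT1M-like) with gain 1, device `b` (GT9X-like) with gain
#' ~0.9, each with proportional noise, optional spurious rest counts, and
#' an integer-epoch recording lag for device `b`.  Defaults emulate the
#' free-living protocol: ~732 wear minutes/day, ~70% sedentary, and a
#' light fraction chosen so roughly 14% of first-adjusted-bin epochs are
#' light activity.
#'
#' @param seed global integer seed; per-(participant, day) substreams are
#'   derived from it so any day is reproducible in isolation.
#' @param n_participants,days_per_participant study size (20 x 3 default).
#' @param epoch_length epoch length in seconds.
#' @param wear_minutes_per_day target wear time (<= 1440).
#' @param sedentary_fraction,light_fraction fractions of wear epochs that
#'   are sedentary (0-24 counts) and low-light (25-99 counts); the rest is
#'   bout time.
#' @param bout_mean_epochs mean bout duration in epochs (geometric).
#' @param beta_true power-law exponent of bout time-at-intensity (< 0).
#' @param bout_min_intensity,bout_max_intensity bout-intensity support
#'   bounds in counts.
#' @param gain_a,gain_b multiplicative device gains on the latent intensity.
#' @param noise_frac_a,noise_frac_b proportional noise SD (fraction of the
#'   epoch's expected counts).
#' @param spurious_rate_a,spurious_rate_b probability that a latent-zero
#'   epoch still records a few counts (device noise at rest).
#' @param lag_epochs integer recording lag of device `b` (positive = `b`
#'   late).
#' @param saturation count ceiling per epoch.
#' @param sample_rate raw-signal rate in Hz for device `b`.
#' @param step_freq_range movement-frequency band (Hz) of the raw signal;
#'   the default spans typical walking stride frequencies and lies in the
#'   flat region of the count filter's passband, so the amplitude-to-count
#'   map stays invertible in expectation.
#' @param amp_per_count raw-sinusoid amplitude in g per latent count.
#' @param zero_sed_prob probability a sedentary epoch is an exact zero.
#' @param mg_per_count ENMO mg per latent count for device `b`'s epoch-ENMO
#'   stream (default 0.25: hip ENMO spans a numerically narrower range than
#'   counts, which is what makes count data occupy more 25-unit bins).
#' @param wear_start_hour local hour wear begins.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_participants = 20, days_per_participant = 3,
                       epoch_length = 15, wear_minutes_per_day = 732,
                       sedentary_fraction = 0.70, light_fraction = 0.114,
                       bout_mean_epochs = 8, beta_true = -2,
                       bout_min_intensity = 100, bout_max_intensity = 1200,
                       gain_a = 1, gain_b = 0.9,
                       noise_frac_a = 0.03, noise_frac_b = 0.05,
                       spurious_rate_a = 0, spurious_rate_b = 0.02,
                       lag_epochs = 3, saturation = 20000,
                       sample_rate = 30, step_freq_range = c(0.5, 1.2),
                       amp_per_count = 1.5e-3, zero_sed_prob = 0.85,
                       mg_per_count = 0.25, wear_start_hour = 7) {
  if (beta_true >= 0) stop("beta_true must be negative for a realistic profile")
  if (gain_a <= 0 || gain_b <= 0) stop("gains must be positive")
  if (wear_minutes_per_day > 1440) stop("wear target exceeds a day")
  if (sedentary_fraction + light_fraction >= 1)
    stop("sedentary + light fractions must leave room for bouts")
  if (abs(lag_epochs) > 300) stop("lag outside the alignment search window")
  structure(as.list(environment()), class = "sim_config")
}

#' In-lab session preset
#'
#' A short structured session with sustained activity bouts and little
#' sedentary time, emulating a supervised activity protocol (walking
#' through sprinting at self-selected pace).
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
inlab_config <- function(...) {
  defaults <- list(wear_minutes_per_day = 60, sedentary_fraction = 0.25,
                   light_fraction = 0.10, bout_mean_epochs = 20,
                   beta_true = -1, bout_max_intensity = 4000, lag_epochs = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

.substream <- function(config, participant, day) {
  as.integer((as.numeric(config$seed) * 100003 + participant * 1009 + day * 101) %%
               2147483629)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simulate one participant-day of paired-device data
#'
#' Builds the latent epoch intensity sequence (sedentary background, light
#' background and power-law bouts, shuffled as contiguous segments), then
#' emits both device count streams — device `b` delayed by the configured
#' lag, exposed epochs recording zero — and, optionally, a 30 Hz raw
#' triaxial signal consistent with device `b`'s counts.  Output is a pure
#' function of `(config, participant, day)`.
#'
#' @param config a [sim_config()].
#' @param participant participant index (1-based).
#' @param day day index (1-based).
#' @param emit_raw also synthesise the raw signal for device `b`
#'   (default `FALSE`; raw generation is by far the most expensive step).
#' @return an object of class `synthetic_day`: `device_a`, `device_b`
#'   (count [epoch_series()]), `enmo_b` (epoch ENMO in mg for device `b`),
#'   optional `raw_b` ([raw_signal()]), `wear_log`, and `truth` (latent
#'   intensity, bout mask, `beta_true`, `lag_epochs`).
#' @export
simulate_day <- function(config, participant = 1, day = 1, emit_raw = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream(config, participant, day), {
    n <- round(config$wear_minutes_per_day * 60 / config$epoch_length)
    n_active <- round(n * (1 - config$sedentary_fraction - config$light_fraction))
    n_light <- round(n * config$light_fraction)

    grid <- seq(12.5, 3987.5, by = 25)
    grid <- grid[grid > config$bout_min_intensity & grid < config$bout_max_intensity]
    # allocate bout epochs per grid intensity so that accumulated time follows
    # intensity^beta_true near-exactly (floor + Bernoulli remainder), instead
    # of sampling bouts independently: independent sampling leaves the upper
    # bins empty or single-occupied so often that the occupied-bin log-log
    # fit cannot see the generating exponent
    w <- grid^config$beta_true
    e_target <- n_active * w / sum(w)
    n_per <- floor(e_target) +
      (stats::runif(length(grid)) < (e_target - floor(e_target)))
    bouts <- list()
    for (j in which(n_per > 0)) {
      left <- n_per[j]
      while (left > 0) {
        len <- min(left, stats::rgeom(1, 1 / config$bout_mean_epochs) + 1)
        bouts[[length(bouts) + 1]] <- rep(grid[j], len)
        left <- left - len
      }
    }
    n_active <- sum(n_per)
    n_sed <- n - n_active - n_light
    sed <- ifelse(stats::runif(n_sed) < config$zero_sed_prob, 0,
                  sample.int(24, n_sed, replace = TRUE))
    light <- sample(25:99, n_light, replace = TRUE)
    segs <- c(bouts,
              lapply(sed, identity),
              lapply(light, identity))
    flags <- c(rep(TRUE, length(bouts)), rep(FALSE, n_sed + n_light))
    ord <- sample(length(segs))
    latent <- unlist(segs[ord], use.names = FALSE)
    is_bout <- rep(flags[ord], lengths(segs)[ord])

    emit <- function(gain, noise_frac, spurious_rate, device_id) {
      mu <- gain * latent
      v <- round(pmax(0, mu + stats::rnorm(n, 0, noise_frac * mu)))
      zero <- which(latent == 0)
      if (spurious_rate > 0 && length(zero)) {
        sp <- zero[stats::runif(length(zero)) < spurious_rate]
        v[sp] <- sample.int(30, length(sp), replace = TRUE)
      }
      pmin(v, config$saturation)
    }
    start <- as.POSIXct("2024-06-01 00:00:00", tz = "UTC") +
      (day - 1) * 86400 + config$wear_start_hour * 3600
    pid <- sprintf("P%02d", participant)
    va <- emit(config$gain_a, config$noise_frac_a, config$spurious_rate_a)
    vb <- emit(config$gain_b, config$noise_frac_b, config$spurious_rate_b)
    # device b records late by lag_epochs; exposed epochs hold zeros and the
    # stream still claims full wear (alignment is the analyst's problem)
    k <- config$lag_epochs
    vb_shift <- numeric(n)
    if (k >= 0) vb_shift[(k + 1):n] <- vb[1:(n - k)]
    else vb_shift[1:(n + k)] <- vb[(1 - k):n]
    dev_a <- epoch_series(va, config$epoch_length, start, pid, "GT1M-sim",
                          units = "counts")
    dev_b <- epoch_series(vb_shift, config$epoch_length, start, pid, "GT9X-sim",
                          units = "counts")
    # epoch-level ENMO stream for device b, on the narrower mg scale
    mu_mg <- config$gain_b * latent * config$mg_per_count
    enmo_b <- epoch_series(pmax(0, mu_mg + stats::rnorm(n, 0, config$noise_frac_b * mu_mg)),
                           config$epoch_length, start, pid, "GT9X-sim",
                           units = "mg")
    wl <- wear_log(pid, start, start + n * config$epoch_length)
    raw_b <- if (emit_raw) simulate_raw_from_counts(dev_b, config) else NULL
    structure(list(participant_id = pid, day = day, config = config,
                   truth = list(beta_true = config$beta_true,
                                lag_epochs = config$lag_epochs,
                                latent = latent, is_bout = is_bout),
                   device_a = dev_a, device_b = dev_b, enmo_b = enmo_b,
                   raw_b = raw_b, wear_log = wl),
              class = "synthetic_day")
  })
}

#' @export
print.synthetic_day <- function(x, ...) {
  cat(sprintf("<synthetic_day> %s day %d: %d epochs, beta_true = %g, lag = %d\n",
              x$participant_id, x$day, length(x$device_a$values),
              x$truth$beta_true, x$truth$lag_epochs))
  invisible(x)
}

#' Simulate a whole study
#'
#' @param config a [sim_config()].
#' @param emit_raw forward to [simulate_day()].
#' @return nested list: `study[[participant]][[day]]` of `synthetic_day`.
#' @export
simulate_study <- function(config, emit_raw = FALSE) {
  lapply(seq_len(config$n_participants), function(p)
    lapply(seq_len(config$days_per_participant), function(d)
      simulate_day(config, p, d, emit_raw = emit_raw)))
}

#' Ground-truth intensity gradient of simulated days
#'
#' Bins the latent *bout* intensities of one or more [simulate_day()]
#' results under a bin scheme and runs [compute_ig()] on them — the
#' quantity the generator's `beta_true` parameterises.  The latent
#' intensity is a dimensionless value on the shared 0-4000 grid and is
#' interpreted in whichever units the scheme uses.
#'
#' @param days a `synthetic_day` or list of them (same participant).
#' @param variant bin-scheme variant, as in [make_bin_scheme()].
#' @return an `ig_result`.
#' @export
latent_ig <- function(days, variant = "count_fine") {
  if (inherits(days, "synthetic_day")) days <- list(days)
  scheme <- make_bin_scheme(variant)
  vals <- unlist(lapply(days, function(d) d$truth$latent[d$truth$is_bout]))
  s <- epoch_series(if (scheme$units == "counts") round(vals) else vals,
                    epoch_length = days[[1]]$config$epoch_length,
                    units = scheme$units)
  compute_ig(bin_time(s, scheme))
}

#' Synthesise a raw triaxial signal from epoch counts
#'
#' Emits, for each epoch, a gravity-aligned vertical axis carrying one
#' sinusoid in the movement band whose amplitude grows linearly with the
#' epoch's count (`amp_per_count` g per count); zero-count epochs give a
#' constant (0, 0, 1) g signal.  The mapping is monotone, so epoch ENMO and
#' re-emulated counts preserve the rank order of the source counts.  Used
#' to exercise the raw-signal path against a known count stream; it is not
#' a biomechanical gait model.
#'
#' @param series a count-typed [epoch_series()].
#' @param config a [sim_config()] (rate, band, amplitude map).
#' @return a [raw_signal()].
#' @export
simulate_raw_from_counts <- function(series, config = sim_config()) {
  if (series$units != "counts") stop("count-typed series required")
  spe <- as.integer(round(config$sample_rate * series$epoch_length))
  n_ep <- length(series$values)
  tt <- (seq_len(spe) - 1) / config$sample_rate
  f <- stats::runif(n_ep, config$step_freq_range[1], config$step_freq_range[2])
  phase <- stats::runif(n_ep, 0, 2 * pi)
  amp <- pmin(6, series$values * config$amp_per_count)
  az <- 1 + rep(amp, each = spe) *
    sin(2 * pi * rep(f, each = spe) * rep(tt, times = n_ep) +
          rep(phase, each = spe))
  zero <- numeric(n_ep * spe)
  raw_signal(zero, zero, az, sample_rate = config$sample_rate,
             participant_id = series$participant_id,
             device_id = series$device_id)
}

#' Approximate count emulation from a raw signal
#'
#' A documented stand-in for count formation on older uniaxial devices:
#' the vertical axis is mean-centred, band-pass filtered (2nd-order
#' Butterworth, forward-backward, 0.25-2.5 Hz by default), rectified, put
#' through a dead band below 0.05 g, clipped at 2.50 g, and the surviving
#' magnitude is integrated per epoch and scaled to integer counts.  The
#' proprietary manufacturer algorithm is not public; this emulator matches
#' only its documented qualitative structure (band limits, dead band,
#' clipping) and is used solely to generate and test synthetic data.
#' Mean-centring makes the output exactly invariant to any constant added
#' to the vertical axis.
#'
#' @param signal a [raw_signal()] with `sample_rate >= 10` Hz.
#' @param epoch_length epoch length in seconds.
#' @param band band-pass corner frequencies in Hz.
#' @param dead_band threshold in g below which samples register nothing.
#' @param clip saturation in g.
#' @param scale counts per g-second of integrated magnitude.
#' @return a count-typed [epoch_series()].
#' @export
emulate_counts <- function(signal, epoch_length = 15, band = c(0.25, 2.5),
                           dead_band = 0.05, clip = 2.5, scale = 128) {
  if (signal$sample_rate < 10) stop("sample rate too low for the filter band")
  spe <- as.integer(round(signal$sample_rate * epoch_length))
  n_ep <- length(signal$az) %/% spe
  if (n_ep < 1) stop("signal shorter than one epoch")
  v <- signal$az - mean(signal$az)
  bf <- signal::butter(2, band / (signal$sample_rate / 2), type = "pass")
  v <- signal::filtfilt(bf, v)
  v <- abs(v)
  v[v < dead_band] <- 0
  v <- pmin(v, clip)
  use <- seq_len(n_ep * spe)
  sums <- colSums(matrix(v[use], nrow = spe))
  counts <- round(sums / signal$sample_rate * scale)
  epoch_series(counts, epoch_length = epoch_length,
               participant_id = signal$participant_id,
               device_id = signal$device_id, units = "counts")
}

#' Write a small fixture dataset to disk
#'
#' Materialises a compact standard dataset in the package's text dialects:
#' per participant-day epoch CSVs for both devices, a combined wear log,
#' and one short raw-signal CSV.  Used by the command-line `fixtures`
#' subcommand and by examples.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()]; keep it small — every epoch becomes a
#'   text row.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, config = sim_config(n_participants = 2,
                                                    days_per_participant = 1,
                                                    wear_minutes_per_day = 120)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl_rows <- list()
  for (p in seq_len(config$n_participants)) {
    for (d in seq_len(config$days_per_participant)) {
      sday <- simulate_day(config, p, d)
      write_epoch_csv(sday$device_a,
                      file.path(dir, sprintf("%s_day%d_gt1m.csv", sday$participant_id, d)))
      write_epoch_csv(sday$device_b,
                      file.path(dir, sprintf("%s_day%d_gt9x.csv", sday$participant_id, d)))
      wl_rows[[length(wl_rows) + 1]] <- data.frame(
        participant_id = sday$participant_id,
        on = format(sday$wear_log$on, .TS_FMT, tz = "UTC"),
        off = format(sday$wear_log$off, .TS_FMT, tz = "UTC"))
    }
  }
  utils::write.csv(do.call(rbind, wl_rows), file.path(dir, "wear_log.csv"),
                   row.names = FALSE, quote = FALSE)
  short <- simulate_day(sim_config(seed = config$seed, wear_minutes_per_day = 5),
                        1, 1, emit_raw = TRUE)
  write_raw_csv(short$raw_b, file.path(dir, "P01_raw_gt9x.csv"))
  invisible(dir)
}
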