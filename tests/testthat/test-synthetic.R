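test_that("simulation is a pure function of (config, participant, day)", {
  cfg <- sim_config(seed = 7, wear_minutes_per_day = 120)
  d1 <- simulate_day(cfg, 2, 1)
  d2 <- simulate_day(cfg, 2, 1)
  expect_identical(d1$device_a$values, d2$device_a$values)
  expect_identical(d1$device_b$values, d2$device_b$values)
  expect_identical(d1$truth$latent, d2$truth$latent)
  # different day gives a different stream but the global RNG is untouched
  set.seed(99); before <- rnorm(1)
  simulate_day(cfg, 2, 2)
  set.seed(99); after <- rnorm(1)
  expect_identical(before, after)
  expect_false(identical(d1$device_a$values, simulate_day(cfg, 2, 2)$device_a$values))
})

test_that("noise-free equal-gain devices emit identical streams", {
  cfg <- sim_config(seed = 3, wear_minutes_per_day = 60, gain_b = 1,
                    noise_frac_a = 0, noise_frac_b = 0,
                    spurious_rate_b = 0, lag_epochs = 0)
  d <- simulate_day(cfg)
  expect_identical(d$device_a$values, d$device_b$values)
  expect_equal(length(d$device_a$values), 60 * 60 / 15)
})

test_that("configuration guards reject infeasible study conditions", {
  expect_error(sim_config(beta_true = 0.5), "negative")
  expect_error(sim_config(wear_minutes_per_day = 2000), "exceeds")
  expect_error(sim_config(gain_b = 0), "positive")
  expect_error(sim_config(sedentary_fraction = 0.9, light_fraction = 0.2),
               "room for bouts")
})

test_that("the injected device lag is recovered end to end", {
  cfg <- sim_config(seed = 5, wear_minutes_per_day = 240, lag_epochs = 7)
  d <- simulate_day(cfg)
  lr <- detect_lag(d$device_a, d$device_b, max_lag = 30)
  expect_identical(lr$lag_epochs, 7L)
})

test_that("the latent bout distribution carries the configured exponent", {
  cfg <- sim_config(seed = 13, n_participants = 8)
  for (beta in c(-1.5, -2.5)) {
    cfg$beta_true <- beta
    slopes <- sapply(1:8, function(p) {
      days <- lapply(1:3, function(d) simulate_day(cfg, p, d))
      latent_ig(days, "count_fine")$slope
    })
    expect_lt(abs(mean(slopes) - beta), 0.1)
  }
})

test_that("wear structure matches the configured protocol", {
  cfg <- sim_config(seed = 17)
  d <- simulate_day(cfg)
  expect_equal(wear_minutes(apply_wear_log(d$device_a, d$wear_log)), 732)
  sed_frac <- mean(d$truth$latent < 25)
  expect_equal(sed_frac, 0.70, tolerance = 0.05)
  # first adjusted bin is mostly sedentary, with a modest light share
  expect_equal(first_bin_composition(d$device_a), 0.14, tolerance = 0.5)
})

test_that("count data occupy more fine bins than ENMO data, flattening the IG", {
  cfg <- sim_config(seed = 19)
  ratios <- c(); steeper <- c()
  for (p in 1:6) {
    d <- simulate_day(cfg, p, 1)
    cb <- bin_time(d$device_b, make_bin_scheme("count_fine"))
    ab <- bin_time(d$enmo_b, make_bin_scheme("acc"))
    ratios <- c(ratios, bin_occupancy_ratio(cb, ab))
    steeper <- c(steeper, abs(compute_ig(ab)$slope) - abs(compute_ig(cb)$slope))
  }
  expect_true(all(ratios > 1))
  expect_gt(mean(steeper), 0)   # |accIG| >= |countIG| on average
})

test_that("raw synthesis is gravity-aligned and monotone in counts", {
  cfg <- sim_config(seed = 23)
  zero <- count_series(rep(0, 4))
  sig <- simulate_raw_from_counts(zero, cfg)
  expect_equal(sig$az, rep(1, length(sig$az)))
  expect_equal(max(abs(enmo_epochs(sig)$values)), 0)

  set.seed(24)
  s <- count_series(c(100, 400, 900, 1600, 2500, 3600))
  e <- enmo_epochs(simulate_raw_from_counts(s, cfg))$values
  expect_true(all(diff(e) > 0))
})

test_that("count emulation mirrors the documented filter chain", {
  rate <- 30; spe <- rate * 15
  tt <- (seq_len(4 * spe) - 1) / rate
  mk <- function(amp, f = 1) raw_signal(rep(0, length(tt)), rep(0, length(tt)),
                                        1 + amp * sin(2 * pi * f * tt),
                                        sample_rate = rate)
  # constant gravity: the band-pass removes DC entirely
  expect_true(all(emulate_counts(mk(0))$values == 0))
  # amplitude below the 0.05 g dead band registers nothing
  expect_true(all(emulate_counts(mk(0.04))$values == 0))
  # monotone in amplitude
  c_half <- emulate_counts(mk(0.5))$values
  c_full <- emulate_counts(mk(1.0))$values
  expect_true(all(c_full > c_half))
  # adding a constant to the vertical axis changes nothing
  shifted <- mk(0.5); shifted$az <- shifted$az + 0.37
  expect_identical(emulate_counts(shifted)$values, c_half)
})

test_that("counts survive the raw round trip in rank order", {
  cfg <- sim_config(seed = 29, wear_minutes_per_day = 60)
  d <- simulate_day(cfg, 1, 1, emit_raw = TRUE)
  back <- emulate_counts(d$raw_b, epoch_length = 15)
  # counts under ~33 map to amplitudes below the 0.05 g dead band, where the
  # emulated device is blind by design; rank order is claimed above it
  keep <- d$device_b$values >= 50
  rho <- cor(d$device_b$values[keep], back$values[keep], method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("fixtures materialise to readable text files", {
  dir <- withr::local_tempdir()
  write_fixtures(dir, sim_config(seed = 2, n_participants = 2,
                                 days_per_participant = 1,
                                 wear_minutes_per_day = 30))
  files <- list.files(dir)
  expect_true(all(c("P01_day1_gt1m.csv", "P02_day1_gt9x.csv",
                    "wear_log.csv", "P01_raw_gt9x.csv") %in% files))
  s <- read_epoch_csv(file.path(dir, "P01_day1_gt1m.csv"))
  expect_equal(length(s$values), 30 * 4)
  expect_identical(s$values, simulate_day(sim_config(seed = 2, n_participants = 2,
                                                     days_per_participant = 1,
                                                     wear_minutes_per_day = 30),
                                          1, 1)$device_a$values)
})
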