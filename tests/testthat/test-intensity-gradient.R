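test_that("the three bin schemes have the published structure", {
  acc <- make_bin_scheme("acc")
  fine <- make_bin_scheme("count_fine")
  adj <- make_bin_scheme("count_adjusted")
  expect_equal(acc$n_closed_bins, 160L)
  expect_equal(acc$width, 25)
  expect_identical(acc$units, "mg")
  expect_equal(fine$n_closed_bins, 160L)
  expect_equal(fine$width, 25)
  expect_equal(adj$n_closed_bins, 40L)
  expect_equal(adj$width, 100)
  for (s in list(acc, fine, adj)) {
    expect_equal(s$n_closed_bins * s$width, 4000)
    expect_equal(s$midpoints[1], s$width / 2)
    expect_equal(s$midpoints[length(s$midpoints)], 4000 + s$width / 2)
    expect_true(all(diff(s$breaks) > 0))
  }
  expect_equal(acc$midpoints[1], 12.5)
  expect_error(make_bin_scheme("bogus"))
})

test_that("binned time conserves wear minutes and respects bin edges", {
  adj <- make_bin_scheme("count_adjusted")
  b <- bin_time(count_series(c(0, 12, 24)), adj)
  expect_equal(b$minutes[1], 0.75)
  expect_equal(sum(b$minutes), 0.75)
  expect_equal(b$occupied_bins, 1)

  # value exactly 4000 falls into the terminal open bin
  b2 <- bin_time(count_series(c(3999, 4000, 4001)), adj)
  expect_equal(b2$minutes[40], 0.25)
  expect_equal(b2$minutes[41], 0.5)

  # one epoch in each closed adjusted bin
  b3 <- bin_time(count_series(seq(50, 3950, by = 100)), adj)
  expect_equal(b3$occupied_bins, 40)

  expect_error(bin_time(mg_series(c(1, 2)), adj), "unit mismatch")
})

test_that("binned minutes equal wear minutes for random series and schemes", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(100:800, 1)
    s <- count_series(sample(0:6000, n, replace = TRUE), wear = runif(n) < 0.9)
    for (v in c("count_fine", "count_adjusted")) {
      b <- bin_time(s, make_bin_scheme(v))
      expect_equal(sum(b$minutes), wear_minutes(s))
      expect_true(all(b$minutes >= 0))
    }
  }
})

test_that("every adjusted bin aggregates exactly four fine bins", {
  fine <- make_bin_scheme("count_fine")
  adj <- make_bin_scheme("count_adjusted")
  set.seed(52)
  for (i in 1:10) {
    s <- count_series(sample(0:5000, 500, replace = TRUE))
    mf <- bin_time(s, fine)$minutes
    ma <- bin_time(s, adj)$minutes
    agg <- c(colSums(matrix(mf[1:160], nrow = 4)), mf[161])
    expect_identical(ma, agg)
  }
})

test_that("the IG regression matches closed forms on constructed bins", {
  adj <- make_bin_scheme("count_adjusted")
  # two occupied bins, midpoints 50 and 150, minutes 100 and 10
  s <- count_series(c(rep(10, 400), rep(150, 40)))
  fit <- compute_ig(bin_time(s, adj))
  expect_equal(fit$slope, log(0.1) / log(3), tolerance = 1e-12)
  expect_equal(fit$n_bins_used, 2)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # minutes exactly proportional to midpoint^-2 across all bins
  for (v in c("acc", "count_fine", "count_adjusted")) {
    sch <- make_bin_scheme(v)
    bt <- manual_binned(sch, 500 * sch$midpoints^-2)
    f <- compute_ig(bt)
    expect_equal(f$slope, -2, tolerance = 1e-9)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }

  # equal minutes in every occupied bin: slope 0
  flat <- manual_binned(adj, rep(c(2, 0), c(20, 21)))
  expect_equal(compute_ig(flat)$slope, 0, tolerance = 1e-12)

  expect_error(compute_ig(manual_binned(adj, c(1, rep(0, 40)))), "occupied")
})

test_that("the IG slope ignores bin order and overall time scaling", {
  sch <- make_bin_scheme("count_adjusted")
  set.seed(53)
  minutes <- c(rexp(41) * (runif(41) < 0.5))
  minutes[c(3, 17)] <- c(4, 2)  # ensure >= 2 occupied
  f1 <- compute_ig(manual_binned(sch, minutes))
  f2 <- compute_ig(manual_binned(sch, minutes * 7.3))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f2$intercept - f1$intercept, log(7.3), tolerance = 1e-10)

  perm <- sample(41)
  sch_p <- sch; sch_p$midpoints <- sch$midpoints[perm]
  f3 <- compute_ig(manual_binned(sch_p, minutes[perm]))
  expect_equal(f3$slope, f1$slope, tolerance = 1e-10)
})

test_that("the pseudo-minutes flag brings empty bins into the fit", {
  sch <- make_bin_scheme("count_adjusted")
  minutes <- c(10, 5, rep(0, 39))
  f0 <- compute_ig(manual_binned(sch, minutes))
  expect_equal(f0$n_bins_used, 2)
  f1 <- compute_ig(manual_binned(sch, minutes), pseudo_minutes = 1e-3)
  expect_equal(f1$n_bins_used, 41)
  expect_lt(f1$slope, f0$slope)  # empty high bins steepen the fit
})

test_that("occupancy ratio and first-bin composition follow their definitions", {
  fine <- make_bin_scheme("count_fine")
  counts_b <- bin_time(count_series(seq(0, 1125, by = 25)), fine)   # 46 bins
  acc_b <- bin_time(mg_series(seq(0, 487, by = 25.6)), make_bin_scheme("acc")) # 20 bins
  expect_equal(counts_b$occupied_bins, 46)
  expect_equal(acc_b$occupied_bins, 20)
  expect_equal(bin_occupancy_ratio(counts_b, acc_b), 2.3)
  same <- bin_time(count_series(seq(50, 950, by = 100)), fine)
  expect_equal(bin_occupancy_ratio(same, same), 1)
  empty_acc <- manual_binned(make_bin_scheme("acc"), rep(0, 161))
  expect_error(bin_occupancy_ratio(counts_b, empty_acc), "occupied")

  expect_equal(first_bin_composition(count_series(c(10, 30, 50, 90, 500))), 0.75)
  expect_equal(first_bin_composition(count_series(rep(0, 5))), 0)
  expect_equal(first_bin_composition(count_series(c(25, 50, 99))), 1)
  expect_error(first_bin_composition(count_series(c(200, 300))), "empty")
})
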