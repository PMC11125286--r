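# independent repeated-measures correlation oracle: within-subject centring
# reduces the common-slope ANCOVA to a plain correlation of the residuals
rm_corr_oracle <- function(pairs) {
  cx <- unlist(tapply(pairs$x, pairs$subject, function(v) v - mean(v)))
  cy <- unlist(tapply(pairs$y, pairs$subject, function(v) v - mean(v)))
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

test_that("classic Bland-Altman matches hand-computed limits", {
  b <- bland_altman(paired_obs(c(1, 1, 1), c(0, 0, 0), c(-1, 0, 1)))
  expect_equal(b$bias, 0)
  expect_equal(b$sd_total, 1)
  expect_equal(b$loa_lower, -qnorm(0.975), tolerance = 1e-10)
  expect_equal(b$loa_upper, qnorm(0.975), tolerance = 1e-10)
  expect_match(b$method, "classic")
  # constant differences: limits collapse onto the bias
  bc <- bland_altman(paired_obs(1:4, c(1, 2, 3, 4), c(4, 5, 6, 7)))
  expect_equal(bc$bias, 3)
  expect_equal(bc$loa_lower, 3)
  expect_equal(bc$loa_upper, 3)
  expect_error(bland_altman(paired_obs(1:2, c(1, 2), c(2, 3))), "3 pairs")
})

test_that("repeated-measures limits use variance components from the ANOVA", {
  # two subjects with differences {0,0} and {2,2}: within variance 0,
  # between mean square 4, n0 = 2, so sd_total = sqrt(2)
  b <- bland_altman(paired_obs(c(1, 1, 2, 2), c(0, 0, 0, 0), c(0, 0, 2, 2)))
  expect_match(b$method, "repeated")
  expect_equal(b$bias, 1)
  expect_equal(b$var_within, 0)
  expect_equal(b$var_between, 2, tolerance = 1e-10)
  expect_equal(b$sd_total, sqrt(2), tolerance = 1e-10)
  # LOA symmetry around the bias
  expect_equal(b$loa_upper - b$bias, b$bias - b$loa_lower, tolerance = 1e-12)
})

test_that("one pair per subject reduces to the classic formula exactly", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    d <- rnorm(n)
    p <- paired_obs(seq_len(n), rep(0, n), d)
    b <- bland_altman(p)
    expect_match(b$method, "classic")
    expect_equal(b$sd_total, sd(d), tolerance = 1e-12)
    expect_equal(b$bias, mean(d), tolerance = 1e-12)
  }
})

test_that("repeated-measures limits widen when differences cluster by subject", {
  set.seed(62)
  subj <- rep(1:8, each = 5)
  d <- rnorm(8, sd = 3)[subj] + rnorm(40, sd = 0.5)
  p <- paired_obs(subj, rep(0, 40), d)
  rmba <- bland_altman(p)
  naive_sd <- sd(d)
  expect_gt(rmba$var_between, 0)
  # MOVER interval brackets each limit
  expect_lt(rmba$loa_ci["lower", 1], rmba$loa_lower)
  expect_gt(rmba$loa_ci["upper", 2], rmba$loa_upper)
  expect_equal(rmba$sd_total, naive_sd, tolerance = 0.25)
})

test_that("ICC(A,1) reproduces reference values on fixed tables", {
  # constant offset: absolute agreement penalises it (2/17 by hand ANOVA)
  i1 <- icc_absolute_single(paired_obs(1:4, c(1, 2, 3, 4), c(6, 7, 8, 9)))
  expect_equal(i1$icc, 2 / 17, tolerance = 1e-10)
  expect_equal(i1$mse, 0)
  # generic 5-subject table, frozen from an independent implementation
  i2 <- icc_absolute_single(paired_obs(1:5, c(7, 9, 4, 6, 8), c(8, 11, 3, 7, 9)))
  expect_equal(i2$icc, 0.875969, tolerance = 1e-6)
  expect_equal(round(i2$ci_lower, 2), 0.31)
  expect_equal(round(i2$ci_upper, 2), 0.99)
  expect_true(i2$ci_lower <= i2$icc && i2$icc <= i2$ci_upper)
  # perfect agreement
  i3 <- icc_absolute_single(paired_obs(1:3, c(1, 2, 3), c(1, 2, 3)))
  expect_equal(i3$icc, 1)
  expect_equal(i3$ci_upper, 1)
})

test_that("ICC on duplicated data is one for both model labels", {
  set.seed(63)
  for (model in c("two-way random", "two-way mixed")) {
    v <- rnorm(6)
    i <- icc_absolute_single(paired_obs(1:6, v, v), model = model)
    expect_equal(i$icc, 1)
    expect_identical(i$model, model)
  }
})

test_that("ICC input validation and degenerate tables are handled", {
  expect_error(icc_absolute_single(paired_obs(c(1, 1), c(1, 2), c(1, 2))),
               "one pair per subject")
  expect_error(icc_absolute_single(paired_obs(1, 1, 2)), "2 subjects")
})

test_that("repeated-measures correlation matches the frozen reference case", {
  p <- paired_obs(rep(1:3, each = 3),
                  c(1, 2, 3, 0, 1, 3, 2, 4, 5),
                  c(2, 4, 5, 5, 6, 9, 1, 3, 2))
  r <- rm_corr(p)
  expect_equal(r$r_rm, 0.8597270, tolerance = 1e-6)
  expect_equal(r$df, 5)
  expect_equal(r$p_value, 0.0131053, tolerance = 1e-5)
  expect_equal(r$r_rm, rm_corr_oracle(p), tolerance = 1e-10)
})

test_that("repeated-measures correlation equals the centring oracle broadly", {
  set.seed(64)
  for (i in 1:10) {
    subj <- rep(seq_len(sample(3:6, 1)), each = sample(3:5, 1))
    p <- paired_obs(subj, rnorm(length(subj)), rnorm(length(subj)))
    expect_equal(rm_corr(p)$r_rm, rm_corr_oracle(p), tolerance = 1e-10)
  }
})

test_that("rm correlation hits +/-1 on exact within-subject lines", {
  subj <- rep(1:3, each = 4)
  x <- c(1:4, 2:5, 0:3)
  up <- paired_obs(subj, x, 2 * x + subj * 10)
  expect_equal(rm_corr(up)$r_rm, 1, tolerance = 1e-12)
  down <- paired_obs(subj, x, -x + subj * 10)
  expect_equal(rm_corr(down)$r_rm, -1, tolerance = 1e-12)
  expect_equal(r_squared_rm(up), 1, tolerance = 1e-10)
  expect_equal(r_squared_rm(down), 1, tolerance = 1e-10)
})

test_that("rm correlation ignores per-subject constant shifts", {
  set.seed(65)
  subj <- rep(1:4, each = 5)
  p <- paired_obs(subj, rnorm(20), rnorm(20))
  shifted <- p
  shifted$x <- p$x + c(10, -3, 7, 100)[as.integer(p$subject)]
  shifted$y <- p$y + c(-5, 2, 0, 50)[as.integer(p$subject)]
  expect_equal(rm_corr(p)$r_rm, rm_corr(shifted)$r_rm, tolerance = 1e-9)
})

test_that("subjects with a single observation are dropped with a warning", {
  p <- paired_obs(c(1, 1, 2, 2, 3), c(1, 2, 1, 3, 9), c(2, 3, 0, 4, 1))
  expect_warning(r <- rm_corr(p), "dropping")
  expect_equal(r$n_subjects, 2)
  expect_error(suppressWarnings(rm_corr(paired_obs(c(1, 1, 2), 1:3, 3:1))),
               "2 subjects")
})

test_that("the paired t-test handles degenerate differences", {
  v <- c(1.2, 3.4, 2.2, 5.1)
  same <- paired_t(v, v)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  off <- paired_t(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(is.infinite(off$t) && off$t > 0)
  expect_equal(off$p, 0)
  expect_true(off$zero_variance)
  expect_error(paired_t(1:2, 2:3), "3 pairs")
  # ordinary case agrees with the base test
  set.seed(66)
  x <- rnorm(12); y <- x + rnorm(12, 0.3)
  expect_equal(paired_t(x, y)$p, t.test(y, x, paired = TRUE)$p.value)
})

test_that("distribution gates return their statistics", {
  set.seed(67)
  v <- rnorm(20)
  sw <- shapiro_wilk(v)
  expect_true(sw$W > 0 && sw$W <= 1)
  f <- variance_f_test(rnorm(15), rnorm(15, sd = 2))
  expect_lt(f$p, 0.5)
  expect_error(shapiro_wilk(c(1, 2)), "3 values")
})
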