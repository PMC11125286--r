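#' Paired observations for agreement analyses
#'
#' Agreement functions take a plain data.frame with columns `subject`, `x`
#' and `y`: one row per paired measurement, `x` and `y` in the same units.
#' Differences are always `d = y - x`, so to reproduce a "device under test
#' minus reference" convention pass the reference as `x`.
#'
#' @param subject subject identifiers (one per row; repeats mark repeated
#'   measurements).
#' @param x,y paired measurements.
#' @return a validated data.frame with columns `subject`, `x`, `y`.
#' @export
paired_obs <- function(subject, x, y) {
  if (length(subject) != length(x) || length(x) != length(y))
    stop("subject, x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed in pairs")
  data.frame(subject = as.character(subject), x = as.numeric(x),
             y = as.numeric(y))
}

.check_pairs <- function(pairs) {
  stopifnot(all(c("subject", "x", "y") %in% names(pairs)))
  if (anyNA(pairs$x) || anyNA(pairs$y)) stop("missing values in pairs")
  pairs
}

#' Bland-Altman agreement, with a repeated-measures variant
#'
#' Computes the mean difference (bias) and 95% limits of agreement
#' `bias +/- 1.96 * sd_total` for paired measurements.  When several
#' subjects contribute two or more pairs each, the SD of the differences is
#' built from variance components — a one-way random-effects ANOVA of the
#' differences with subject as the factor — so that clustering within
#' subjects does not understate the limits:
#' `sd_total = sqrt(sigma2_between + sigma2_within)`.  With one pair per
#' subject (or a single subject) the method reduces exactly to the classic
#' Bland-Altman SD of the differences.  The bias is the pooled mean of all
#' differences.
#'
#' @param pairs data.frame from [paired_obs()].
#' @param conf_level confidence level for the optional MOVER-style interval
#'   around each limit of agreement (default 0.95).
#' @return an object of class `agreement_result`: `bias`, `loa_lower`,
#'   `loa_upper`, `sd_total`, `var_between`, `var_within`, `n_subjects`,
#'   `n_pairs`, `method`, and `loa_ci` (a 2x2 matrix of approximate
#'   confidence bounds for the lower/upper limit, `NA` in degenerate cases).
#' @export
bland_altman <- function(pairs, conf_level = 0.95) {
  pairs <- .check_pairs(pairs)
  d <- pairs$y - pairs$x
  N <- length(d)
  if (N < 3) stop("at least 3 pairs required")
  subj <- factor(pairs$subject)
  k <- nlevels(subj)
  ni <- as.vector(table(subj))
  z <- stats::qnorm(0.975)
  bias <- mean(d)
  repeated <- k >= 2 && any(ni >= 2)
  if (repeated && N - k > 0) {
    di <- tapply(d, subj, mean)
    ssb <- sum(ni * (di - bias)^2)
    ssw <- sum((d - di[subj])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (N - k)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    var_b <- max(0, (msb - msw) / n0)
    var_w <- msw
    sd_total <- sqrt(var_b + var_w)
    method <- "repeated-measures Bland-Altman (variance components)"
    se_bias <- sqrt(var_b * sum(ni^2) / N^2 + var_w / N)
    # delta-method SE of sd_total from the mean-square sampling variances
    v_s2 <- (msb / n0)^2 * 2 / (k - 1) +
      ((1 - 1 / n0) * msw)^2 * 2 / max(1, N - k)
    se_s <- if (sd_total > 0) sqrt(v_s2) / (2 * sd_total) else 0
  } else {
    var_b <- 0
    var_w <- stats::var(d)
    sd_total <- sqrt(var_w)
    method <- "classic Bland-Altman"
    se_bias <- sd_total / sqrt(N)
    se_s <- if (sd_total > 0) sd_total * sqrt(1 / (2 * (N - 1))) else 0
  }
  loa_lower <- bias - z * sd_total
  loa_upper <- bias + z * sd_total
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- sqrt((zc * se_bias)^2 + (z * zc * se_s)^2)  # MOVER-style combination
  loa_ci <- rbind(lower = c(loa_lower - half, loa_lower + half),
                  upper = c(loa_upper - half, loa_upper + half))
  colnames(loa_ci) <- c("ci_lower", "ci_upper")
  structure(list(bias = bias, loa_lower = loa_lower, loa_upper = loa_upper,
                 sd_total = sd_total, var_between = var_b, var_within = var_w,
                 n_subjects = k, n_pairs = N, method = method,
                 loa_ci = loa_ci),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s\n  bias = %.4g, 95%% LOA [%.4g, %.4g] (sd = %.4g; %d subjects, %d pairs)\n",
              x$method, x$bias, x$loa_lower, x$loa_upper, x$sd_total,
              x$n_subjects, x$n_pairs))
  invisible(x)
}

#' Intraclass correlation: single measurement, absolute agreement
#'
#' ICC for a two-way model with `n` subjects and `k = 2` methods (one pair
#' per subject), absolute-agreement definition, single-measurement unit —
#' ICC(A,1) in the McGraw & Wong taxonomy:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' which penalises systematic offsets between methods.  The 95% confidence
#' interval uses the F-distribution closed forms.  Under the
#' absolute-agreement definition the mixed-model estimate and interval are
#' computed with the same formulas as the random-model ones; only the
#' population interpretation differs, and the result carries the model
#' label.
#'
#' @param pairs data.frame from [paired_obs()], one row per subject.
#' @param model `"two-way random"` (methods sampled from a population, e.g.
#'   interchangeable devices) or `"two-way mixed"` (the methods are the
#'   only ones of interest, e.g. fixed metric variants).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `model`, `type`, and mean squares `msr`, `msc`, `mse`.
#' @export
icc_absolute_single <- function(pairs, model = c("two-way random", "two-way mixed"),
                                conf_level = 0.95) {
  model <- match.arg(model)
  pairs <- .check_pairs(pairs)
  if (anyDuplicated(pairs$subject))
    stop("one pair per subject expected; aggregate repeated measurements first")
  n <- nrow(pairs)
  if (n < 2) stop("at least 2 subjects required")
  k <- 2
  m <- cbind(pairs$x, pairs$y)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - grand)^2) - sum((rowMeans(m) - grand)^2) * k -
    sum((colMeans(m) - grand)^2) * n
  dfe <- (n - 1) * (k - 1)
  mse <- sse / dfe
  if (mse < 0 && mse > -1e-12) mse <- 0
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) {
    warning("degenerate ANOVA table: ICC clamped")
    icc <- 0
  } else {
    icc <- (msr - mse) / denom
  }
  icc <- max(-1, min(1, icc))
  alpha <- 1 - conf_level
  if (icc == 1) {
    ci <- c(1, 1)  # perfect agreement: no residual variability
  } else if (denom <= 0) {
    ci <- c(NA_real_, NA_real_)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(NA_real_, 1)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(max(-1, lower), min(1, upper))
    }
  }
  structure(list(icc = icc, ci_lower = ci[1], ci_upper = ci[2],
                 model = model, type = "absolute agreement, single measurement",
                 msr = msr, msc = msc, mse = mse, n_subjects = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,1) = %.3f (95%% CI %.3f, %.3f), %s, n = %d\n",
              x$icc, x$ci_lower, x$ci_upper, x$model, x$n_subjects))
  invisible(x)
}

#' Repeated-measures correlation
#'
#' Within-subject association between `x` and `y` from an ANCOVA with
#' subject as a categorical factor and a common slope for `x`:
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with
#' `df = N - n_subjects - 1`, and a two-sided p-value from
#' `F(1, df)`.  Subjects contributing fewer than two observations carry no
#' within-subject information and are dropped with a warning.  The estimate
#' is invariant to adding any per-subject constant to `x` or to `y`.
#'
#' @param pairs data.frame from [paired_obs()].
#' @return an object of class `rm_corr_result`: `r_rm`, `df`, `p_value`,
#'   `slope`, `n_subjects`, `n_obs`.
#' @export
rm_corr <- function(pairs) {
  pairs <- .check_pairs(pairs)
  ni <- table(pairs$subject)
  drop <- names(ni)[ni < 2]
  if (length(drop)) {
    warning("dropping ", length(drop), " subject(s) with < 2 observations")
    pairs <- pairs[!(pairs$subject %in% drop), , drop = FALSE]
  }
  if (length(unique(pairs$subject)) < 2)
    stop("at least 2 subjects with >= 2 observations required")
  subj <- factor(pairs$subject)
  dat <- transform(pairs, subj = subj)
  fit0 <- stats::lm(y ~ subj, data = dat)
  fit <- stats::lm(y ~ subj + x, data = dat)
  # sequential sum of squares for x after the subject intercepts
  ss_e <- sum(stats::residuals(fit)^2)
  ss_x <- sum(stats::residuals(fit0)^2) - ss_e
  slope <- unname(stats::coef(fit)["x"])
  df <- nrow(pairs) - nlevels(subj) - 1
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_e))
  if (!is.finite(r)) r <- 0
  fstat <- if (ss_e > 0) (ss_x / 1) / (ss_e / df) else Inf
  p <- if (is.finite(fstat)) stats::pf(fstat, 1, df, lower.tail = FALSE) else 0
  structure(list(r_rm = r, df = df, p_value = p, slope = slope,
                 n_subjects = nlevels(subj), n_obs = nrow(pairs)),
            class = "rm_corr_result")
}

#' @export
print.rm_corr_result <- function(x, ...) {
  cat(sprintf("<rm_corr_result> r_rm = %.4f (df = %d, p = %.3g)\n",
              x$r_rm, x$df, x$p_value))
  invisible(x)
}

#' Repeated-measures coefficient of determination
#'
#' @param pairs data.frame from [paired_obs()].
#' @return `r_rm^2` from [rm_corr()].
#' @export
r_squared_rm <- function(pairs) {
  rm_corr(pairs)$r_rm^2
}

#' Paired t-test with zero-variance handling
#'
#' Thin wrapper over [stats::t.test()] for paired data that handles the
#' degenerate constant-difference case (which the base test refuses):
#' identical vectors give `t = 0, p = 1`; a constant non-zero difference
#' gives an infinite `t` with `p = 0` and `zero_variance = TRUE`.
#'
#' @param x,y paired numeric vectors.
#' @return list with `t`, `df`, `p`, `zero_variance`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs required")
  d <- y - x
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1, zero_variance = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, zero_variance = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' @param v numeric vector (3 to 5000 values).
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(v) {
  if (length(v) < 3) stop("at least 3 values required")
  s <- stats::shapiro.test(v)
  list(W = unname(s$statistic), p = s$p.value)
}

#' F-test for equality of variances
#'
#' @param a,b numeric vectors.
#' @return list with `F`, `df1`, `df2`, `p` (two-sided).
#' @export
variance_f_test <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("at least 3 values per group required")
  f <- stats::var.test(a, b)
  list(F = unname(f$statistic), df1 = unname(f$parameter[1]),
       df2 = unname(f$parameter[2]), p = f$p.value)
}
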