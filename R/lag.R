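#' Detect the integer-epoch lag between two simultaneously worn devices
#'
#' Scans shifts `k` in `[-max_lag, max_lag]` and returns the one maximising
#' the Pearson correlation between series `a` and series `b` delayed by `k`
#' epochs; a positive lag means events appear `k` epochs later in `b` than
#' in `a`.  Only epochs that are wear-true in both series (after shifting)
#' enter the correlation.  Ties are broken towards the smallest `|k|`, then
#' towards negative `k`.  This automates the study practice of aligning
#' paired devices before comparing their counts: free-living sessions have
#' shown lags from a few epochs up to 229 epochs, hence the generous
#' default window.
#'
#' @param a,b [epoch_series()] objects with the same epoch length.
#' @param max_lag largest shift searched, in epochs (default 300, i.e.
#'   75 min at 15 s epochs).
#' @return a list of class `lag_result`: `lag_epochs`, `score_at_lag`,
#'   `reference_device` (device id of `a`), `method`, and a `scores`
#'   data.frame of every candidate shift.
#' @export
detect_lag <- function(a, b, max_lag = 300) {
  if (a$epoch_length != b$epoch_length)
    stop("series must share an epoch length")
  na <- length(a$values); nb <- length(b$values)
  if (min(na, nb) < 3) stop("series too short for lag detection")
  if (stats::sd(a$values[a$wear]) == 0 || stats::sd(b$values[b$wear]) == 0)
    stop("constant series: correlation undefined")
  ks <- seq.int(-max_lag, max_lag)
  score <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    # b delayed by k: compare a[t] with b[t + k]
    ia <- seq.int(max(1, 1 - k), min(na, nb - k))
    if (length(ia) < 3) next
    ib <- ia + k
    ok <- a$wear[ia] & b$wear[ib]
    if (sum(ok) < 3) next
    va <- a$values[ia][ok]; vb <- b$values[ib][ok]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    score[i] <- stats::cor(va, vb)
  }
  if (all(is.na(score))) stop("no shift with enough overlapping wear epochs")
  best <- order(-score, abs(ks), ks, na.last = TRUE)[1]
  structure(list(lag_epochs = ks[best], score_at_lag = score[best],
                 reference_device = a$device_id,
                 method = "cross-correlation",
                 scores = data.frame(lag = ks, score = score)),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> lag = %d epochs (r = %.4f) vs reference %s\n",
              x$lag_epochs, x$score_at_lag, x$reference_device))
  invisible(x)
}

#' Choose the reference device from logged rest periods
#'
#' The more trustworthy device is the one that actually records zero counts
#' while the log sheet says the participant was at rest.  Returns the
#' device id with the greater fraction of zero-count epochs whose start
#' times fall inside the rest intervals; ties go to `a`.
#'
#' @param a,b [epoch_series()] objects.
#' @param rest_log a [wear_log()]-style set of rest intervals.
#' @return the selected `device_id` string.
#' @export
rest_anchored_reference <- function(a, b, rest_log) {
  if (length(rest_log$on) < 1) stop("at least one rest interval required")
  frac0 <- function(s) {
    st <- as.numeric(epoch_starts(s))
    inside <- rep(FALSE, length(st))
    for (j in seq_along(rest_log$on))
      inside <- inside | (st >= as.numeric(rest_log$on[j]) &
                            st < as.numeric(rest_log$off[j]))
    if (!any(inside)) return(NA_real_)
    mean(s$values[inside] == 0)
  }
  fa <- frac0(a); fb <- frac0(b)
  if (is.na(fa) && is.na(fb)) return(a$device_id)
  if (is.na(fb) || (!is.na(fa) && fa >= fb)) a$device_id else b$device_id
}

#' Shift an epoch series by a whole number of epochs
#'
#' Delays the series by `k` epochs (advance for negative `k`) while keeping
#' its length and start time: output epoch `i` carries the input value from
#' epoch `i - k`.  The `|k|` epochs exposed at one end have no counterpart;
#' they are filled with value 0 and marked non-wear so they drop out of any
#' paired analysis.  `apply_lag(apply_lag(s, k), -k)` restores the
#' overlapping region exactly.
#'
#' @param series an [epoch_series()].
#' @param k signed shift in epochs, `|k| < length(series)`.
#' @return the shifted [epoch_series()].
#' @export
apply_lag <- function(series, k) {
  n <- length(series$values)
  k <- as.integer(k)
  if (abs(k) >= n) stop("|k| must be smaller than the series length")
  if (k == 0) return(series)
  v <- numeric(n); w <- rep(FALSE, n)
  if (k > 0) {
    v[(k + 1):n] <- series$values[1:(n - k)]
    w[(k + 1):n] <- series$wear[1:(n - k)]
  } else {
    v[1:(n + k)] <- series$values[(1 - k):n]
    w[1:(n + k)] <- series$wear[(1 - k):n]
  }
  series$values <- v
  series$wear <- w
  series
}
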