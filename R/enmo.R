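#' Parameters for ENMO epoch summarisation
#'
#' @param epoch_length epoch length in seconds (default 15); must contain an
#'   integer number of samples at the signal's rate.
#' @param truncate_negative truncate negative ENMO to zero at the sample
#'   level before averaging (default `TRUE`, matching GGIR's documented
#'   behaviour).
#' @param truncate_after_average alternative ordering: average the signed
#'   per-sample values, then truncate the epoch mean (default `FALSE`).
#' @param calibrate run [recalibrate()] before summarising (default `FALSE`).
#' @param stationary_sd_threshold per-axis SD below which a window counts as
#'   stationary, in g (default 0.013).
#' @param stationary_window stationary-window length in seconds (default 10).
#' @return a list of class `enmo_params`.
#' @export
enmo_params <- function(epoch_length = 15, truncate_negative = TRUE,
                        truncate_after_average = FALSE, calibrate = FALSE,
                        stationary_sd_threshold = 0.013,
                        stationary_window = 10) {
  if (epoch_length <= 0 || stationary_sd_threshold <= 0 || stationary_window <= 0)
    stop("lengths and thresholds must be positive")
  structure(list(epoch_length = epoch_length,
                 truncate_negative = truncate_negative,
                 truncate_after_average = truncate_after_average,
                 calibrate = calibrate,
                 stationary_sd_threshold = stationary_sd_threshold,
                 stationary_window = stationary_window),
            class = "enmo_params")
}

#' Per-sample ENMO
#'
#' Euclidean norm of the triaxial acceleration minus 1 g, in mg.  With
#' truncation on (the default) negative values are clipped to zero, so a
#' stationary device reads 0 regardless of orientation.  Rotation-invariant
#' by construction.
#'
#' @param ax,ay,az acceleration in g (vectors of equal length).
#' @param truncate clip negative values to zero (default `TRUE`).
#' @return ENMO per sample in mg.
#' @export
enmo_per_sample <- function(ax, ay, az, truncate = TRUE) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az)))
    stop("non-finite acceleration sample")
  e <- (sqrt(ax^2 + ay^2 + az^2) - 1) * 1000
  if (truncate) e <- pmax(0, e)
  e
}

#' ENMO averaged over fixed epochs
#'
#' Computes per-sample ENMO and averages it within consecutive
#' non-overlapping epochs.  A trailing partial epoch is discarded, so the
#' output has `floor(n_samples / (rate * epoch_length))` epochs.
#'
#' @param signal a [raw_signal()].
#' @param params an [enmo_params()].
#' @return an [epoch_series()] in mg with an all-`TRUE` wear mask.
#' @export
enmo_epochs <- function(signal, params = enmo_params()) {
  spe <- signal$sample_rate * params$epoch_length
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_length must contain an integer number of samples")
  spe <- as.integer(round(spe))
  n <- length(signal$ax)
  if (n < spe) stop("signal shorter than one epoch")
  if (isTRUE(params$calibrate)) {
    cal <- recalibrate(signal, params)
    signal <- cal$signal
  }
  n_ep <- n %/% spe
  use <- seq_len(n_ep * spe)
  e <- enmo_per_sample(signal$ax[use], signal$ay[use], signal$az[use],
                       truncate = params$truncate_negative &&
                         !params$truncate_after_average)
  m <- colMeans(matrix(e, nrow = spe, ncol = n_ep))
  if (params$truncate_after_average) m <- pmax(0, m)
  epoch_series(m, epoch_length = params$epoch_length,
               participant_id = signal$participant_id,
               device_id = signal$device_id, units = "mg")
}

#' Simplified stationary-period recalibration
#'
#' A lightweight offset-and-gain recalibration: windows whose per-axis SD is
#' below `stationary_sd_threshold` are taken as stationary, and per-axis
#' gain and offset are fitted by iterative least squares so that the
#' stationary window means have unit norm (the local gravity vector).  The
#' fit alternates between projecting calibrated window means onto the unit
#' sphere and regressing each axis on its raw mean — an intentionally
#' simple approximation to the ellipsoid auto-calibration used by full
#' processing pipelines, adequate when at least three distinct orientations
#' are observed.  With fewer than three stationary windows (or fewer than
#' three distinct orientations) the signal is returned unchanged and the
#' report's `warning` field is set.
#'
#' @param signal a [raw_signal()].
#' @param params an [enmo_params()].
#' @param max_iter maximum number of alternating iterations.
#' @return a list with elements `signal` (recalibrated [raw_signal()]) and
#'   `report` (offsets, gains, `n_windows`, `residual_before`,
#'   `residual_after`, `warning`).
#' @export
recalibrate <- function(signal, params = enmo_params(), max_iter = 50) {
  wlen <- as.integer(round(params$stationary_window * signal$sample_rate))
  n <- length(signal$ax)
  nw <- n %/% wlen
  report <- list(offsets = c(0, 0, 0), gains = c(1, 1, 1), n_windows = 0L,
                 residual_before = NA_real_, residual_after = NA_real_,
                 warning = FALSE)
  if (nw < 1) { report$warning <- TRUE; return(list(signal = signal, report = report)) }
  use <- seq_len(nw * wlen)
  g <- function(v) matrix(v[use], nrow = wlen)
  mx <- g(signal$ax); my <- g(signal$ay); mz <- g(signal$az)
  sds <- cbind(apply(mx, 2, stats::sd), apply(my, 2, stats::sd),
               apply(mz, 2, stats::sd))
  stat <- which(apply(sds, 1, max) < params$stationary_sd_threshold)
  means <- cbind(colMeans(mx), colMeans(my), colMeans(mz))[stat, , drop = FALSE]
  # require at least 3 windows with meaningfully distinct orientations
  distinct <- if (nrow(means) >= 3) {
    qr(scale(means, scale = FALSE))$rank >= 2 || nrow(unique(round(means, 3))) >= 3
  } else FALSE
  report$n_windows <- nrow(means)
  if (nrow(means) < 3 || !distinct) {
    report$warning <- TRUE
    return(list(signal = signal, report = report))
  }
  resid <- function(m) sum((sqrt(rowSums(m^2)) - 1)^2)
  report$residual_before <- resid(means)
  offset <- c(0, 0, 0); gain <- c(1, 1, 1)
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(means, 2, gain, `*`), 2, offset, `+`)
    nrm <- sqrt(rowSums(cal^2))
    target <- cal / nrm  # closest points on the unit sphere
    new_off <- numeric(3); new_gain <- numeric(3)
    for (j in 1:3) {
      if (stats::sd(means[, j]) < 1e-12) {
        # axis never varies across orientations: fit offset only
        new_gain[j] <- gain[j]
        new_off[j] <- mean(target[, j]) - new_gain[j] * mean(means[, j])
      } else {
        fit <- stats::lm.fit(cbind(1, means[, j]), target[, j])
        new_off[j] <- fit$coefficients[1]; new_gain[j] <- fit$coefficients[2]
      }
    }
    delta <- max(abs(new_off - offset), abs(new_gain - gain))
    offset <- new_off; gain <- new_gain
    if (delta < 1e-10) break
  }
  cal_means <- sweep(sweep(means, 2, gain, `*`), 2, offset, `+`)
  report$residual_after <- resid(cal_means)
  if (report$residual_after > report$residual_before + 1e-12) {
    # never make the stationary residual worse; fall back to identity
    report$warning <- TRUE
    report$offsets <- c(0, 0, 0); report$gains <- c(1, 1, 1)
    report$residual_after <- report$residual_before
    return(list(signal = signal, report = report))
  }
  report$offsets <- offset; report$gains <- gain
  signal$ax <- gain[1] * signal$ax + offset[1]
  signal$ay <- gain[2] * signal$ay + offset[2]
  signal$az <- gain[3] * signal$az + offset[3]
  list(signal = signal, report = report)
}
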