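#' Device-comparison workflow
#'
#' Runs the paired-device comparison over a set of sessions: per session,
#' detect the inter-device lag (optionally choosing the reference device by
#' rest anchoring when a rest log is supplied), align device `b` onto the
#' reference, pool the overlapping wear epochs, and compute per-activity and
#' combined agreement: OLS slope and intercept of `b` on `a`, a
#' repeated-measures R-squared, and repeated-measures Bland-Altman bias and
#' limits of agreement.
#'
#' @param sessions list of sessions; each a list with elements `a` and `b`
#'   ([epoch_series()] worn simultaneously) and optional `activity` label
#'   and `rest_log` ([wear_log()]-style rest intervals).
#' @param max_lag lag search window in epochs.
#' @return list with `lags` (one row per session) and `agreement` (one row
#'   per activity plus `"combined"`).
#' @export
compare_devices <- function(sessions, max_lag = 300) {
  if (!length(sessions)) stop("no sessions supplied")
  lag_rows <- list(); pooled <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    a <- s$a; b <- s$b
    if (is.null(a) || is.null(b)) {
      warning("session ", i, " lacks a paired series; skipped")
      next
    }
    ref <- if (!is.null(s$rest_log)) rest_anchored_reference(a, b, s$rest_log)
           else a$device_id
    if (identical(ref, b$device_id)) { tmp <- a; a <- b; b <- tmp }
    lr <- detect_lag(a, b, max_lag = max_lag)
    b_al <- apply_lag(b, -lr$lag_epochs)
    n <- min(length(a), length(b_al))
    ok <- a$wear[seq_len(n)] & b_al$wear[seq_len(n)]
    lag_rows[[length(lag_rows) + 1]] <- data.frame(
      session = i, subject = a$participant_id,
      activity = s$activity %||% "all",
      reference = ref, lag_epochs = lr$lag_epochs,
      score = lr$score_at_lag)
    pooled[[length(pooled) + 1]] <- data.frame(
      subject = a$participant_id, activity = s$activity %||% "all",
      x = a$values[seq_len(n)][ok], y = b_al$values[seq_len(n)][ok])
  }
  if (!length(pooled)) stop("no usable sessions")
  df <- do.call(rbind, pooled)
  agree_row <- function(sub, label) {
    fit <- stats::lm(y ~ x, data = sub)
    r2 <- tryCatch(r_squared_rm(sub),
                   error = function(e) stats::cor(sub$x, sub$y)^2,
                   warning = function(w) stats::cor(sub$x, sub$y)^2)
    ba <- bland_altman(sub)
    data.frame(activity = label,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, bias = ba$bias,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
               n_pairs = nrow(sub))
  }
  acts <- unique(df$activity)
  rows <- lapply(acts, function(a) agree_row(df[df$activity == a, ], a))
  if (length(acts) > 1) rows <- c(rows, list(agree_row(df, "combined")))
  list(lags = do.call(rbind, lag_rows),
       agreement = do.call(rbind, rows))
}

#' Per-intensity minutes-per-day comparison
#'
#' Joins two [summarise_day()] tables (same participants and days, two
#' devices) and, per intensity category, reports the OLS slope and
#' intercept, repeated-measures R-squared, repeated-measures Bland-Altman
#' bias and limits, ICC(A,1) with its confidence interval (two-way random
#' model, participant-day rows), and a paired t-test.  Differences are
#' `device b minus device a`.
#'
#' @param summary_a,summary_b data.frames from [summarise_day()].
#' @param model ICC model label, passed to [icc_absolute_single()].
#' @return data.frame, one row per category (LPA, MPA, VPA, total_pa, SED).
#' @export
compare_intensity_minutes <- function(summary_a, summary_b,
                                      model = "two-way random") {
  key <- c("participant_id", "day")
  m <- merge(summary_a, summary_b, by = key, suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no overlapping participant-days")
  cats <- c("LPA", "MPA", "VPA", "total_pa", "SED")
  rows <- lapply(cats, function(cc) {
    sub <- data.frame(subject = m$participant_id,
                      row_id = paste(m$participant_id, m$day, sep = "/"),
                      x = m[[paste0(cc, "_a")]], y = m[[paste0(cc, "_b")]])
    fit <- stats::lm(y ~ x, data = sub)
    r2 <- tryCatch(r_squared_rm(sub),
                   error = function(e) stats::cor(sub$x, sub$y)^2,
                   warning = function(w) stats::cor(sub$x, sub$y)^2)
    ba <- bland_altman(sub)
    icc <- icc_absolute_single(
      data.frame(subject = sub$row_id, x = sub$x, y = sub$y), model = model)
    tt <- paired_t(sub$x, sub$y)
    data.frame(category = cc,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, bias = ba$bias,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
               icc = icc$icc, icc_ci_lower = icc$ci_lower,
               icc_ci_upper = icc$ci_upper,
               t = tt$t, p = tt$p, n = nrow(sub))
  })
  do.call(rbind, rows)
}

#' Intensity-gradient computation and variant comparison
#'
#' Computes the requested IG variants for every participant — accIG from an
#' ENMO series, countIG and adjIG from a count series — plus the
#' occupied-bin ratio and first-bin composition diagnostics, then compares
#' the count-based variants against the accIG by Bland-Altman and ICC
#' (two-way mixed, absolute agreement) when at least two participants
#' provide both members of a pair.
#'
#' @param participants named list; each element a list with `counts` (a
#'   wear-masked count [epoch_series()]) and/or `enmo` (a wear-masked mg
#'   [epoch_series()]).
#' @param variants subset of `c("acc", "count_fine", "count_adjusted")`.
#' @return list with `per_participant` (one row each: the three IG slopes,
#'   occupancy ratio, first-bin LPA fraction) and `agreement` (one row per
#'   compared variant pair, `NULL` with fewer than 2 complete pairs).
#' @export
compute_ig_study <- function(participants,
                             variants = c("acc", "count_fine", "count_adjusted")) {
  if (!length(variants)) stop("no variants requested")
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  for (id in names(participants)) {
    p <- participants[[id]]
    need_counts <- any(c("count_fine", "count_adjusted") %in% variants)
    if ((("acc" %in% variants) && is.null(p$enmo)) ||
        (need_counts && is.null(p$counts))) {
      warning("participant ", id, " lacks a required stream; skipped")
      next
    }
    ig <- function(series, variant) {
      b <- bin_time(series, make_bin_scheme(variant))
      list(bin = b, fit = compute_ig(b))
    }
    acc <- if ("acc" %in% variants) ig(p$enmo, "acc")
    fine <- if ("count_fine" %in% variants) ig(p$counts, "count_fine")
    adj <- if ("count_adjusted" %in% variants) ig(p$counts, "count_adjusted")
    rows[[id]] <- data.frame(
      participant_id = id,
      acc_ig = if (!is.null(acc)) acc$fit$slope else NA_real_,
      count_ig = if (!is.null(fine)) fine$fit$slope else NA_real_,
      adj_ig = if (!is.null(adj)) adj$fit$slope else NA_real_,
      occupancy_ratio = if (!is.null(acc) && !is.null(fine))
        bin_occupancy_ratio(fine$bin, acc$bin) else NA_real_,
      first_bin_lpa = if (!is.null(adj))
        tryCatch(first_bin_composition(p$counts), error = function(e) NA_real_)
        else NA_real_)
  }
  if (!length(rows)) stop("no usable participants")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  agreement <- NULL
  if (nrow(per) >= 2 && "acc" %in% variants) {
    cmp <- function(ycol, label) {
      ok <- stats::complete.cases(per$acc_ig, per[[ycol]])
      if (sum(ok) < 2) return(NULL)
      prs <- data.frame(subject = per$participant_id[ok],
                        x = per$acc_ig[ok], y = per[[ycol]][ok])
      ba <- bland_altman(prs)
      icc <- icc_absolute_single(prs, model = "two-way mixed")
      data.frame(comparison = label, bias = ba$bias,
                 loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                 icc = icc$icc, icc_ci_lower = icc$ci_lower,
                 icc_ci_upper = icc$ci_upper, n = sum(ok))
    }
    agreement <- do.call(rbind, Filter(Negate(is.null), list(
      if ("count_fine" %in% variants) cmp("count_ig", "accIG_vs_countIG"),
      if ("count_adjusted" %in% variants) cmp("adj_ig", "accIG_vs_adjIG"))))
  }
  list(per_participant = per, agreement = agreement)
}

# polynomial rolling hash, enough to fingerprint a config in table headers
# without new dependencies
.config_hash <- function(obj) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(obj)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a result table with a provenance header
#'
#' Delimited text with comment lines carrying the package version and a
#' hash of the generating configuration, so runs are attributable.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param config object whose fingerprint goes in the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# igradient %s",
                     as.character(utils::packageVersion("igradient"))), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", .config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
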