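#' Count cutpoint sets
#'
#' A cutpoint set maps a non-negative integer epoch count to one of four
#' intensity categories — SED, LPA, MPA, VPA — via three ordered upper
#' boundaries (inclusive).  [evenson_cutpoints()] returns the Evenson
#' thresholds rescaled to 15 s epochs: SED 0–24, LPA 25–573, MPA 574–1002,
#' VPA >= 1003 counts.  The published bands leave count 25 unassigned
#' ("SED < 25", "LPA 26–573"); here it is assigned to LPA so the categories
#' partition the integers, the conservative choice for sedentary time.
#'
#' @param name label for the set.
#' @param epoch_length epoch length (s) the thresholds refer to.
#' @param sed_max,lpa_max,mpa_max inclusive upper bounds, in counts/epoch,
#'   for SED, LPA and MPA; everything above `mpa_max` is VPA.
#' @return an object of class `cutpoint_set`.
#' @export
cutpoint_set <- function(name, epoch_length, sed_max, lpa_max, mpa_max) {
  if (!(sed_max < lpa_max && lpa_max < mpa_max))
    stop("boundaries must be strictly increasing")
  structure(list(name = name, epoch_length = epoch_length,
                 sed_max = sed_max, lpa_max = lpa_max, mpa_max = mpa_max,
                 categories = c("SED", "LPA", "MPA", "VPA")),
            class = "cutpoint_set")
}

#' @rdname cutpoint_set
#' @export
evenson_cutpoints <- function() {
  cutpoint_set("evenson_15s", epoch_length = 15,
               sed_max = 24, lpa_max = 573, mpa_max = 1002)
}

#' Classify epoch counts into intensity categories
#'
#' @param counts non-negative epoch counts (vectorised).
#' @param cuts a [cutpoint_set()] (default [evenson_cutpoints()]).
#' @return factor with levels SED, LPA, MPA, VPA.
#' @export
classify_epochs <- function(counts, cuts = evenson_cutpoints()) {
  if (any(counts < 0)) stop("negative count")
  cut(counts, breaks = c(-Inf, cuts$sed_max, cuts$lpa_max, cuts$mpa_max, Inf),
      labels = cuts$categories, right = TRUE)
}

#' Daily minutes per intensity category
#'
#' Splits a wear-masked count series at local midnight and accumulates
#' wear-true epoch time per category and day.  Category minutes always sum
#' to wear minutes exactly (to epoch resolution).
#'
#' @param series a count-typed [epoch_series()] with its wear mask applied.
#' @param cuts a [cutpoint_set()]; its `epoch_length` must match the series.
#' @return data.frame with one row per calendar day: `participant_id`,
#'   `device_id`, `day`, `SED`, `LPA`, `MPA`, `VPA`, `total_pa`
#'   (LPA+MPA+VPA), `mvpa` (MPA+VPA), `wear_minutes`, all in minutes.
#' @export
summarise_day <- function(series, cuts = evenson_cutpoints()) {
  if (series$units != "counts") stop("cutpoints apply to count-typed series")
  if (cuts$epoch_length != series$epoch_length)
    stop("cutpoint set is for ", cuts$epoch_length, " s epochs, series uses ",
         series$epoch_length, " s")
  day <- as.Date(epoch_starts(series))
  cat_ <- classify_epochs(series$values, cuts)
  per_min <- series$epoch_length / 60
  rows <- lapply(split(seq_along(day), day), function(i) {
    w <- i[series$wear[i]]
    mins <- table(factor(cat_[w], levels = cuts$categories)) * per_min
    data.frame(participant_id = series$participant_id,
               device_id = series$device_id,
               day = day[i[1]],
               SED = unname(mins["SED"]), LPA = unname(mins["LPA"]),
               MPA = unname(mins["MPA"]), VPA = unname(mins["VPA"]),
               total_pa = unname(mins["LPA"] + mins["MPA"] + mins["VPA"]),
               mvpa = unname(mins["MPA"] + mins["VPA"]),
               wear_minutes = length(w) * per_min)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
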