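#' Epoch-level activity series
#'
#' The basic container for accelerometer output summarised over fixed-length
#' epochs: one value per epoch (integer activity counts, or ENMO in mg),
#' plus a wear mask of the same length.  Epochs are indexed by their start
#' time: epoch `i` starts at `start_time + (i - 1) * epoch_length`.
#'
#' @param values numeric vector of non-negative epoch values.  Count-typed
#'   series must be integer-valued.
#' @param epoch_length epoch length in seconds (default 15).
#' @param start_time `POSIXct` start of the first epoch.
#' @param participant_id,device_id identifier strings.
#' @param units `"counts"` or `"mg"`.
#' @param wear logical wear mask, same length as `values` (default all `TRUE`).
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(values, epoch_length = 15,
                         start_time = as.POSIXct("2024-01-01 07:00:00", tz = "UTC"),
                         participant_id = "P01", device_id = "dev",
                         units = c("counts", "mg"), wear = NULL) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (is.null(wear)) wear <- rep(TRUE, length(values))
  if (length(wear) != length(values))
    stop("`wear` and `values` must have the same length")
  if (!is.numeric(epoch_length) || epoch_length <= 0)
    stop("`epoch_length` must be a positive number of seconds")
  if (anyNA(values))
    stop("missing epoch value at row ", which(is.na(values))[1])
  if (any(values < 0))
    stop("negative epoch value at row ", which(values < 0)[1])
  if (units == "counts" && any(values != round(values)))
    stop("count-typed series must be integer-valued (row ",
         which(values != round(values))[1], ")")
  structure(
    list(participant_id = as.character(participant_id),
         device_id = as.character(device_id),
         start_time = as.POSIXct(start_time),
         epoch_length = epoch_length,
         units = units,
         values = values,
         wear = as.logical(wear)),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s / %s: %d x %gs epochs (%s), %d wear-true\n",
              x$participant_id, x$device_id, length(x$values),
              x$epoch_length, x$units, sum(x$wear)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

#' Start times of every epoch in a series
#' @param series an [epoch_series()].
#' @return `POSIXct` vector, one element per epoch.
#' @export
epoch_starts <- function(series) {
  series$start_time + (seq_along(series$values) - 1) * series$epoch_length
}

#' Raw triaxial acceleration signal
#'
#' @param ax,ay,az equal-length numeric vectors of acceleration in g.
#' @param sample_rate sampling rate in Hz (default 30).
#' @param participant_id,device_id identifier strings.
#' @return an object of class `raw_signal`.
#' @export
raw_signal <- function(ax, ay, az, sample_rate = 30,
                       participant_id = "P01", device_id = "dev") {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axis vectors must have equal length")
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  structure(
    list(participant_id = as.character(participant_id),
         device_id = as.character(device_id),
         sample_rate = sample_rate,
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)),
    class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %s / %s: %d samples at %g Hz (%.1f s)\n",
              x$participant_id, x$device_id, length(x$ax),
              x$sample_rate, length(x$ax) / x$sample_rate))
  invisible(x)
}

#' Wear-time log
#'
#' Self-reported on/off intervals for one participant.  Intervals are
#' half-open `[on, off)`; overlapping or touching intervals are merged and
#' the list is sorted, so the stored form is canonical.
#'
#' @param participant_id identifier string.
#' @param on,off `POSIXct` vectors of equal length with `on < off` pairwise.
#' @return an object of class `wear_log`.
#' @export
wear_log <- function(participant_id, on, off) {
  on <- as.POSIXct(on); off <- as.POSIXct(off)
  if (length(on) != length(off)) stop("`on` and `off` must have equal length")
  if (any(!(on < off))) stop("every interval must satisfy on < off")
  if (length(on) > 1) {
    o <- order(on)
    on <- on[o]; off <- off[o]
    # merge overlapping/adjacent intervals
    keep_on <- on[1]; keep_off <- off[1]
    res_on <- res_off <- c()
    for (i in seq_along(on)[-1]) {
      if (on[i] <= keep_off) {
        keep_off <- max(keep_off, off[i])
      } else {
        res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
        keep_on <- on[i]; keep_off <- off[i]
      }
    }
    on <- .POSIXct(c(res_on, keep_on), tz = attr(keep_on, "tzone"))
    off <- .POSIXct(c(res_off, keep_off), tz = attr(keep_off, "tzone"))
  }
  structure(list(participant_id = as.character(participant_id),
                 on = on, off = off),
            class = "wear_log")
}

#' @export
print.wear_log <- function(x, ...) {
  cat(sprintf("<wear_log> %s: %d interval(s)\n", x$participant_id,
              length(x$on)))
  invisible(x)
}

.TS_FMT <- "%Y-%m-%dT%H:%M:%S"

#' Read an epoch series from delimited text
#'
#' The native dialect is a comma-separated file with columns
#' `timestamp,value` (optionally `timestamp,value,wear`), ISO-8601
#' timestamps, preceded by optional `# key: value` metadata lines
#' (`participant`, `device`, `units`).  An ActiLife-like preamble of
#' arbitrary header lines is also accepted: all lines before the
#' `timestamp,value` column-header sentinel are skipped.
#'
#' @param path file to read.
#' @param epoch_length expected epoch length in seconds; checked against the
#'   timestamp spacing when more than one row is present.
#' @param units value units, overriding any `# units:` metadata line.
#' @return an [epoch_series()] with wear initialised from the `wear` column,
#'   or all-`TRUE` when absent.
#' @export
read_epoch_csv <- function(path, epoch_length = 15, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^timestamp,", lines)
  if (!length(hdr)) stop("no `timestamp,...` header line found in ", path)
  hdr <- hdr[1]
  meta <- .parse_meta(lines[seq_len(hdr - 1)])
  if (is.null(units)) units <- meta$units %||% "counts"
  df <- utils::read.csv(text = lines[hdr:length(lines)],
                        stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no epoch rows in ", path)
  ts <- as.POSIXct(df$timestamp, format = .TS_FMT, tz = "UTC")
  if (anyNA(ts))
    stop("malformed timestamp at row ", which(is.na(ts))[1], " of ", path)
  if (anyNA(df$value))
    stop("missing epoch value at row ", which(is.na(df$value))[1], " of ", path)
  if (any(df$value < 0))
    stop("negative epoch value at row ", which(df$value < 0)[1], " of ", path)
  if (nrow(df) > 1) {
    gaps <- as.numeric(diff(ts), units = "secs")
    if (any(abs(gaps - epoch_length) > 1e-6))
      stop("missing or irregular epochs: gap of ", gaps[which.max(abs(gaps - epoch_length))],
           " s where ", epoch_length, " s expected")
  }
  wear <- if ("wear" %in% names(df)) as.logical(df$wear) else rep(TRUE, nrow(df))
  epoch_series(df$value, epoch_length = epoch_length, start_time = ts[1],
               participant_id = meta$participant %||% "P01",
               device_id = meta$device %||% "dev",
               units = units, wear = wear)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_meta <- function(lines) {
  m <- regmatches(lines, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", lines))
  m <- Filter(length, m)
  stats::setNames(lapply(m, `[`, 3), vapply(m, `[`, "", 2))
}

#' Write an epoch series as delimited text
#'
#' Inverse of [read_epoch_csv()]: metadata comment lines, then
#' `timestamp,value,wear` rows with ISO-8601 timestamps.
#'
#' @param series an [epoch_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  ts <- format(epoch_starts(series), .TS_FMT, tz = "UTC")
  lines <- c(
    sprintf("# participant: %s", series$participant_id),
    sprintf("# device: %s", series$device_id),
    sprintf("# units: %s", series$units),
    "timestamp,value,wear",
    sprintf("%s,%s,%s", ts, format(series$values, trim = TRUE, scientific = FALSE),
            series$wear))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write raw triaxial signals as delimited text
#'
#' Four columns: `sample,ax,ay,az` with acceleration in g, plus `# key:`
#' metadata lines (`participant`, `device`, `sample_rate`).
#'
#' @param path file to read or write.
#' @return [read_raw_csv()]: a [raw_signal()]; [write_raw_csv()]: `path`.
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^sample,", lines)[1]
  if (is.na(hdr)) stop("no `sample,ax,ay,az` header line found in ", path)
  meta <- .parse_meta(lines[seq_len(hdr - 1)])
  df <- utils::read.csv(text = lines[hdr:length(lines)])
  raw_signal(df$ax, df$ay, df$az,
             sample_rate = as.numeric(meta$sample_rate %||% 30),
             participant_id = meta$participant %||% "P01",
             device_id = meta$device %||% "dev")
}

#' @rdname read_raw_csv
#' @param signal a [raw_signal()].
#' @export
write_raw_csv <- function(signal, path) {
  lines <- c(
    sprintf("# participant: %s", signal$participant_id),
    sprintf("# device: %s", signal$device_id),
    sprintf("# sample_rate: %g", signal$sample_rate),
    "sample,ax,ay,az",
    sprintf("%d,%.6g,%.6g,%.6g", seq_along(signal$ax),
            signal$ax, signal$ay, signal$az))
  writeLines(lines, path)
  invisible(path)
}

#' Read a wear log from delimited text
#'
#' Expects columns `participant_id,on,off` with ISO-8601 timestamps; one
#' [wear_log()] is returned per participant.
#'
#' @param path file to read.
#' @return a named list of [wear_log()] objects, one per participant.
#' @export
read_wear_log <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  on <- as.POSIXct(df$on, format = .TS_FMT, tz = "UTC")
  off <- as.POSIXct(df$off, format = .TS_FMT, tz = "UTC")
  if (anyNA(on) || anyNA(off)) stop("malformed timestamp in wear log ", path)
  out <- lapply(split(seq_len(nrow(df)), df$participant_id), function(i)
    wear_log(df$participant_id[i[1]], on[i], off[i]))
  out
}

#' Apply a wear log to an epoch series
#'
#' Marks epoch `i` as wear iff its start time falls inside some logged
#' `[on, off)` interval.  Values are unchanged; the operation is idempotent.
#'
#' @param series an [epoch_series()].
#' @param log a [wear_log()] for the same participant.
#' @return the series with its wear mask replaced.
#' @export
apply_wear_log <- function(series, log) {
  if (!inherits(log, "wear_log")) stop("`log` must be a wear_log")
  if (!identical(series$participant_id, log$participant_id))
    stop("participant mismatch: series is ", series$participant_id,
         ", log is ", log$participant_id)
  st <- as.numeric(epoch_starts(series))
  wear <- rep(FALSE, length(st))
  for (j in seq_along(log$on))
    wear <- wear | (st >= as.numeric(log$on[j]) & st < as.numeric(log$off[j]))
  series$wear <- wear
  series
}

#' Total wear time of a series in minutes
#'
#' @param series an [epoch_series()].
#' @return (number of wear-true epochs) x epoch_length / 60.
#' @export
wear_minutes <- function(series) {
  sum(series$wear) * series$epoch_length / 60
}
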