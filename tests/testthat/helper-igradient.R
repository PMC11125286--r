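# shared builders for small in-code fixtures

count_series <- function(values, ...) {
  epoch_series(values, epoch_length = 15, units = "counts", ...)
}

mg_series <- function(values, ...) {
  epoch_series(values, epoch_length = 15, units = "mg", ...)
}

# autocorrelated non-negative integer series for lag experiments
rand_count_series <- function(n, seed) {
  set.seed(seed)
  v <- round(pmax(0, 500 + 120 * cumsum(rnorm(n)) / sqrt(n) * 4 +
                    200 * sin(seq_len(n) / 17)))
  count_series(v)
}

# a binned_time object with prescribed minutes, bypassing bin_time
manual_binned <- function(scheme, minutes) {
  structure(list(scheme = scheme, minutes = minutes,
                 n_epochs_binned = NA_integer_,
                 occupied_bins = sum(minutes > 0)),
            class = "binned_time")
}

default_start <- as.POSIXct("2024-01-01 07:00:00", tz = "UTC")
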