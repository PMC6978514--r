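#' Spike train set
#'
#' Container for a population of sorted single units: one vector of spike
#' times per unit, a shared recording duration, and a group label.
#'
#' @param spike_times list of numeric vectors; spike times in seconds,
#'   each sorted ascending, all in `[0, duration)`.
#' @param duration recording duration in seconds.
#' @param group group label, e.g. `"control"`, `"APP/PS1"` or `"synthetic"`.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spike_times, duration, group = "synthetic") {
  stopifnot(is.list(spike_times), is.numeric(duration), duration > 0)
  spike_times <- lapply(spike_times, function(st) sort(as.numeric(st)))
  bad <- vapply(spike_times, function(st)
    length(st) > 0 && (st[1] < 0 || st[length(st)] >= duration), logical(1))
  if (any(bad))
    stop("spike times must lie in [0, duration)")
  structure(list(spike_times = spike_times,
                 duration = as.numeric(duration),
                 group = group),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$spike_times, length, integer(1))
  cat(sprintf("spike_train_set: %d units, %.1f s, group '%s'\n",
              length(n), x$duration, x$group))
  cat(sprintf("  total spikes %d, mean rate %.3f Hz\n",
              sum(n), mean(n) / x$duration))
  invisible(x)
}

#' Number of units in a spike train set
#' @param s a `spike_train_set`.
#' @return integer count of units.
#' @export
n_units <- function(s) length(s$spike_times)

#' Binary raster
#'
#' Units x bins 0/1 matrix at a fixed bin width. Bin `k` (1-based) covers
#' the half-open interval `[t0 + (k-1) w, t0 + k w)`.
#'
#' @param mat integer/numeric matrix of 0s and 1s, units in rows.
#' @param bin_width bin width in seconds (default 0.010).
#' @param t0 time of the left edge of the first bin, seconds.
#' @return An object of class `binary_raster`.
#' @export
binary_raster <- function(mat, bin_width = 0.010, t0 = 0) {
  mat <- as.matrix(mat)
  if (length(mat) && !all(mat == 0L | mat == 1L))
    stop("raster entries must be 0 or 1")
  storage.mode(mat) <- "integer"
  structure(list(mat = mat, bin_width = as.numeric(bin_width),
                 t0 = as.numeric(t0)),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("binary_raster: %d units x %d bins (%.0f ms bins)\n",
              nrow(x$mat), ncol(x$mat), x$bin_width * 1000))
  if (ncol(x$mat) > 0)
    cat(sprintf("  mean per-bin spike probability %.4f\n", mean(x$mat)))
  invisible(x)
}

#' Epoch set
#'
#' Non-overlapping, sorted `[start, end)` intervals labelled `"running"` or
#' `"stationary"`, whose union covers the recording.
#'
#' @param start,end numeric vectors of epoch boundaries in seconds.
#' @param label character vector of labels.
#' @return An object of class `epoch_set` (a data.frame).
#' @export
epoch_set <- function(start, end, label) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   label = as.character(label))
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df)) {
    if (any(df$end <= df$start)) stop("epochs must have end > start")
    if (nrow(df) > 1 && any(abs(df$start[-1] - df$end[-nrow(df)]) > 1e-9))
      stop("epochs must tile the recording without gaps or overlap")
    if (!all(df$label %in% c("running", "stationary")))
      stop("labels must be 'running' or 'stationary'")
  }
  rownames(df) <- NULL
  class(df) <- c("epoch_set", "data.frame")
  df
}

#' @export
print.epoch_set <- function(x, ...) {
  run <- sum(x$end[x$label == "running"] - x$start[x$label == "running"])
  tot <- if (nrow(x)) max(x$end) - min(x$start) else 0
  cat(sprintf("epoch_set: %d epochs over %.1f s, %.1f%% running\n",
              nrow(x), tot, if (tot > 0) 100 * run / tot else 0))
  invisible(x)
}

#' Velocity trace
#'
#' Signed running velocity sampled on a uniform time grid.
#'
#' @param time sample times in seconds (uniform step).
#' @param velocity velocities in cm/s (signed; forward positive).
#' @return An object of class `velocity_trace`.
#' @export
velocity_trace <- function(time, velocity) {
  stopifnot(length(time) == length(velocity), all(is.finite(velocity)))
  if (length(time) > 2) {
    dt <- diff(time)
    if (max(abs(dt - dt[1])) > 1e-9) stop("time grid must be uniform")
  }
  structure(list(time = as.numeric(time), velocity = as.numeric(velocity)),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("velocity_trace: %d samples, %.1f s, mean |v| %.2f cm/s\n",
              length(x$time),
              if (length(x$time) > 1) diff(range(x$time)) else 0,
              mean(abs(x$velocity))))
  invisible(x)
}

#' Pattern distribution
#'
#' Probability vector over the `2^N` binary patterns of an N-unit ensemble.
#' Pattern index `k` in `0..2^N - 1` encodes the population state with unit 1
#' as the least-significant bit: unit `i` is active in pattern `k` iff bit
#' `i - 1` of `k` is set.
#'
#' @param p numeric probability vector of length `2^N`; must sum to 1.
#' @param n_samples number of bins the distribution was estimated from
#'   (`NA` for exact model distributions).
#' @return An object of class `pattern_distribution`.
#' @export
pattern_distribution <- function(p, n_samples = NA_real_) {
  p <- as.numeric(p)
  N <- round(log2(length(p)))
  if (2^N != length(p)) stop("length(p) must be a power of 2")
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stop("probabilities must sum to 1")
  if (N > 20) stop("ensembles larger than 20 units are not supported")
  structure(list(p = p, N = as.integer(N), n_samples = n_samples),
            class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("pattern_distribution: N = %d (%d patterns), %d with p > 0\n",
              x$N, length(x$p), sum(x$p > 0)))
  invisible(x)
}

#' Raw multi-channel recording
#'
#' @param voltage channels x samples matrix, microvolts.
#' @param sampling_rate samples per second (default 30000).
#' @param channel_positions data.frame with columns `shank` and `depth`
#'   (one row per channel); defaults to a single linear shank at 25 um pitch.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(voltage, sampling_rate = 30000,
                          channel_positions = NULL) {
  voltage <- as.matrix(voltage)
  if (nrow(voltage) < 1) stop("need at least one channel")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(channel_positions))
    channel_positions <- data.frame(shank = 1L,
                                    depth = 25 * seq_len(nrow(voltage)))
  stopifnot(nrow(channel_positions) == nrow(voltage))
  structure(list(voltage = voltage, sampling_rate = sampling_rate,
                 channel_positions = channel_positions),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d channels x %d samples (%.1f s at %g kHz)\n",
              nrow(x$voltage), ncol(x$voltage),
              ncol(x$voltage) / x$sampling_rate, x$sampling_rate / 1000))
  invisible(x)
}

# run a block with a temporary seed when one is given, without disturbing
# the caller's RNG stream otherwise
with_opt_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
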