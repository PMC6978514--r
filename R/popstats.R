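# First- and second-order population statistics: mean rates, z-scored
# instantaneous rates, behaviour-conditioned pairwise correlations, and
# firing-rate-matched shuffle nulls for state-dependent correlation changes.

#' Mean firing rates
#'
#' Total spike count of each unit divided by the recording duration.
#'
#' @param s a [spike_train_set].
#' @return numeric vector of per-unit rates in Hz.
#' @export
mean_firing_rates <- function(s) {
  vapply(s$spike_times, length, numeric(1)) / s$duration
}

#' Z-scored instantaneous firing rate of one unit
#'
#' Sliding-window spike counts (window `window_s`, advanced in steps of
#' `step_s`; windows centred on the step grid, truncated at the recording
#' edges) z-scored over the full recording. A constant series -- e.g. a
#' unit with no spikes -- has an undefined z-score and is returned as
#' all zeros with attribute `"constant" = TRUE`.
#'
#' @param spike_times numeric vector of spike times, seconds.
#' @param duration recording duration, seconds.
#' @param window_s sliding window width, seconds (default 0.1).
#' @param step_s step between windows, seconds (default 0.01;
#'   `window_s` must be an integer multiple).
#' @return numeric z-score series, one value per step.
#' @export
instantaneous_rate_zscore <- function(spike_times, duration,
                                      window_s = 0.1, step_s = 0.01) {
  if (window_s < step_s) stop("window_s must be >= step_s")
  k <- window_s / step_s
  if (abs(k - round(k)) > 1e-9)
    stop("window_s must be an integer multiple of step_s")
  k <- as.integer(round(k))
  n <- ceiling(duration / step_s)
  counts <- tabulate(pmin(floor(spike_times / step_s) + 1L, n), nbins = n)
  if (k %% 2 == 0) k <- k + 1L
  half <- (k - 1L) %/% 2L
  csum <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  x <- (csum[hi + 1L] - csum[lo])
  if (stats::sd(x) == 0) {
    z <- rep(0, n)
    attr(z, "constant") <- TRUE
    return(z)
  }
  z <- (x - mean(x)) / stats::sd(x)
  attr(z, "constant") <- FALSE
  z
}

# z-scored rate series for all units, as a samples x units matrix
rate_series_matrix <- function(s, window_s = 0.1, step_s = 0.01) {
  cols <- lapply(s$spike_times, instantaneous_rate_zscore,
                 duration = s$duration, window_s = window_s, step_s = step_s)
  m <- do.call(cbind, cols)
  attr(m, "step_s") <- step_s
  m
}

#' Pairwise correlations of z-scored rate series
#'
#' Product-moment correlation for every pair of units, optionally restricted
#' to the samples whose time (step centre) falls inside epochs of one
#' behavioural state. Pairs with fewer than 2 included samples, or with a
#' constant series over the included samples, get `NA`.
#'
#' @param series samples x units matrix of z-scored rates (from
#'   [instantaneous_rate_zscore] / internally [rate_series_matrix]), with a
#'   `"step_s"` attribute, or a [spike_train_set] (series are built with
#'   defaults).
#' @param epochs optional [epoch_set]; with `label`, restricts samples.
#' @param label `"running"` or `"stationary"` (used when `epochs` given).
#' @param window_s,step_s series parameters when `series` is a
#'   [spike_train_set].
#' @return correlation matrix (units x units, symmetric, unit diagonal),
#'   with attribute `"condition"`.
#' @export
pairwise_correlations <- function(series, epochs = NULL, label = NULL,
                                  window_s = 0.1, step_s = 0.01) {
  if (inherits(series, "spike_train_set"))
    series <- rate_series_matrix(series, window_s, step_s)
  if (ncol(series) < 2) stop("need at least 2 units")
  step <- attr(series, "step_s")
  if (is.null(step)) step <- step_s
  cond <- "overall"
  if (!is.null(epochs)) {
    if (is.null(label)) stop("label required when epochs are given")
    cond <- label
    tcent <- (seq_len(nrow(series)) - 0.5) * step
    keep <- rep(FALSE, length(tcent))
    for (i in which(epochs$label == label))
      keep <- keep | (tcent >= epochs$start[i] & tcent < epochs$end[i])
    series <- series[keep, , drop = FALSE]
  }
  if (nrow(series) < 2) {
    r <- matrix(NA_real_, ncol(series), ncol(series))
  } else {
    r <- suppressWarnings(stats::cor(series))
    r[!is.finite(r)] <- NA_real_
  }
  diag(r) <- 1
  attr(r, "condition") <- cond
  r
}

#' Firing-rate-matched shuffle of spike trains
#'
#' Replaces each unit's spike times by the same number of points drawn
#' uniformly on `[0, duration)` -- preserving the spike count (and hence the
#' mean firing rate) exactly while destroying all temporal structure.
#'
#' @param s a [spike_train_set].
#' @param seed optional integer seed.
#' @return A shuffled [spike_train_set].
#' @export
rate_matched_shuffle <- function(s, seed = NULL) {
  st <- with_opt_seed(seed, lapply(s$spike_times, function(x)
    sort(stats::runif(length(x), 0, s$duration))))
  spike_train_set(st, s$duration, s$group)
}

#' Correlation change between running and stationary states, with null
#'
#' Computes the per-pair change in correlation (running minus stationary)
#' from behaviour-conditioned correlations of z-scored rate series, and a
#' null distribution from `n_reps` rate-matched shuffles processed
#' identically.
#'
#' @param s a [spike_train_set].
#' @param e an [epoch_set] with both states present.
#' @param n_reps shuffle repetitions (default 1000).
#' @param seed optional integer seed.
#' @param window_s,step_s rate-series parameters.
#' @return list: `delta` (per-pair running - stationary r, lower-triangle
#'   order of `which(lower.tri)`), `null` (n_reps x n_pairs matrix),
#'   `pairs` (2-column index matrix), `seed`.
#' @export
correlation_state_change <- function(s, e, n_reps = 1000, seed = NULL,
                                     window_s = 0.1, step_s = 0.01) {
  if (!all(c("running", "stationary") %in% e$label))
    stop("both behavioural states must be present")
  delta_of <- function(set) {
    m <- rate_series_matrix(set, window_s, step_s)
    r_run <- pairwise_correlations(m, e, "running")
    r_sta <- pairwise_correlations(m, e, "stationary")
    (r_run - r_sta)[lower.tri(r_run)]
  }
  nu <- n_units(s)
  pairs <- which(lower.tri(matrix(0, nu, nu)), arr.ind = TRUE)
  delta <- delta_of(s)
  null <- with_opt_seed(seed, {
    out <- matrix(NA_real_, n_reps, length(delta))
    for (i in seq_len(n_reps)) out[i, ] <- delta_of(rate_matched_shuffle(s))
    out
  })
  list(delta = delta, null = null, pairs = pairs, seed = seed)
}
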