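# Wheel behaviour: quadrature decoding, velocity smoothing, running /
# stationary epoch segmentation and behaviour summaries.

#' Decode a 2-bit quadrature encoder signal into velocity
#'
#' The encoder emits the Gray-code cycle 00 -> 01 -> 11 -> 10 (forward).
#' Each legal transition is one tick (+1 forward, -1 reverse); a two-step
#' jump within one sample is an illegal transition, counted and logged but
#' contributing zero displacement. Tick counts are converted to cm/s and
#' averaged over a centred 150 ms window at 10 ms steps.
#'
#' @param states integer vector of encoder states at `sampling_rate`, each
#'   in `{0b00, 0b01, 0b11, 0b10}` = `{0, 1, 3, 2}`.
#' @param cm_per_tick wheel calibration, cm per encoder tick (> 0).
#' @param sampling_rate encoder sampling rate, Hz (default 30000).
#' @param window velocity averaging window, seconds (default 0.150).
#' @param step velocity time step, seconds (default 0.010).
#' @return A [velocity_trace]; the number of illegal transitions is attached
#'   as attribute `"n_illegal"`.
#' @export
decode_quadrature <- function(states, cm_per_tick, sampling_rate = 30000,
                              window = 0.150, step = 0.010) {
  if (cm_per_tick <= 0) stop("cm_per_tick must be > 0")
  if (!all(states %in% c(0L, 1L, 2L, 3L))) stop("states must be 2-bit")
  # Gray code -> phase 0..3
  phase <- c(`0` = 0L, `1` = 1L, `3` = 2L, `2` = 3L)[as.character(states)]
  d <- diff(phase) %% 4L
  ticks <- integer(length(d))
  ticks[d == 1L] <- 1L
  ticks[d == 3L] <- -1L
  n_illegal <- sum(d == 2L)
  if (n_illegal > 0)
    message(n_illegal, " illegal quadrature transitions (zero displacement)")
  # displacement per step bin, then centred moving average over the window
  n_steps <- floor(length(states) / (step * sampling_rate))
  bin_of <- pmin(floor((seq_along(ticks) - 0.5) / (step * sampling_rate)) + 1L,
                 n_steps)
  disp <- as.numeric(tapply(ticks, factor(bin_of, levels = seq_len(n_steps)),
                            sum, default = 0)) * cm_per_tick
  v_step <- disp / step
  k <- max(1L, round(window / step))
  if (k %% 2 == 0) k <- k + 1L
  half <- (k - 1L) %/% 2L
  csum <- cumsum(c(0, v_step))
  lo <- pmax(seq_len(n_steps) - half, 1L)
  hi <- pmin(seq_len(n_steps) + half, n_steps)
  v <- (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
  vt <- velocity_trace((seq_len(n_steps) - 1) * step, v)
  attr(vt, "n_illegal") <- n_illegal
  vt
}

#' Segment a velocity trace into running and stationary epochs
#'
#' A sample is running when `|velocity| > run_threshold` (absolute value:
#' the wheel can turn in either direction); contiguous same-label samples
#' merge into epochs whose union tiles the trace.
#'
#' @param v a [velocity_trace].
#' @param run_threshold cm/s (default 1.0).
#' @return An [epoch_set].
#' @export
segment_epochs <- function(v, run_threshold = 1.0) {
  n <- length(v$time)
  if (n == 0) stop("empty velocity trace")
  dt <- if (n > 1) v$time[2] - v$time[1] else 0.01
  running <- abs(v$velocity) > run_threshold
  r <- rle(running)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(ends_i, -1) + 1L)
  t0 <- v$time[1]
  epoch_set(start = t0 + (starts_i - 1) * dt,
            end = t0 + ends_i * dt,
            label = ifelse(r$values, "running", "stationary"))
}

#' Summarise running behaviour
#'
#' @param e an [epoch_set].
#' @param v the matching [velocity_trace].
#' @return list: `proportion_running` (total running time / duration),
#'   `mean_run_velocity` (mean |velocity| over running samples; `NA` if the
#'   animal never ran), `mean_inter_run_interval` (mean duration of
#'   stationary epochs between consecutive running epochs; `NA` if < 2 runs),
#'   `n_run_epochs`.
#' @export
behavior_summary <- function(e, v) {
  dur <- max(e$end) - min(e$start)
  run_rows <- which(e$label == "running")
  run_time <- sum(e$end[run_rows] - e$start[run_rows])
  prop <- run_time / dur
  if (!length(run_rows))
    return(list(proportion_running = 0, mean_run_velocity = NA_real_,
                mean_inter_run_interval = NA_real_, n_run_epochs = 0L))
  in_run <- rep(FALSE, length(v$time))
  for (i in run_rows)
    in_run <- in_run | (v$time >= e$start[i] & v$time < e$end[i])
  mean_v <- mean(abs(v$velocity[in_run]))
  # IRIs: stationary epochs strictly between two running epochs
  iri <- NA_real_
  if (length(run_rows) >= 2) {
    between <- which(e$label == "stationary" &
                     seq_len(nrow(e)) > min(run_rows) &
                     seq_len(nrow(e)) < max(run_rows))
    if (length(between))
      iri <- mean(e$end[between] - e$start[between])
  }
  list(proportion_running = prop, mean_run_velocity = mean_v,
       mean_inter_run_interval = iri, n_run_epochs = length(run_rows))
}
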