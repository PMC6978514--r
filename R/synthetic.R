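# Synthetic-data generators with known ground truth: Poisson spike trains,
# exact Ising-model rasters, raw multi-channel traces with embedded
# waveforms and broadband artifacts, state-modulated populations, and
# wheel-running behaviour. Every generator is a pure function of its
# parameters and seed.

#' Generate homogeneous Poisson spike trains
#'
#' @param rates per-unit mean rates in Hz (all >= 0).
#' @param duration recording duration in seconds (> 0).
#' @param seed optional integer seed.
#' @param group group label for the resulting set.
#' @return list: `trains` (a [spike_train_set]) and `ground_truth`
#'   (`spike_times`, `rates`, `seed`).
#' @export
gen_poisson_trains <- function(rates, duration, seed = NULL,
                               group = "synthetic") {
  if (any(rates < 0) || duration <= 0)
    stop("rates must be >= 0 and duration > 0")
  st <- with_opt_seed(seed, lapply(rates, function(r) {
    n <- stats::rpois(1, r * duration)
    sort(stats::runif(n, 0, duration))
  }))
  trains <- spike_train_set(st, duration, group)
  list(trains = trains,
       ground_truth = list(spike_times = st, rates = rates, seed = seed))
}

# categorical sampling of 0-based pattern codes from probabilities p
sample_codes <- function(p, n) {
  if (n == 0) return(integer(0))
  cum <- cumsum(p)
  cum[length(cum)] <- 1
  findInterval(stats::runif(n), cum, left.open = TRUE) # 0-based codes
}

#' Sample a binary raster from a maximum-entropy model's exact distribution
#'
#' Enumerates all `2^N` pattern probabilities and draws `n_bins` i.i.d.
#' bins categorically -- an exact sampler, with no Markov-chain mixing
#' concerns (hence the N <= 20 enumeration bound).
#'
#' @param model a [maxent_model] with `N <= 20`.
#' @param n_bins number of bins (0 gives a valid empty raster).
#' @param seed optional integer seed.
#' @param bin_width bin width in seconds.
#' @return list: `raster` (a [binary_raster]) and `ground_truth`
#'   (`model`, `codes`, `seed`).
#' @export
gen_ising_raster <- function(model, n_bins, seed = NULL, bin_width = 0.010) {
  if (model$N > 20) stop("exact enumeration requires N <= 20")
  p <- model_pattern_probs(model)$p
  codes <- with_opt_seed(seed, sample_codes(p, n_bins))
  mat <- t(state_bits(codes, model$N))
  if (n_bins == 0) mat <- matrix(0L, model$N, 0)
  raster <- binary_raster(mat, bin_width = bin_width)
  list(raster = raster,
       ground_truth = list(model = model, codes = codes, seed = seed))
}

#' Make a spike waveform template
#'
#' Biphasic (negative-then-positive) extracellular spike shape on a peak
#' channel, attenuated on neighbouring channels of the same shank. The
#' waveform window is 1 ms before to 2 ms after the trough.
#'
#' @param unit_id integer unit id.
#' @param peak_channel channel index carrying the full-amplitude waveform.
#' @param n_channels total channel count.
#' @param amplitude_sd peak (trough) amplitude in multiples of the noise SD.
#' @param sampling_rate Hz (default 30000).
#' @param neighbor_decay amplitude attenuation per channel of distance from
#'   the peak channel (default 0.3 = 30% of the next-nearer channel).
#' @return An object of class `waveform_template`: `unit_id`,
#'   `peak_channel`, `waveform` (channels x window samples, in noise-SD
#'   units), `amplitude_sd`, `window` (sample offsets relative to trough).
#' @export
make_waveform_template <- function(unit_id, peak_channel, n_channels,
                                   amplitude_sd = 12, sampling_rate = 30000,
                                   neighbor_decay = 0.3) {
  if (amplitude_sd <= 0) stop("amplitude_sd must be > 0")
  pre <- round(0.001 * sampling_rate); post <- round(0.002 * sampling_rate)
  t <- (-pre):post
  # trough at 0, overshoot peaking ~0.5 ms later at ~40% of trough depth
  shape <- -exp(-(t / (0.00025 * sampling_rate))^2 / 2) +
    0.4 * exp(-((t - 0.0005 * sampling_rate) / (0.0005 * sampling_rate))^2 / 2)
  shape <- shape / max(abs(shape))
  wf <- matrix(0, n_channels, length(t))
  for (ch in seq_len(n_channels)) {
    d <- abs(ch - peak_channel)
    if (d <= 2) wf[ch, ] <- amplitude_sd * neighbor_decay^d * shape
  }
  structure(list(unit_id = unit_id, peak_channel = peak_channel,
                 waveform = wf, amplitude_sd = amplitude_sd, window = t),
            class = "waveform_template")
}

#' Generate a raw multi-channel recording with embedded spikes
#'
#' Band-limited Gaussian noise (generated directly in the 500-3500 Hz
#' acquisition band and rescaled to `noise_sd` per channel), plus waveform
#' templates inserted at homogeneous-Poisson times, plus optional broadband
#' artifacts: high-amplitude (12 noise-SD) 2 ms deflections placed
#' simultaneously on 95% of the channels. Every insertion is recorded in
#' the ground truth.
#'
#' @param templates list of [make_waveform_template] objects (non-empty;
#'   all with the same channel count).
#' @param rates per-template firing rates in Hz.
#' @param duration seconds.
#' @param noise_sd per-channel noise SD in microvolts (> 0).
#' @param artifact_rate artifact events per second (default 0).
#' @param seed optional integer seed.
#' @param sampling_rate Hz (default 30000).
#' @return list: `recording` (a [raw_recording]) and `ground_truth`
#'   (`spike_times` per unit, `artifact_times`, `noise_sd`, `seed`).
#' @export
gen_raw_recording <- function(templates, rates, duration, noise_sd,
                              artifact_rate = 0, seed = NULL,
                              sampling_rate = 30000) {
  if (!length(templates)) stop("templates must be non-empty")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  n_ch <- nrow(templates[[1]]$waveform)
  if (any(vapply(templates, function(tp) nrow(tp$waveform), 0L) != n_ch))
    stop("all templates must share the channel count")
  stopifnot(length(rates) == length(templates))
  n_samp <- round(duration * sampling_rate)
  with_opt_seed(seed, {
    # noise, band-limited to the acquisition band then rescaled per channel
    bf <- signal::butter(2, c(500, 3500) / (sampling_rate / 2), type = "pass")
    v <- matrix(0, n_ch, n_samp)
    for (ch in seq_len(n_ch)) {
      x <- signal::filtfilt(bf, stats::rnorm(n_samp))
      v[ch, ] <- x * (noise_sd / stats::sd(x))
    }
    spike_times <- vector("list", length(templates))
    for (u in seq_along(templates)) {
      tp <- templates[[u]]
      n_spk <- stats::rpois(1, rates[u] * duration)
      st <- sort(stats::runif(n_spk, 0.005, duration - 0.005))
      spike_times[[u]] <- st
      idx0 <- round(st * sampling_rate)
      for (s0 in idx0) {
        cols <- s0 + tp$window + 1L
        ok <- cols >= 1 & cols <= n_samp
        v[, cols[ok]] <- v[, cols[ok]] + noise_sd * tp$waveform[, ok]
      }
    }
    artifact_times <- numeric(0)
    if (artifact_rate > 0) {
      n_art <- stats::rpois(1, artifact_rate * duration)
      artifact_times <- sort(stats::runif(n_art, 0.01, duration - 0.01))
      art_ch <- seq_len(max(1L, ceiling(0.95 * n_ch)))
      span <- 0:round(0.002 * sampling_rate)
      for (a0 in round(artifact_times * sampling_rate)) {
        cols <- a0 + span + 1L
        cols <- cols[cols >= 1 & cols <= n_samp]
        v[art_ch, cols] <- v[art_ch, cols] + 12 * noise_sd
      }
    }
    rec <- raw_recording(v, sampling_rate = sampling_rate)
    list(recording = rec,
         ground_truth = list(spike_times = spike_times,
                             artifact_times = artifact_times,
                             noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a behavioural-state-modulated population raster
#'
#' Bins whose centre lies in a running epoch are drawn from
#' `model_running`, all other bins from `model_stationary` (both exact
#' Ising samplers).
#'
#' @param model_stationary,model_running [maxent_model]s sharing N.
#' @param epochs an [epoch_set] covering the recording.
#' @param bin_width seconds (default 0.010).
#' @param seed optional integer seed.
#' @return list: `raster`, `ground_truth` (`models`, `state_per_bin`,
#'   `seed`).
#' @export
gen_state_modulated_population <- function(model_stationary, model_running,
                                           epochs, bin_width = 0.010,
                                           seed = NULL) {
  if (model_stationary$N != model_running$N)
    stop("models must share the unit count N")
  duration <- max(epochs$end)
  n_bins <- ceiling(duration / bin_width)
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  in_run <- rep(FALSE, n_bins)
  for (i in which(epochs$label == "running"))
    in_run <- in_run | (centers >= epochs$start[i] & centers < epochs$end[i])
  p_sta <- model_pattern_probs(model_stationary)$p
  p_run <- model_pattern_probs(model_running)$p
  codes <- with_opt_seed(seed, {
    out <- integer(n_bins)
    out[!in_run] <- sample_codes(p_sta, sum(!in_run))
    out[in_run] <- sample_codes(p_run, sum(in_run))
    out
  })
  mat <- t(state_bits(codes, model_stationary$N))
  list(raster = binary_raster(mat, bin_width = bin_width),
       ground_truth = list(model_stationary = model_stationary,
                           model_running = model_running,
                           state_per_bin = ifelse(in_run, "running",
                                                  "stationary"),
                           seed = seed))
}

#' Generate wheel-running behaviour
#'
#' Alternating stationary and running bouts with exponential durations
#' (mean bout length `mean_bout` seconds; mean inter-bout gap set so the
#' expected running fraction equals `run_fraction`). The velocity trace is
#' sampled at 10 ms; running samples follow a smooth bout profile around
#' `mean_velocity` (always above the 1 cm/s threshold), stationary samples
#' jitter near 0 (always below it).
#'
#' @param duration seconds.
#' @param run_fraction target proportion of time running, in `[0, 1]`.
#' @param mean_velocity mean running speed, cm/s (default 6).
#' @param seed optional integer seed.
#' @param mean_bout mean running-bout duration, seconds (default 1.15,
#'   which at a 6% running fraction gives a mean inter-run interval of
#'   about 18 s).
#' @param dt velocity time step, seconds (default 0.01).
#' @return list: `velocity` (a [velocity_trace]) and `epochs`
#'   (an [epoch_set]).
#' @export
gen_behavior <- function(duration, run_fraction, mean_velocity = 6,
                         seed = NULL, mean_bout = 1.15, dt = 0.01) {
  if (run_fraction < 0 || run_fraction > 1)
    stop("run_fraction must be in [0, 1]")
  n <- round(duration / dt)
  with_opt_seed(seed, {
    v <- pmax(0, stats::rnorm(n, 0.1, 0.1))      # stationary jitter < 1 cm/s
    v <- pmin(v, 0.8)
    starts <- ends <- numeric(0)
    if (run_fraction > 0) {
      mean_gap <- mean_bout * (1 - run_fraction) / run_fraction
      t <- stats::rexp(1, 1 / mean_gap)
      while (t < duration) {
        bout <- stats::rexp(1, 1 / mean_bout)
        b0 <- t; b1 <- min(t + bout, duration)
        if (b1 - b0 >= 2 * dt) { starts <- c(starts, b0); ends <- c(ends, b1) }
        t <- b1 + stats::rexp(1, 1 / mean_gap)
      }
    }
    time <- (seq_len(n) - 1) * dt
    for (k in seq_along(starts)) {
      i <- which(time >= starts[k] & time < ends[k])
      if (!length(i)) next
      ramp <- sin(pi * seq(0.05, 0.95, length.out = length(i)))
      prof <- 1.5 + (mean_velocity - 1.5) * ramp / mean(ramp) *
        stats::runif(1, 0.8, 1.2)
      v[i] <- pmax(1.2, prof + stats::rnorm(length(i), 0, 0.3))
    }
    vel <- velocity_trace(time, v)
    list(velocity = vel, epochs = segment_epochs(vel, run_threshold = 1.0))
  })
}

# pattern codes -> spike trains (one spike at each active bin's centre)
#' Convert a binary raster to spike trains
#'
#' Places one spike at the centre of every active bin; useful for feeding
#' raster-level generators into spike-train-level analyses.
#'
#' @param r a [binary_raster].
#' @param group group label.
#' @return A [spike_train_set] of duration `ncol(r$mat) * bin_width`.
#' @export
raster_to_spike_trains <- function(r, group = "synthetic") {
  centers <- bin_centers(r) - r$t0
  st <- lapply(seq_len(nrow(r$mat)), function(u) centers[r$mat[u, ] == 1L])
  spike_train_set(st, duration = ncol(r$mat) * r$bin_width, group = group)
}
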