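#' @importFrom mclust Mclust mclustBIC
NULL

# Spike sorting from multi-channel extracellular traces: common (mean)
# referencing, 8-SD amplitude-threshold detection, artifact removal,
# double-crossing consolidation, PCA + Gaussian-mixture clustering,
# waveform curation, duplicate merging and ISI-based quality control.

#' Common mean reference
#'
#' Subtracts the across-channel mean signal from every channel at each
#' sample, suppressing activity common to the whole array.
#'
#' @param raw a [raw_recording] with >= 2 channels.
#' @return A [raw_recording] whose per-sample channel mean is 0.
#' @export
common_reference <- function(raw) {
  if (nrow(raw$voltage) < 2)
    stop("mean referencing needs at least 2 channels")
  v <- raw$voltage
  v <- v - rep(colMeans(v), each = nrow(v))
  raw_recording(v, raw$sampling_rate, raw$channel_positions)
}

# robust per-channel noise SD (median absolute deviation scaled to SD),
# insensitive to the spikes themselves
estimate_noise_sd <- function(raw) {
  apply(raw$voltage, 1, stats::mad)
}

#' Detect threshold-crossing spike events
#'
#' Per channel, tags every contiguous excursion of `|voltage|` beyond
#' `threshold_sd` noise SDs (both polarities; SD estimated robustly via the
#' MAD) as one putative spike, with its peak at the extremal sample.
#'
#' @param raw a [raw_recording].
#' @param threshold_sd threshold in noise-SD multiples (default 8).
#' @return An object of class `spike_event_set`: a data.frame with columns
#'   `channel`, `peak_sample` (1-based), `time` (s), `amplitude` (uV,
#'   signed); the per-channel noise SDs are attached as attribute
#'   `"noise_sd"`.
#' @export
detect_spikes <- function(raw, threshold_sd = 8) {
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  sds <- estimate_noise_sd(raw)
  ev <- vector("list", nrow(raw$voltage))
  for (ch in seq_len(nrow(raw$voltage))) {
    x <- raw$voltage[ch, ]
    above <- abs(x) > threshold_sd * sds[ch]
    if (!any(above)) next
    idx <- which(above)
    run_id <- cumsum(c(1L, diff(idx) > 1L))
    peaks <- vapply(split(idx, run_id), function(i) i[which.max(abs(x[i]))],
                    integer(1))
    ev[[ch]] <- data.frame(channel = ch, peak_sample = as.integer(peaks),
                           amplitude = x[peaks])
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev))
    ev <- data.frame(channel = integer(0), peak_sample = integer(0),
                     amplitude = numeric(0))
  ev$time <- (ev$peak_sample - 1) / raw$sampling_rate
  ev <- ev[order(ev$channel, ev$peak_sample), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "noise_sd") <- sds
  class(ev) <- c("spike_event_set", "data.frame")
  ev
}

#' Remove events that co-occur with array-wide artifacts
#'
#' Finds the samples at which at least `channel_fraction` of all channels
#' are simultaneously beyond the detection threshold and removes every
#' event whose peak lies within `window` seconds of such a sample.
#'
#' @param events a `spike_event_set`.
#' @param raw the [raw_recording] the events came from.
#' @param channel_fraction fraction of channels that must be simultaneously
#'   supra-threshold (default 0.9); the event is removed when the observed
#'   fraction is >= this value.
#' @param window guard interval around artifact samples, seconds
#'   (default 0.002).
#' @param threshold_sd detection threshold (default 8).
#' @return The filtered `spike_event_set`.
#' @export
remove_artifacts <- function(events, raw, channel_fraction = 0.9,
                             window = 0.002, threshold_sd = 8) {
  if (channel_fraction <= 0 || channel_fraction > 1)
    stop("channel_fraction must be in (0, 1]")
  n_ch <- nrow(raw$voltage)
  sds <- attr(events, "noise_sd")
  if (is.null(sds)) sds <- estimate_noise_sd(raw)
  cnt <- integer(ncol(raw$voltage))
  for (ch in seq_len(n_ch))
    cnt <- cnt + (abs(raw$voltage[ch, ]) > threshold_sd * sds[ch])
  bad <- which(cnt >= channel_fraction * n_ch)
  if (!length(bad)) return(events)
  w <- round(window * raw$sampling_rate)
  # nearest artifact sample to each event peak
  near <- findInterval(events$peak_sample, bad)
  d_lo <- ifelse(near >= 1, events$peak_sample - bad[pmax(near, 1)], Inf)
  d_hi <- ifelse(near < length(bad),
                 bad[pmin(near + 1L, length(bad))] - events$peak_sample, Inf)
  keep <- pmin(d_lo, d_hi) > w
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "noise_sd") <- sds
  class(out) <- class(events)
  out
}

#' Consolidate double-counted threshold crossings
#'
#' A biphasic waveform can cross the threshold at both polarities and be
#' detected twice. Events on the same channel within `merge_window` seconds
#' of the previous retained event collapse into one, keeping the
#' largest-|amplitude| peak.
#'
#' @param events a `spike_event_set` (time-sorted per channel).
#' @param merge_window seconds (default 0.001).
#' @param raw optional [raw_recording] (for the sampling rate; otherwise
#'   taken from the event times directly).
#' @return The consolidated `spike_event_set`.
#' @export
consolidate_double_crossings <- function(events, merge_window = 0.001,
                                         raw = NULL) {
  if (!nrow(events)) return(events)
  keep <- logical(nrow(events))
  for (ch in unique(events$channel)) {
    i <- which(events$channel == ch)
    t <- events$time[i]; a <- abs(events$amplitude[i])
    grp <- cumsum(c(1, diff(t) > merge_window))
    best <- vapply(split(seq_along(i), grp),
                   function(j) j[which.max(a[j])], integer(1))
    keep[i[best]] <- TRUE
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "noise_sd") <- attr(events, "noise_sd")
  class(out) <- class(events)
  out
}

# neighbor_channels nearest channels (including the channel itself) by
# array geometry; across-shank distance is penalized
channel_neighborhood <- function(raw, ch, neighbor_channels = 8) {
  pos <- raw$channel_positions
  d <- sqrt((pos$depth - pos$depth[ch])^2 +
            (200 * (pos$shank - pos$shank[ch]))^2)
  order(d)[seq_len(min(neighbor_channels + 1L, nrow(pos)))]
}

# waveform snippets (1 ms pre / 2 ms post the peak) concatenated across a
# channel neighbourhood; events too close to the recording edge are dropped
extract_snippets <- function(raw, events, channels, pre = 0.001, post = 0.002) {
  npre <- round(pre * raw$sampling_rate)
  npost <- round(post * raw$sampling_rate)
  ok <- events$peak_sample > npre &
    events$peak_sample <= ncol(raw$voltage) - npost
  idx <- which(ok)
  out <- matrix(NA_real_, length(idx), length(channels) * (npre + npost + 1))
  for (r in seq_along(idx)) {
    cols <- (events$peak_sample[idx[r]] - npre):(events$peak_sample[idx[r]] + npost)
    out[r, ] <- as.numeric(t(raw$voltage[channels, cols, drop = FALSE]))
  }
  list(snippets = out, kept = idx)
}

#' Cluster spike events into putative units
#'
#' Per detecting channel: waveform snippets are concatenated across the
#' channel and its `neighbor_channels` nearest channels, projected onto the
#' smallest principal subspace explaining more than `variance_explained` of
#' the waveform variance, and partitioned by a Gaussian-mixture model whose
#' component count is selected by BIC over `1..max_components`; each event
#' gets the label of its maximum-posterior component. Labels are unique
#' across channels.
#'
#' @param raw a [raw_recording].
#' @param events a `spike_event_set` (>= 2 events overall).
#' @param variance_explained PCA variance target (default 0.8).
#' @param neighbor_channels neighbouring channels to concatenate
#'   (default 8).
#' @param max_components mixture components considered (default 10; reduced
#'   with a warning when a channel has fewer events).
#' @return integer vector of unit labels, one per event (`NA` for events
#'   too close to the recording edge to extract a full snippet).
#' @export
cluster_spikes <- function(raw, events, variance_explained = 0.8,
                           neighbor_channels = 8, max_components = 10) {
  if (nrow(events) < 2) stop("need at least 2 events to cluster")
  labels <- rep(NA_integer_, nrow(events))
  offset <- 0L
  for (ch in sort(unique(events$channel))) {
    i <- which(events$channel == ch)
    nb <- channel_neighborhood(raw, ch, neighbor_channels)
    sn <- extract_snippets(raw, events[i, , drop = FALSE], nb)
    if (!nrow(sn$snippets)) next
    if (nrow(sn$snippets) == 1) {
      labels[i[sn$kept]] <- offset + 1L
      offset <- offset + 1L
      next
    }
    pc <- stats::prcomp(sn$snippets, center = TRUE, scale. = FALSE)
    varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ndim <- which(varfrac > variance_explained)[1]
    proj <- pc$x[, seq_len(ndim), drop = FALSE]
    kmax <- min(max_components, nrow(proj) - 1L)
    if (kmax < max_components)
      warning(sprintf("channel %d: only %d events; trying k = 1..%d",
                      ch, nrow(proj), kmax))
    fit <- mclust::Mclust(proj, G = seq_len(max(kmax, 1L)), verbose = FALSE)
    cl <- if (is.null(fit)) rep(1L, nrow(proj)) else fit$classification
    labels[i[sn$kept]] <- offset + as.integer(cl)
    offset <- offset + max(cl)
  }
  labels
}

# assemble sorted units from labelled events
events_to_units <- function(raw, events, labels, neighbor_channels = 8) {
  sds <- attr(events, "noise_sd")
  if (is.null(sds)) sds <- estimate_noise_sd(raw)
  units <- list()
  for (lab in sort(unique(labels[!is.na(labels)]))) {
    i <- which(!is.na(labels) & labels == lab)
    ch <- as.integer(names(which.max(table(events$channel[i]))))
    nb <- channel_neighborhood(raw, ch, neighbor_channels)
    sn <- extract_snippets(raw, events[i, , drop = FALSE], nb)
    mw <- if (nrow(sn$snippets)) {
      matrix(colMeans(sn$snippets), nrow = length(nb), byrow = TRUE)
    } else matrix(0, length(nb), 1)
    st <- sort(events$time[i])
    units[[length(units) + 1L]] <- list(
      unit_id = lab, spike_times = st, n_spikes = length(st),
      peak_channel = ch, mean_waveform = mw, waveform_channels = nb,
      peak_amplitude_sd = max(abs(mw[1, ])) / sds[ch],
      isi_violation_fraction = isi_violation_fraction(st))
  }
  units
}

isi_violation_fraction <- function(spike_times, isi_cutoff = 0.003) {
  if (length(spike_times) < 2) return(0)
  mean(diff(spike_times) < isi_cutoff)
}

#' Automated waveform curation
#'
#' Deterministic surrogate for manual waveform review: rejects units whose
#' mean waveform peak on the detecting channel is below `min_peak_sd` noise
#' SDs, or whose waveform is symmetric (positive and negative peaks within
#' 10% of each other -- characteristic of noise, not of extracellular
#' action potentials).
#'
#' @param units list of sorted units (from the sorting pipeline).
#' @param min_peak_sd minimum mean-waveform peak, in noise SDs (default 8).
#' @param symmetry_tol relative peak-magnitude difference below which a
#'   waveform counts as symmetric (default 0.1).
#' @return the retained units; rejected ids in attribute `"rejected"`.
#' @export
curate_units <- function(units, min_peak_sd = 8, symmetry_tol = 0.1) {
  ok <- vapply(units, function(u) {
    w <- u$mean_waveform[1, ]                 # detecting channel
    pk_pos <- max(w); pk_neg <- -min(w)
    peak <- max(pk_pos, pk_neg)
    if (u$peak_amplitude_sd < min_peak_sd) return(FALSE)
    sym <- min(pk_pos, pk_neg) / peak > 1 - symmetry_tol
    !sym
  }, logical(1))
  out <- units[ok]
  attr(out, "rejected") <-
    vapply(units[!ok], function(u) u$unit_id, numeric(1))
  out
}

#' Merge duplicate units detected on different channels
#'
#' When at least `coincidence_fraction` of the smaller unit's spikes fall
#' within `coincidence_window` seconds of the other unit's spikes, the two
#' are tagged as the same neuron and the smaller-count unit is dropped.
#'
#' @param units list of sorted units.
#' @param coincidence_window seconds (default 0.0005).
#' @param coincidence_fraction proportion (default 0.5).
#' @return the de-duplicated unit list.
#' @export
merge_duplicates <- function(units, coincidence_window = 0.0005,
                             coincidence_fraction = 0.5) {
  if (length(units) < 2) return(units)
  ord <- order(-vapply(units, function(u) u$n_spikes, numeric(1)))
  kept <- list()
  for (k in ord) {
    u <- units[[k]]
    dup <- FALSE
    for (v in kept) {
      near <- vapply(u$spike_times, function(t)
        min(abs(v$spike_times - t)), numeric(1))
      if (mean(near <= coincidence_window) >= coincidence_fraction) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- u
  }
  kept[order(vapply(kept, function(u) u$unit_id, numeric(1)))]
}

#' Quality-control filter on sorted units
#'
#' Retains units with at least `min_spikes` spikes and at most
#' `max_isi_violation` of their inter-spike intervals below `isi_cutoff`.
#'
#' @param units list of sorted units.
#' @param duration recording duration, seconds.
#' @param min_spikes minimum spike count (default 50).
#' @param max_isi_violation maximum ISI-violation fraction (default 0.10).
#' @param isi_cutoff refractory cutoff, seconds (default 0.003).
#' @param group group label for the resulting set.
#' @return A [spike_train_set] of the retained units; a per-unit QC report
#'   data.frame is attached as attribute `"qc"`.
#' @export
qc_units <- function(units, duration, min_spikes = 50,
                     max_isi_violation = 0.10, isi_cutoff = 0.003,
                     group = "synthetic") {
  rep_df <- data.frame(
    unit_id = vapply(units, function(u) as.numeric(u$unit_id), numeric(1)),
    n_spikes = vapply(units, function(u) u$n_spikes, numeric(1)),
    isi_violation_fraction = vapply(units, function(u)
      isi_violation_fraction(u$spike_times, isi_cutoff), numeric(1)))
  rep_df$retained <- rep_df$n_spikes >= min_spikes &
    rep_df$isi_violation_fraction <= max_isi_violation
  kept <- units[rep_df$retained]
  out <- spike_train_set(lapply(kept, function(u) u$spike_times),
                         duration, group)
  attr(out, "qc") <- rep_df
  attr(out, "units") <- kept
  out
}

#' Spike-count autocorrelogram
#'
#' Symmetric histogram of spike-time differences in bins of `bin` seconds
#' out to `max_lag`; the zero-lag bin excludes self-pairs.
#'
#' @param spike_times numeric vector (>= 2 spikes for a non-empty result).
#' @param max_lag seconds (default 0.05).
#' @param bin seconds (default 0.001).
#' @return data.frame with columns `lag` (bin centre, s) and `count`.
#' @export
autocorrelogram <- function(spike_times, max_lag = 0.05, bin = 0.001) {
  edges <- seq(-max_lag - bin / 2, max_lag + bin / 2, by = bin)
  centers <- (utils::head(edges, -1) + edges[-1]) / 2
  if (length(spike_times) < 2)
    return(data.frame(lag = centers, count = 0L))
  st <- sort(spike_times)
  diffs <- numeric(0)
  for (k in seq_len(length(st) - 1)) {      # forward lags only, then mirror
    d <- st[-seq_len(k)] - utils::head(st, -k)
    d <- d[d <= max_lag + bin / 2]
    if (!length(d)) break
    diffs <- c(diffs, d)
  }
  cnt <- graphics::hist(c(diffs, -diffs), breaks = edges, plot = FALSE)$counts
  data.frame(lag = centers, count = cnt)
}

#' End-to-end spike sorting
#'
#' Runs the full chain: common mean reference, threshold detection,
#' artifact removal, double-crossing consolidation, PCA + Gaussian-mixture
#' clustering, waveform curation, duplicate merging and ISI/count QC.
#'
#' @param raw a [raw_recording].
#' @param threshold_sd detection threshold in noise SDs (default 8).
#' @param variance_explained PCA variance target (default 0.8).
#' @param neighbor_channels channels concatenated per waveform (default 8).
#' @param channel_fraction artifact channel fraction (default 0.9).
#' @param min_spikes,max_isi_violation,isi_cutoff QC parameters.
#' @param group group label.
#' @return A [spike_train_set] (with `"qc"` and `"units"` attributes, as in
#'   [qc_units]).
#' @export
sort_spikes <- function(raw, threshold_sd = 8, variance_explained = 0.8,
                        neighbor_channels = 8, channel_fraction = 0.9,
                        min_spikes = 50, max_isi_violation = 0.10,
                        isi_cutoff = 0.003, group = "synthetic") {
  ref <- common_reference(raw)
  ev <- detect_spikes(ref, threshold_sd)
  ev <- remove_artifacts(ev, ref, channel_fraction,
                         threshold_sd = threshold_sd)
  ev <- consolidate_double_crossings(ev)
  labels <- cluster_spikes(ref, ev, variance_explained, neighbor_channels)
  units <- events_to_units(ref, ev, labels, neighbor_channels)
  units <- curate_units(units, min_peak_sd = threshold_sd)
  units <- merge_duplicates(units)
  qc_units(units, duration = ncol(raw$voltage) / raw$sampling_rate,
           min_spikes = min_spikes, max_isi_violation = max_isi_violation,
           isi_cutoff = isi_cutoff, group = group)
}
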