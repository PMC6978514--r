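# Detection, artifact handling, consolidation, clustering, curation and QC.

make_events <- function(channel, time, amplitude, sampling_rate = 30000) {
  ev <- data.frame(channel = channel,
                   peak_sample = as.integer(round(time * sampling_rate)) + 1L,
                   amplitude = amplitude, time = time)
  ev <- ev[order(ev$channel, ev$peak_sample), ]
  rownames(ev) <- NULL
  class(ev) <- c("spike_event_set", "data.frame")
  ev
}

test_that("common referencing zeroes the across-channel mean", {
  x <- sin(seq(0, 10, length.out = 3000))
  same <- raw_recording(rbind(x, x))
  out <- common_reference(same)
  expect_true(all(abs(out$voltage) < 1e-12))

  opp <- raw_recording(rbind(x, -x))
  expect_equal(common_reference(opp)$voltage, opp$voltage, tolerance = 1e-12)

  withr::with_seed(1, v <- matrix(rnorm(8 * 1000), 8))
  ref <- common_reference(raw_recording(v))
  expect_lt(max(abs(colMeans(ref$voltage))), 1e-12)
  expect_error(common_reference(raw_recording(v[1, , drop = FALSE])),
               "channels")
})

test_that("common referencing cancels common-mode artifacts but keeps spikes", {
  n_ch <- 16
  withr::with_seed(2, noise <- matrix(rnorm(n_ch * 30000), n_ch))
  v <- noise
  v[, 1000:1030] <- v[, 1000:1030] + 50          # common-mode on all channels
  spike <- 12 * c(-1, -2, -1)
  v[3, 5000:5002] <- v[3, 5000:5002] + spike     # single-channel spike
  ref <- common_reference(raw_recording(v))
  # artifact cancels: referenced interval equals the referenced pure noise
  ref_noise <- common_reference(raw_recording(noise))
  expect_equal(ref$voltage[, 1000:1030], ref_noise$voltage[, 1000:1030],
               tolerance = 1e-10)
  # single-channel template shrinks by exactly (1 - 1/n_channels)
  expect_equal(ref$voltage[3, 5001] - ref_noise$voltage[3, 5001],
               spike[2] * (1 - 1 / n_ch), tolerance = 1e-10)
})

test_that("threshold detection finds injected spikes and rejects subthreshold ones", {
  withr::with_seed(3, v <- matrix(rnorm(2 * 300000), 2))  # 10 s, 2 channels
  tp_shape <- c(-0.3, -1, -0.4, 0.3, 0.15)
  inject_at <- seq(0.5, 9.5, by = 0.5) * 30000
  for (s0 in inject_at) v[1, s0 + seq_along(tp_shape)] <-
    v[1, s0 + seq_along(tp_shape)] + 12 * tp_shape
  small_at <- seq(0.25, 9.25, by = 0.5) * 30000
  for (s0 in small_at) v[2, s0 + seq_along(tp_shape)] <-
    v[2, s0 + seq_along(tp_shape)] + 5 * tp_shape
  ev <- detect_spikes(raw_recording(rbind(v)))
  ev1 <- ev[ev$channel == 1, ]
  hits <- sapply(inject_at / 30000, function(t) any(abs(ev1$time - t) < 5e-4))
  expect_gte(mean(hits), 0.99)
  expect_equal(nrow(ev[ev$channel == 2, ]), 0)   # 5 SD stays subthreshold
})

test_that("pure Gaussian noise yields essentially no events at 8 SD", {
  withr::with_seed(4, v <- matrix(rnorm(2 * 60 * 30000), 2))
  ev <- detect_spikes(raw_recording(v))
  # analytic false-event rate beyond 8 SD is ~1e-15 per sample
  expect_equal(nrow(ev), 0)
})

test_that("artifact removal drops co-occurring events with boundary semantics", {
  withr::with_seed(5, v <- matrix(rnorm(20 * 60000), 20))
  art <- 2000:2060
  v[1:19, art] <- v[1:19, art] + 12                # 95% of channels
  v[7, 30000 + 0:2] <- v[7, 30000 + 0:2] + c(-5, -12, -5)  # true spike
  raw <- raw_recording(v)
  ev <- detect_spikes(raw)
  expect_true(any(abs(ev$time - 1) < 0.002))       # artifact detected
  kept <- remove_artifacts(ev, raw, channel_fraction = 0.9)
  expect_false(any(abs(kept$time - (2000 / 30000)) < 0.002))
  expect_true(any(abs(kept$time - 1) < 1e-3))      # spike retained
  # channel_fraction = 1: the 95% artifact no longer qualifies
  kept_all <- remove_artifacts(ev, raw, channel_fraction = 1)
  expect_true(any(abs(kept_all$time - (2000 / 30000)) < 0.003))
  # with no artifacts present the event set is unchanged
  ev2 <- make_events(1, c(0.1, 0.2), c(-9, -10))
  attr(ev2, "noise_sd") <- apply(v, 1, mad)
  expect_equal(nrow(remove_artifacts(ev2, raw_recording(v * 0 +
    matrix(rnorm(length(v)), nrow(v)), 30000), 0.9)), 2)
})

test_that("double-crossing consolidation keeps the largest peak per window", {
  # +/- crossings 0.3 ms apart collapse to one event
  ev <- make_events(c(1, 1), c(0.0100, 0.0103), c(9, -12))
  out <- consolidate_double_crossings(ev)
  expect_equal(nrow(out), 1)
  expect_equal(out$amplitude, -12)
  # two true spikes 5 ms apart stay separate
  ev2 <- make_events(c(1, 1), c(0.010, 0.015), c(-12, -11))
  expect_equal(nrow(consolidate_double_crossings(ev2)), 2)
  # three crossings inside 1 ms merge to the extremal peak (brute force:
  # any pairwise gap <= 1 ms chains into one group)
  ev3 <- make_events(rep(1, 3), c(0.0100, 0.0104, 0.0108), c(8.5, -13, 9))
  out3 <- consolidate_double_crossings(ev3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$amplitude, -13)
  # different channels are never merged
  ev4 <- make_events(c(1, 2), c(0.010, 0.0101), c(-12, -12))
  expect_equal(nrow(consolidate_double_crossings(ev4)), 2)
})

test_that("clustering separates distinct templates and picks one for one", {
  tps <- lapply(1:2, function(u)
    make_waveform_template(u, c(3, 10)[u], 12, amplitude_sd = 14))
  g <- gen_raw_recording(tps, rates = c(3, 3), duration = 40, noise_sd = 10,
                         seed = 6)
  ref <- common_reference(g$recording)
  ev <- consolidate_double_crossings(detect_spikes(ref))
  labels <- cluster_spikes(ref, ev)
  truth <- match_spikes_to_truth(ev$time, g$ground_truth$spike_times)
  ok <- !is.na(labels) & !is.na(truth)
  expect_gte(mclust::adjustedRandIndex(labels[ok], truth[ok]), 0.95)

  # single template: model selection chooses one cluster
  g1 <- gen_raw_recording(tps[1], rates = 3, duration = 40, noise_sd = 10,
                          seed = 7)
  ref1 <- common_reference(g1$recording)
  ev1 <- consolidate_double_crossings(detect_spikes(ref1))
  ev1 <- ev1[ev1$channel == 3, ]
  class(ev1) <- c("spike_event_set", "data.frame")
  lab1 <- cluster_spikes(ref1, ev1)
  expect_equal(length(unique(stats::na.omit(lab1))), 1)
})

test_that("QC retains and discards units by count and ISI-violation rules", {
  mk <- function(st) list(unit_id = 1, spike_times = st, n_spikes = length(st),
                          peak_channel = 1,
                          mean_waveform = matrix(c(-10, 4), 1),
                          peak_amplitude_sd = 10,
                          isi_violation_fraction = 0)
  u49 <- mk(sort(runif(49, 0, 100)))
  out <- qc_units(list(u49), duration = 100)
  expect_equal(n_units(out), 0)
  expect_false(attr(out, "qc")$retained[1])

  # 12% of ISIs below 3 ms: discarded
  withr::with_seed(8, {
    base <- cumsum(rexp(200, 2))
    viol <- sort(c(base, base[1:27] + 0.001))   # 27/226 ~ 12% short ISIs
  })
  u_viol <- mk(viol[viol < max(viol) + 1])
  out2 <- qc_units(list(u_viol), duration = max(viol) + 1)
  expect_equal(n_units(out2), 0)

  # a 2 Hz Poisson unit over 600 s passes both rules
  st <- gen_poisson_trains(2, 600, seed = 9)$trains$spike_times[[1]]
  out3 <- qc_units(list(mk(st)), duration = 600)
  expect_equal(n_units(out3), 1)
  # expected violation fraction ~ 1 - exp(-2 * 0.003) ~ 0.6%
  expect_lt(attr(out3, "qc")$isi_violation_fraction[1], 0.03)

  # idempotence: QC of the QC output changes nothing
  again <- qc_units(attr(out3, "units"), duration = 600)
  expect_identical(again$spike_times, out3$spike_times)
})

test_that("duplicate merging drops coincident units but keeps independent ones", {
  mk <- function(id, st) list(unit_id = id, spike_times = st,
                              n_spikes = length(st), peak_channel = 1,
                              mean_waveform = matrix(c(-10, 4), 1),
                              peak_amplitude_sd = 10,
                              isi_violation_fraction = 0)
  st <- sort(runif(100, 0, 600))
  expect_length(merge_duplicates(list(mk(1, st), mk(2, st))), 1)
  # subset unit is absorbed by its superset
  expect_length(merge_duplicates(list(mk(1, st[1:40]), mk(2, st))), 1)
  # two independent 1 Hz Poisson units: expected coincidence ~0.1%
  a <- gen_poisson_trains(1, 600, seed = 10)$trains$spike_times[[1]]
  b <- gen_poisson_trains(1, 600, seed = 11)$trains$spike_times[[1]]
  expect_length(merge_duplicates(list(mk(1, a), mk(2, b))), 2)
})

test_that("waveform curation rejects low-amplitude and symmetric clusters", {
  mk <- function(id, wf, amp) list(unit_id = id, spike_times = 1:60 / 10,
                                   n_spikes = 60, peak_channel = 1,
                                   mean_waveform = matrix(wf, 1),
                                   peak_amplitude_sd = amp,
                                   isi_violation_fraction = 0)
  good <- mk(1, c(-12, 5), 12)
  weak <- mk(2, c(-5, 2), 5)
  sym <- mk(3, c(-12, 11.5), 12)
  kept <- curate_units(list(good, weak, sym))
  expect_equal(vapply(kept, function(u) u$unit_id, numeric(1)), 1)
  expect_setequal(attr(kept, "rejected"), c(2, 3))
})

test_that("autocorrelograms reflect periodicity, refractoriness and flatness", {
  per <- autocorrelogram(seq(0, 10, by = 0.1), max_lag = 0.25)
  peaks <- per$lag[per$count > 0]
  expect_true(all(abs(peaks %% 0.1) < 1e-9 | abs(peaks %% 0.1 - 0.1) < 1e-9))
  expect_equal(per$count[per$lag == 0], 0)      # no self-pairs

  # refractory unit: empty bins within +/-3 ms of zero
  st <- cumsum(0.004 + rexp(500, 10))
  ac <- autocorrelogram(st)
  expect_true(all(ac$count[abs(ac$lag) < 0.003] == 0))

  # Poisson unit: each bin within 3 SE of rate^2 * duration * bin
  st2 <- gen_poisson_trains(5, 600, seed = 12)$trains$spike_times[[1]]
  acp <- autocorrelogram(st2, max_lag = 0.05, bin = 0.005)
  expected <- 5^2 * 600 * 0.005
  off_zero <- acp$count[abs(acp$lag) > 1e-9]
  expect_true(all(abs(off_zero - expected) < 3 * sqrt(expected)))
  expect_equal(nrow(autocorrelogram(numeric(0))) > 0, TRUE)
})
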