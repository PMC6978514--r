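# Fixture builders used across the suite. Everything is generated in code
# under fixed seeds; no data files.

# random pairwise model with biases in [-3, -1] and couplings in [-.5, .5]
random_model <- function(N = 5, seed = 1) {
  withr::with_seed(seed, {
    h <- stats::runif(N, -3, -1)
    J <- matrix(0, N, N)
    J[upper.tri(J)] <- stats::runif(N * (N - 1) / 2, -0.5, 0.5)
    maxent_model(h, J + t(J))
  })
}

# random full-support pattern distribution over N units
random_distribution <- function(N = 5, seed = 1, concentration = 1) {
  withr::with_seed(seed, {
    w <- stats::rgamma(2^N, concentration)
    pattern_distribution(w / sum(w))
  })
}

# raster of independent Bernoulli(q) units
bernoulli_raster <- function(n_units, n_bins, q, seed = 1) {
  withr::with_seed(seed,
    binary_raster(matrix(stats::rbinom(n_units * n_bins, 1, q),
                         n_units, n_bins)))
}

# binary entropy in bits
h_binary <- function(q) {
  ifelse(q %in% c(0, 1), 0, -q * log2(q) - (1 - q) * log2(1 - q))
}

# feature covariance (Fisher information per sample) of a model, by direct
# enumeration -- independent of the fitting code path
fisher_cov <- function(m) {
  d <- model_pattern_probs(m)
  N <- m$N
  S <- t(sapply(0:(2^N - 1), function(k) (k %/% 2^(0:(N - 1))) %% 2))
  ut <- which(upper.tri(diag(N)), arr.ind = TRUE)
  F <- cbind(S, S[, ut[, 1], drop = FALSE] * S[, ut[, 2], drop = FALSE])
  mu <- colSums(F * d$p)
  crossprod(F * d$p, F) - tcrossprod(mu)
}

# templates for a 3-unit, n_ch-channel synthetic recording
three_unit_templates <- function(n_ch = 16, amplitude_sd = 12) {
  peaks <- round(seq(2, n_ch - 1, length.out = 3))
  lapply(1:3, function(u)
    make_waveform_template(u, peaks[u], n_ch, amplitude_sd))
}

# match each sorted spike to a ground-truth insertion within a tolerance;
# returns per-spike ground-truth unit (NA when unmatched = false positive)
match_spikes_to_truth <- function(spike_times, gt_times_list, tol = 5e-4) {
  all_gt <- unlist(gt_times_list)
  gt_unit <- rep(seq_along(gt_times_list),
                 vapply(gt_times_list, length, integer(1)))
  ord <- order(all_gt)
  all_gt <- all_gt[ord]; gt_unit <- gt_unit[ord]
  vapply(spike_times, function(t) {
    i <- findInterval(t, all_gt)
    cand <- c(i, i + 1L)
    cand <- cand[cand >= 1 & cand <= length(all_gt)]
    if (!length(cand)) return(NA_integer_)
    j <- cand[which.min(abs(all_gt[cand] - t))]
    if (abs(all_gt[j] - t) <= tol) gt_unit[j] else NA_integer_
  }, integer(1))
}
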