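# Binarization, pattern distributions, entropy estimation, conditioning,
# bootstrap and firing-rate matching.

test_that("binarization follows the at-least-once rule on half-open bins", {
  s <- spike_train_set(list(c(0.003, 0.007), 0.010, numeric(0)), 0.05)
  r <- binarize(s, 0.010)
  expect_equal(ncol(r$mat), 5)
  expect_equal(r$mat[1, ], c(1L, 0L, 0L, 0L, 0L))  # two spikes, single 1
  expect_equal(r$mat[2, ], c(0L, 1L, 0L, 0L, 0L))  # 10 ms goes to bin 2
  expect_equal(r$mat[3, ], rep(0L, 5))             # empty train
})

test_that("epoch restriction keeps bins by centre and is additive", {
  r <- bernoulli_raster(3, 500, 0.1, seed = 1)   # 5 s at 10 ms
  e_all <- epoch_set(0, 5, "running")
  expect_identical(restrict_to_epochs(r, e_all, "running")$mat, r$mat)

  e <- epoch_set(c(0, 1, 2), c(1, 2, 5), c("stationary", "running", "stationary"))
  expect_equal(ncol(restrict_to_epochs(r, e, "running")$mat), 100)

  e2 <- epoch_set(c(0, 1, 2, 3), c(1, 2, 3, 5),
                  c("running", "stationary", "running", "stationary"))
  expect_equal(ncol(restrict_to_epochs(r, e2, "running")$mat), 200)
  expect_error(restrict_to_epochs(r, e_all, "stationary"), "label")
})

test_that("pattern distribution counts patterns with LSB-first encoding", {
  # bins: 00, 00, (unit1 only), (both)
  mat <- rbind(c(0, 0, 1, 1), c(0, 0, 0, 1))
  d <- pattern_distribution_of(binary_raster(mat))
  expect_equal(d$p, c(0.5, 0.25, 0, 0.25))
  # all-silent raster: delta on pattern 0
  d0 <- pattern_distribution_of(binary_raster(matrix(0L, 2, 10)))
  expect_equal(d0$p, c(1, 0, 0, 0))
})

test_that("empirical pattern frequencies converge to the exact model distribution", {
  m <- random_model(N = 4, seed = 5)
  exact <- model_pattern_probs(m)
  n <- 5e4
  emp <- pattern_distribution_of(gen_ising_raster(m, n, seed = 6)$raster)
  se <- sqrt(exact$p * (1 - exact$p) / n)
  expect_true(all(abs(emp$p - exact$p) < 3 * se + 3 / n))
})

test_that("plug-in entropy matches closed forms and stays in [0, N]", {
  expect_equal(shannon_entropy(pattern_distribution(rep(1 / 1024, 1024))), 10)
  expect_equal(shannon_entropy(pattern_distribution(c(1, rep(0, 1023)))), 0)
  expect_equal(shannon_entropy(pattern_distribution(c(0.5, 0.25, 0.25, 0))), 1.5)
  for (seed in 1:10) {
    d <- random_distribution(N = 5, seed = seed, concentration = 0.2)
    h <- shannon_entropy(d)
    expect_gte(h, 0); expect_lte(h, 5)
  }
})

test_that("subsample entropy is deterministic and degenerate at exact population size", {
  r <- bernoulli_raster(10, 2000, 0.05, seed = 7)
  e1 <- subsample_entropy(r, 10, 50, seed = 9)
  e2 <- subsample_entropy(r, 10, 50, seed = 9)
  expect_identical(e1$entropies, e2$entropies)
  expect_equal(sd(e1$entropies), 0)          # only one possible unit set
  expect_error(subsample_entropy(r, 11, 10), "units")
})

test_that("plug-in entropy shows the predicted finite-sample bias", {
  # independent Bernoulli units: mean plug-in entropy over replicate
  # rasters sits at the analytic entropy minus (K-1)/(2 ln2 n), within a
  # factor-of-2 band around that bias
  q <- 0.05; n <- 5e3
  h_hat <- sapply(1:10, function(seed)
    shannon_entropy(pattern_distribution_of(bernoulli_raster(8, n, q, seed))))
  bias <- (2^8 - 1) / (2 * log(2) * n)
  expect_lt(abs(mean(h_hat) - (8 * h_binary(q) - bias)), bias)
})

test_that("entropy state change is near zero without a state effect and detects one", {
  dur <- 200
  e <- epoch_set(c(0, 50, 100, 150), c(50, 100, 150, dur),
                 c("stationary", "running", "stationary", "running"))
  # no effect: same independent model throughout
  r0 <- bernoulli_raster(12, dur / 0.01, 0.05, seed = 13)
  esc0 <- entropy_state_change(r0, e, ensemble_size = 8, n_subsamples = 30,
                               n_shuffle_reps = 30, seed = 14)
  # realization-level SE of the entropy difference: both states hold
  # n_state bins of 8 units at q = 0.05, and the subsamples share the same
  # realization, so the analytic per-state variance sets the scale
  v_unit <- 0.05 * 0.95 * log2(0.95 / 0.05)^2
  se_delta <- sqrt(2 * 8 * v_unit / 10000)
  expect_lt(abs(mean(esc0$delta)), 3 * se_delta)

  # real effect: higher-rate (higher-entropy) running model
  m_lo <- maxent_model(rep(log(0.03 / 0.97), 12))
  m_hi <- maxent_model(rep(log(0.10 / 0.90), 12))
  gap <- model_entropy(m_hi) / 12 * 8 - model_entropy(m_lo) / 12 * 8
  r1 <- gen_state_modulated_population(m_lo, m_hi, e, seed = 15)$raster
  esc1 <- entropy_state_change(r1, e, ensemble_size = 8, n_subsamples = 30,
                               n_shuffle_reps = 0, seed = 16)
  expect_gt(mean(esc1$delta), 0)
  expect_lt(abs(mean(esc1$delta) - gap), 0.1)
  # shuffle null from rate-matched trains has no state structure
  expect_error(entropy_state_change(r1, epoch_set(0, dur, "stationary"),
                                    seed = 1),
               "state")
})

test_that("animal-level bootstrap is centred on the constructed group offset", {
  withr::with_seed(21, {
    ga <- lapply(1:3, function(i) rnorm(400, 1.0, 0.3))
    gb <- lapply(1:3, function(i) rnorm(400, 0.75, 0.3))
  })
  b0 <- animal_level_bootstrap(ga, ga, n_draw = 250, n_reps = 500, seed = 22)
  expect_lt(abs(b0$mean), 3 * sd(b0$differences) + 0.01)
  b1 <- animal_level_bootstrap(ga, gb, n_draw = 250, n_reps = 500, seed = 23)
  expect_lt(abs(b1$mean - 0.25), 0.05)
  b2 <- animal_level_bootstrap(ga, gb, n_draw = 250, n_reps = 500, seed = 23)
  expect_identical(b1$differences, b2$differences)
  expect_error(animal_level_bootstrap(ga, list(rnorm(100)), n_draw = 250),
               "n_draw")
})

test_that("entropy sweep grows with ensemble size and matches the direct call", {
  r <- bernoulli_raster(12, 3e4, 0.05, seed = 31)
  sw <- entropy_sweep(r, ensemble_sizes = c(3, 6, 9), n_subsamples = 40,
                      seed = 32)
  expect_true(all(diff(sw$mean_entropy) > 0))   # independent units: additive
  # coarser bins raise the per-unit marginal entropy while q < 0.5
  sw2 <- entropy_sweep(r, ensemble_sizes = 5, bin_widths = c(0.01, 0.02, 0.04),
                       n_subsamples = 40, seed = 33)
  expect_true(all(diff(sw2$mean_entropy) > 0))
  # per-cell errors are recorded, not thrown
  sw3 <- entropy_sweep(r, ensemble_sizes = c(5, 50), n_subsamples = 5, seed = 34)
  expect_true(is.na(sw3$mean_entropy[2]) && !is.na(sw3$error[2]))
})

test_that("rate matching deletes one-sidedly and equalises entropies", {
  n <- 3e4
  r_hi <- bernoulli_raster(10, n, 0.04, seed = 41)
  r_lo <- bernoulli_raster(10, n, 0.02, seed = 42)
  rm <- rate_matched_entropy(r_hi, r_lo, ensemble_size = 10,
                             n_subsamples = 20, seed = 43)
  # deletion only: matched raster is a subset of the original's 1s
  expect_true(all(rm$matched_a$mat <= r_hi$mat))
  expect_true(all(rm$matched_b$mat <= r_lo$mat))
  target <- 10 * h_binary(0.02) - (2^10 - 1) / (2 * log(2) * n)
  expect_lt(abs(mean(rm$entropy_a$entropies) - target), 0.05)
  expect_lt(abs(mean(rm$entropy_b$entropies) - target), 0.05)
})
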