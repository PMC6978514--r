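# Synthetic cohorts: control-like and amyloid-pathology-like populations
# built from block-structured pairwise maximum-entropy models, with
# behavioural state switching. The group parameter distributions are the
# package's emulation of dorsal-CA1 recordings in aged control vs amyloid
# (APP/PS1-like) mice: the amyloid-like group has lower intrinsic bias
# terms (lower firing rates) and weaker/more negative couplings (weaker
# pairwise interactions).

#' Default group parameters for synthetic cohorts
#'
#' Gaussian parameter distributions for the per-unit bias terms h and
#' within-block couplings J of the generative Ising models, plus the
#' running-state bias boost and behaviour statistics, for the two emulated
#' conditions.
#'
#' @param group `"control-like"` or `"amyloid-like"`.
#' @return list of generator parameters.
#' @export
cohort_params <- function(group = c("control-like", "amyloid-like")) {
  group <- match.arg(group)
  if (group == "control-like") {
    list(group = group, h_mean = -5.96, h_sd = 1.65,
         j_mean = -0.02, j_sd = 1.15, run_boost = 0.5,
         run_fraction = 0.0605, mean_velocity = 6.42)
  } else {
    list(group = group, h_mean = -6.26, h_sd = 1.56,
         j_mean = -0.25, j_sd = 1.04, run_boost = 0.3,
         run_fraction = 0.0684, mean_velocity = 4.63)
  }
}

#' Generate one synthetic animal
#'
#' Units are organised into independent blocks of `block_size`; each block
#' gets its own pairwise maximum-entropy model (h drawn from the group's
#' bias distribution, within-block J from its coupling distribution) and a
#' running-state variant with every bias term raised by `run_boost`.
#' Behaviour is generated with [gen_behavior]; bins inside running epochs
#' are drawn from the running models, other bins from the stationary
#' models ([gen_state_modulated_population] per block).
#'
#' @param params group parameters from [cohort_params].
#' @param n_units total units (default 50; a multiple of `block_size`).
#' @param block_size units per coupled block (default 10, <= 20).
#' @param duration seconds of simulated recording (default 1800).
#' @param bin_width raster bin width, seconds (default 0.010).
#' @param seed optional integer seed.
#' @return list: `spikes` ([spike_train_set]), `raster` ([binary_raster]),
#'   `epochs`, `velocity`, `models` (per-block stationary/running model
#'   pairs), `params`.
#' @export
gen_cohort_animal <- function(params, n_units = 50, block_size = 10,
                              duration = 1800, bin_width = 0.010,
                              seed = NULL) {
  stopifnot(n_units %% block_size == 0, block_size <= 20)
  with_opt_seed(seed, {
    beh <- gen_behavior(duration, params$run_fraction, params$mean_velocity)
    n_blocks <- n_units / block_size
    models <- vector("list", n_blocks)
    rasters <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      h <- stats::rnorm(block_size, params$h_mean, params$h_sd)
      J <- matrix(0, block_size, block_size)
      J[upper.tri(J)] <- stats::rnorm(sum(upper.tri(J)),
                                      params$j_mean, params$j_sd)
      J <- J + t(J)
      m_sta <- maxent_model(h, J)
      m_run <- maxent_model(h + params$run_boost, J)
      models[[b]] <- list(stationary = m_sta, running = m_run)
      rasters[[b]] <- gen_state_modulated_population(
        m_sta, m_run, beh$epochs, bin_width = bin_width)$raster
    }
    mat <- do.call(rbind, lapply(rasters, function(r) r$mat))
    raster <- binary_raster(mat, bin_width = bin_width)
    list(spikes = raster_to_spike_trains(raster, group = params$group),
         raster = raster, epochs = beh$epochs, velocity = beh$velocity,
         models = models, params = params)
  })
}

#' Generate a two-group synthetic cohort
#'
#' @param n_per_group animals per group (default 4).
#' @param n_units,block_size,duration,bin_width per-animal settings, as in
#'   [gen_cohort_animal].
#' @param seed optional integer seed (per-animal sub-seeds are derived
#'   from it).
#' @return list of animals; each has `id`, `group` and the
#'   [gen_cohort_animal] fields.
#' @export
gen_cohort <- function(n_per_group = 4, n_units = 50, block_size = 10,
                       duration = 1800, bin_width = 0.010, seed = NULL) {
  groups <- c("control-like", "amyloid-like")
  animals <- list()
  k <- 0L
  for (g in groups) {
    pars <- cohort_params(g)
    for (a in seq_len(n_per_group)) {
      k <- k + 1L
      sub_seed <- if (is.null(seed)) NULL else (seed * 131L + k) %% 2147483647L
      an <- gen_cohort_animal(pars, n_units, block_size, duration,
                              bin_width, seed = sub_seed)
      an$id <- sprintf("%s_%d", sub("-like", "", g), a)
      an$group <- g
      animals[[k]] <- an
    }
  }
  animals
}
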