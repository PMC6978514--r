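# Pattern (word) entropy of binary population activity: binarization,
# ensemble subsampling, behavioural-state conditioning, shuffle nulls and
# the animal-level bootstrap.

#' Binarize spike trains
#'
#' Each unit's spike train becomes a 0/1 row over non-overlapping bins
#' (default 10 ms): 1 if the unit spiked at least once in the half-open bin,
#' 0 if silent. The number of bins is `ceiling(duration / bin_width)`.
#'
#' @param s a [spike_train_set].
#' @param bin_width bin width in seconds (default 0.010).
#' @return A [binary_raster].
#' @export
binarize <- function(s, bin_width = 0.010) {
  stopifnot(bin_width > 0)
  n_bins <- ceiling(s$duration / bin_width)
  mat <- matrix(0L, n_units(s), n_bins)
  for (u in seq_len(n_units(s))) {
    st <- s$spike_times[[u]]
    if (length(st)) {
      b <- floor(st / bin_width) + 1L
      mat[u, b[b <= n_bins]] <- 1L
    }
  }
  binary_raster(mat, bin_width = bin_width, t0 = 0)
}

# centers of the raster's bins, seconds
bin_centers <- function(r) {
  r$t0 + (seq_len(ncol(r$mat)) - 0.5) * r$bin_width
}

#' Restrict a raster to epochs of one behavioural state
#'
#' Keeps the bins whose centre falls inside an epoch with the given label,
#' concatenated in time order.
#'
#' @param r a [binary_raster].
#' @param e an [epoch_set].
#' @param label `"running"` or `"stationary"`.
#' @return A [binary_raster] over the kept bins.
#' @export
restrict_to_epochs <- function(r, e, label) {
  if (!any(e$label == label)) stop("label not present in epoch set")
  centers <- bin_centers(r)
  keep <- rep(FALSE, length(centers))
  for (i in which(e$label == label))
    keep <- keep | (centers >= e$start[i] & centers < e$end[i])
  if (!any(keep)) stop("no bins fall inside '", label, "' epochs")
  binary_raster(r$mat[, keep, drop = FALSE], bin_width = r$bin_width,
                t0 = r$t0)
}

# pattern code (0-based, unit 1 = LSB) of every bin for a unit subset
raster_codes <- function(r, units) {
  w <- 2^(seq_along(units) - 1)
  as.integer(round(colSums(r$mat[units, , drop = FALSE] * w)))
}

#' Empirical pattern distribution of a unit subset
#'
#' Relative frequency of each of the `2^N` population patterns across bins,
#' for the N units selected (in the order given; the first selected unit is
#' the least-significant bit of the pattern code).
#'
#' @param r a [binary_raster].
#' @param units integer indices of the units to include (distinct; N <= 20).
#'   Default: all units.
#' @return A [pattern_distribution] with `n_samples = ncol(r$mat)`.
#' @export
pattern_distribution_of <- function(r, units = seq_len(nrow(r$mat))) {
  units <- as.integer(units)
  if (!length(units)) stop("unit subset must be non-empty")
  if (anyDuplicated(units) || any(units < 1) || any(units > nrow(r$mat)))
    stop("unit indices must be distinct and valid")
  if (length(units) > 20) stop("at most 20 units per ensemble")
  if (ncol(r$mat) == 0) stop("raster has no bins")
  counts <- tabulate(raster_codes(r, units) + 1L, nbins = 2^length(units))
  pattern_distribution(counts / sum(counts), n_samples = ncol(r$mat))
}

#' Plug-in Shannon entropy of a pattern distribution
#'
#' `sum_k -p_k log2 p_k` with the convention `0 log 0 = 0`. No bias
#' correction is applied (the plug-in / maximum-likelihood estimator).
#'
#' @param d a `pattern_distribution`.
#' @return entropy in bits, in `[0, N]`.
#' @export
shannon_entropy <- function(d) {
  p <- d$p[d$p > 0]
  -sum(p * log2(p))
}

#' Entropy over random ensemble subsamples
#'
#' Draws `n_subsamples` random ensembles of `ensemble_size` units (uniformly
#' without replacement within each draw; unit sets may repeat across draws)
#' and computes the plug-in pattern entropy of each.
#'
#' @param r a [binary_raster].
#' @param ensemble_size units per ensemble (default 10).
#' @param n_subsamples number of random ensembles (default 1000).
#' @param seed optional integer seed.
#' @return list of class `entropy_result`: `entropies` (bits, one per
#'   subsample), `subsets` (list of unit index vectors), `ensemble_size`,
#'   `condition`, `seed`.
#' @export
subsample_entropy <- function(r, ensemble_size = 10, n_subsamples = 1000,
                              seed = NULL) {
  n <- nrow(r$mat)
  if (n < ensemble_size)
    stop(sprintf("need >= %d units, have %d", ensemble_size, n))
  subsets <- with_opt_seed(seed,
    replicate(n_subsamples, sample.int(n, ensemble_size), simplify = FALSE))
  entropies <- vapply(subsets, function(u)
    shannon_entropy(pattern_distribution_of(r, u)), numeric(1))
  structure(list(entropies = entropies, subsets = subsets,
                 ensemble_size = ensemble_size, n_subsamples = n_subsamples,
                 condition = "overall", seed = seed),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "entropy_result (%s): %d subsamples of %d units; mean %.3f, sd %.3f bits\n",
    x$condition, x$n_subsamples, x$ensemble_size,
    mean(x$entropies), stats::sd(x$entropies)))
  invisible(x)
}

# rate-matched shuffle at raster level: independently permute each unit's
# bins, preserving its 1-count (hence its rate) exactly
shuffle_raster_bins <- function(r) {
  mat <- r$mat
  nb <- ncol(mat)
  for (u in seq_len(nrow(mat))) mat[u, ] <- mat[u, sample.int(nb)]
  binary_raster(mat, bin_width = r$bin_width, t0 = r$t0)
}

#' Entropy change between running and stationary states, with shuffle null
#'
#' For each of `n_subsamples` fixed random ensembles, computes the plug-in
#' entropy conditioned on running and on stationary bins and their
#' difference (running minus stationary). The null distribution comes from
#' `n_shuffle_reps` firing-rate-matched shuffles (each unit's bins randomly
#' permuted across the whole recording, preserving its spike-bin count),
#' processed identically over the same ensembles.
#'
#' @param r a [binary_raster] over the full recording.
#' @param e an [epoch_set] with both states present.
#' @param ensemble_size,n_subsamples as in [subsample_entropy].
#' @param n_shuffle_reps shuffle repetitions for the null (default 1000).
#' @param min_state_bins minimum bins required per state (default 100).
#' @param seed optional integer seed.
#' @return list: `delta` (per-subsample running - stationary entropy, bits),
#'   `entropy_running`, `entropy_stationary`, `null` (n_shuffle_reps x
#'   n_subsamples matrix of null deltas), `subsets`, `seed`.
#' @export
entropy_state_change <- function(r, e, ensemble_size = 10,
                                 n_subsamples = 1000, n_shuffle_reps = 1000,
                                 min_state_bins = 100, seed = NULL) {
  centers <- bin_centers(r)
  in_run <- rep(FALSE, length(centers))
  for (i in which(e$label == "running"))
    in_run <- in_run | (centers >= e$start[i] & centers < e$end[i])
  if (sum(in_run) < min_state_bins || sum(!in_run) < min_state_bins)
    stop(sprintf("need >= %d bins per state (running %d, stationary %d)",
                 min_state_bins, sum(in_run), sum(!in_run)))
  n <- nrow(r$mat)
  if (n < ensemble_size) stop("too few units for the ensemble size")
  with_opt_seed(seed, {
    subsets <- replicate(n_subsamples, sample.int(n, ensemble_size),
                         simplify = FALSE)
    both <- function(raster) {
      rr <- binary_raster(raster$mat[, in_run, drop = FALSE], r$bin_width)
      rs <- binary_raster(raster$mat[, !in_run, drop = FALSE], r$bin_width)
      h_run <- vapply(subsets, function(u)
        shannon_entropy(pattern_distribution_of(rr, u)), numeric(1))
      h_sta <- vapply(subsets, function(u)
        shannon_entropy(pattern_distribution_of(rs, u)), numeric(1))
      list(run = h_run, sta = h_sta)
    }
    emp <- both(r)
    null <- matrix(NA_real_, n_shuffle_reps, n_subsamples)
    for (rep_i in seq_len(n_shuffle_reps)) {
      sh <- both(shuffle_raster_bins(r))
      null[rep_i, ] <- sh$run - sh$sta
    }
    list(delta = emp$run - emp$sta, entropy_running = emp$run,
         entropy_stationary = emp$sta, null = null, subsets = subsets,
         seed = seed)
  })
}

#' Animal-level bootstrap of a group entropy difference
#'
#' Per repetition, draws `n_draw` entropy samples without replacement from
#' each animal, averages within animal, and records the difference of the
#' two group means (group A minus group B). The distribution of this
#' difference over `n_reps` repetitions summarises the animal-level effect.
#'
#' @param group_a,group_b lists of per-animal numeric entropy vectors, each
#'   of length >= `n_draw`.
#' @param n_draw samples drawn per animal per repetition (default 250).
#' @param n_reps repetitions (default 5000).
#' @param seed optional integer seed.
#' @return list: `differences` (length `n_reps`), `mean`, `ci95`
#'   (2.5/97.5 percentiles), `n_draw`, `n_reps`.
#' @export
animal_level_bootstrap <- function(group_a, group_b, n_draw = 250,
                                   n_reps = 5000, seed = NULL) {
  check <- function(g, nm) {
    if (!length(g)) stop("group ", nm, " has no animals")
    short <- vapply(g, length, integer(1)) < n_draw
    if (any(short)) stop("group ", nm, " has animals with < n_draw samples")
  }
  check(group_a, "A"); check(group_b, "B")
  with_opt_seed(seed, {
    one <- function(g) mean(vapply(g, function(x)
      mean(x[sample.int(length(x), n_draw)]), numeric(1)))
    diffs <- vapply(seq_len(n_reps), function(i) one(group_a) - one(group_b),
                    numeric(1))
    list(differences = diffs, mean = mean(diffs),
         ci95 = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
         n_draw = n_draw, n_reps = n_reps)
  })
}

# OR-rebin a raster into bins k times wider (a bin is 1 if any constituent
# fine bin is 1); trailing partial groups are kept
rebin_raster <- function(r, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(r)
  nb <- ncol(r$mat)
  grp <- (seq_len(nb) - 1L) %/% factor
  mat <- t(apply(r$mat, 1, function(row)
    as.integer(tapply(row, grp, max) > 0)))
  binary_raster(mat, bin_width = r$bin_width * factor, t0 = r$t0)
}

#' Entropy sweep over ensemble sizes and bin widths
#'
#' Repeats [subsample_entropy] for every combination of ensemble size and
#' bin width. Bin widths must be integer multiples of the raster's width;
#' coarser rasters are produced by OR-rebinning. Per-cell errors are caught
#' and recorded without aborting the sweep.
#'
#' @param r a [binary_raster] at the finest bin width.
#' @param ensemble_sizes integer vector (default 3:19).
#' @param bin_widths numeric vector of bin widths in seconds
#'   (default: the raster's own width).
#' @param n_subsamples subsamples per cell (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with columns `ensemble_size`, `bin_width`,
#'   `mean_entropy`, `sd_entropy`, `error` (NA or the error message).
#' @export
entropy_sweep <- function(r, ensemble_sizes = 3:19, bin_widths = NULL,
                          n_subsamples = 1000, seed = NULL) {
  if (is.null(bin_widths)) bin_widths <- r$bin_width
  grid <- expand.grid(ensemble_size = ensemble_sizes, bin_width = bin_widths)
  out <- with_opt_seed(seed, {
    res <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      res[[i]] <- tryCatch({
        fac <- grid$bin_width[i] / r$bin_width
        if (abs(fac - round(fac)) > 1e-9)
          stop("bin width must be a multiple of the raster bin width")
        rr <- rebin_raster(r, round(fac))
        er <- subsample_entropy(rr, grid$ensemble_size[i], n_subsamples)
        data.frame(mean_entropy = mean(er$entropies),
                   sd_entropy = stats::sd(er$entropies), error = NA_character_)
      }, error = function(e)
        data.frame(mean_entropy = NA_real_, sd_entropy = NA_real_,
                   error = conditionMessage(e)))
    }
    do.call(rbind, res)
  })
  cbind(grid, out)
}

#' Entropy comparison after one-sided firing-rate matching
#'
#' Matches the per-unit binwise firing rates of two rasters by randomly
#' deleting 1-bins, then compares subsample entropies. Units are paired by
#' rate rank (percentile matching); within each pair, the unit with the
#' higher 1-count has 1s deleted at random until the counts (scaled to the
#' shorter recording) agree. Deletion never creates a 1 from a 0. This
#' rate-correction surrogate is a synthetic stand-in: the original
#' correction procedure it emulates is not fully specified anywhere, so
#' results should be read qualitatively.
#'
#' @param r_a,r_b [binary_raster]s with equal unit counts.
#' @param ensemble_size,n_subsamples as in [subsample_entropy].
#' @param seed optional integer seed.
#' @return list: `entropy_a`, `entropy_b` ([subsample_entropy] results on
#'   the matched rasters), `matched_a`, `matched_b` (the rasters).
#' @export
rate_matched_entropy <- function(r_a, r_b, ensemble_size = 10,
                                 n_subsamples = 1000, seed = NULL) {
  if (nrow(r_a$mat) != nrow(r_b$mat))
    stop("rasters must have the same number of units")
  with_opt_seed(seed, {
    qa <- rowMeans(r_a$mat); qb <- rowMeans(r_b$mat)
    ord_a <- order(qa); ord_b <- order(qb)
    ma <- r_a$mat; mb <- r_b$mat
    for (k in seq_along(ord_a)) {
      ua <- ord_a[k]; ub <- ord_b[k]
      target_q <- min(qa[ua], qb[ub])
      for (side in 1:2) {
        if (side == 1) { m <- ma; u <- ua } else { m <- mb; u <- ub }
        n1 <- sum(m[u, ])
        want <- round(target_q * ncol(m))
        if (n1 > want) {
          ones <- which(m[u, ] == 1L)
          m[u, sample(ones, n1 - want)] <- 0L
          if (side == 1) ma <- m else mb <- m
        }
      }
    }
    ra <- binary_raster(ma, r_a$bin_width, r_a$t0)
    rb <- binary_raster(mb, r_b$bin_width, r_b$t0)
    list(entropy_a = subsample_entropy(ra, ensemble_size, n_subsamples),
         entropy_b = subsample_entropy(rb, ensemble_size, n_subsamples),
         matched_a = ra, matched_b = rb)
  })
}
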