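# Maximum-entropy (Ising) models of binary population patterns.
#
# A model over binary states sigma in {0,1}^N assigns
#   P(sigma) = exp(sum_i h_i sigma_i + 1/2 sum_{i != j} J_ij sigma_i sigma_j) / Z
# with J symmetric, zero-diagonal. Order-1 ("independent") models have J = 0.
# All probabilities, moments and the partition function are computed by exact
# enumeration of the 2^N states (N <= 20), chunked to bound memory.

.CHUNK <- 2^14L

# states for pattern codes (0-based); unit i = bit i-1 (LSB-first encoding)
state_bits <- function(codes, N) {
  m <- matrix(0L, length(codes), N)
  for (i in seq_len(N)) m[, i] <- (codes %/% 2^(i - 1)) %% 2L
  m
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Construct a maximum-entropy model
#'
#' @param h numeric vector of per-unit bias terms (dimensionless).
#' @param J optional symmetric coupling matrix with zero diagonal;
#'   `NULL` or all-zero gives an order-1 (independent) model.
#' @return An object of class `maxent_model` with fields `N`, `order`, `h`,
#'   `J` and `logZ` (log partition function, by exact enumeration).
#' @export
maxent_model <- function(h, J = NULL) {
  h <- as.numeric(h)
  N <- length(h)
  if (N < 1 || N > 20) stop("maxent_model supports 1 <= N <= 20 units")
  if (is.null(J)) J <- matrix(0, N, N)
  J <- as.matrix(J)
  stopifnot(nrow(J) == N, ncol(J) == N)
  if (max(abs(J - t(J))) > 1e-12) stop("J must be symmetric")
  if (max(abs(diag(J))) > 1e-12) stop("J must have zero diagonal")
  ord <- if (all(J == 0)) 1L else 2L
  m <- structure(list(N = N, order = ord, h = h, J = J, logZ = NA_real_),
                 class = "maxent_model")
  m$logZ <- model_logZ(m)
  m
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: order %d, N = %d, logZ = %.6f\n",
              x$order, x$N, x$logZ))
  cat(sprintf("  mean h = %.3f", mean(x$h)))
  if (x$order == 2)
    cat(sprintf(", mean J (off-diag) = %.3f",
                mean(x$J[upper.tri(x$J)])))
  cat("\n")
  invisible(x)
}

# unnormalized log-probability of each state code
state_energy <- function(m, codes) {
  S <- state_bits(codes, m$N)
  e <- as.numeric(S %*% m$h)
  if (m$order == 2) e <- e + 0.5 * rowSums((S %*% m$J) * S)
  e
}

model_logZ <- function(m) {
  K <- 2^m$N
  parts <- numeric(0)
  for (lo in seq(0, K - 1, by = .CHUNK)) {
    codes <- lo:min(lo + .CHUNK - 1, K - 1)
    parts <- c(parts, logsumexp(state_energy(m, codes)))
  }
  logsumexp(parts)
}

#' Exact pattern probabilities of a maximum-entropy model
#'
#' Enumerates all `2^N` binary states and returns their exact probabilities
#' under the model.
#'
#' @param m a `maxent_model`.
#' @return A [pattern_distribution].
#' @export
model_pattern_probs <- function(m) {
  K <- 2^m$N
  p <- numeric(K)
  for (lo in seq(0, K - 1, by = .CHUNK)) {
    codes <- lo:min(lo + .CHUNK - 1, K - 1)
    p[codes + 1] <- exp(state_energy(m, codes) - m$logZ)
  }
  pattern_distribution(p / sum(p), n_samples = NA_real_)
}

# first and second moments <sigma_i>, <sigma_i sigma_j> of a pattern
# distribution (empirical or model), by enumeration
distribution_moments <- function(d) {
  N <- d$N
  m1 <- numeric(N)
  m2 <- matrix(0, N, N)
  K <- 2^N
  for (lo in seq(0, K - 1, by = .CHUNK)) {
    codes <- lo:min(lo + .CHUNK - 1, K - 1)
    S <- state_bits(codes, N)
    w <- d$p[codes + 1]
    m1 <- m1 + as.numeric(crossprod(S, w))
    m2 <- m2 + crossprod(S * w, S)
  }
  diag(m2) <- m1
  list(first = m1, second = m2)
}

# feature matrix for the sufficient statistics (sigma_i; sigma_i sigma_j, i<j)
feature_matrix <- function(codes, N) {
  S <- state_bits(codes, N)
  if (N < 2) return(S)
  ut <- which(upper.tri(diag(N)), arr.ind = TRUE)
  cbind(S, S[, ut[, 1], drop = FALSE] * S[, ut[, 2], drop = FALSE])
}

# theta = c(h, J[upper.tri]); returns list(mu, H): model feature means and
# feature covariance (the NLL Hessian), by chunked enumeration
model_feature_stats <- function(theta, N, want_cov = TRUE) {
  D <- length(theta)
  K <- 2^N
  energies <- numeric(K)
  for (lo in seq(0, K - 1, by = .CHUNK)) {
    codes <- lo:min(lo + .CHUNK - 1, K - 1)
    energies[codes + 1] <- as.numeric(feature_matrix(codes, N) %*% theta)
  }
  logZ <- logsumexp(energies)
  mu <- numeric(D)
  EFF <- if (want_cov) matrix(0, D, D) else NULL
  for (lo in seq(0, K - 1, by = .CHUNK)) {
    codes <- lo:min(lo + .CHUNK - 1, K - 1)
    Fc <- feature_matrix(codes, N)
    pc <- exp(energies[codes + 1] - logZ)
    mu <- mu + as.numeric(crossprod(Fc, pc))
    if (want_cov) EFF <- EFF + crossprod(Fc * pc, Fc)
  }
  H <- if (want_cov) EFF - tcrossprod(mu) else NULL
  list(mu = mu, H = H, logZ = logZ)
}

theta_to_model <- function(theta, N, order) {
  h <- theta[seq_len(N)]
  J <- matrix(0, N, N)
  if (order == 2 && N > 1) {
    J[upper.tri(J)] <- theta[-seq_len(N)]
    J <- J + t(J)
  }
  maxent_model(h, J)
}

clip_moments <- function(x, n_samples) {
  eps <- if (is.finite(n_samples) && n_samples > 0) {
    1 / (2 * n_samples)
  } else {
    if (any(x <= 0 | x >= 1))
      warning("moment at 0 or 1 with unknown sample size; clipping at 1e-6")
    1e-6
  }
  pmin(pmax(x, eps), 1 - eps)
}

#' Fit an independent (order-1) maximum-entropy model
#'
#' Closed form: `h_i = log(m_i / (1 - m_i))` where `m_i` is unit i's marginal
#' spike probability. Marginals are clipped to `[eps, 1 - eps]` with
#' `eps = 1/(2 n_samples)` before the logit (or `1e-6` with a warning when
#' the sample size is unknown and a marginal sits exactly at 0 or 1).
#'
#' @param d a `pattern_distribution`.
#' @return `list(model, report)`: the fitted [maxent_model] and a fit report
#'   with `iterations`, `moment_mismatch` and `converged`.
#' @export
fit_independent <- function(d) {
  mom <- distribution_moments(d)
  m1 <- clip_moments(mom$first, d$n_samples)
  h <- log(m1 / (1 - m1))
  model <- maxent_model(h)
  fit1 <- distribution_moments(model_pattern_probs(model))$first
  mism <- max(abs(fit1 - m1))
  list(model = model,
       report = list(iterations = 0L, moment_mismatch = mism,
                     converged = mism <= 1e-9))
}

#' Fit a pairwise (order-2) maximum-entropy model
#'
#' Maximum-likelihood fit of the Ising model to an empirical pattern
#' distribution, with exact gradients and Hessian computed by enumerating all
#' `2^N` states at each step (damped Newton iteration on the convex negative
#' log-likelihood). Convergence is declared when the largest absolute
#' difference between model and empirical first/second moments -- the
#' model's sufficient statistics -- drops below `tol`.
#'
#' @param d a `pattern_distribution` (N <= 20; practical fits are N <= 15).
#' @param tol moment-mismatch convergence tolerance (default 1e-6).
#' @param max_iter iteration cap; on hitting it the best parameters so far
#'   are returned with `converged = FALSE`.
#' @return `list(model, report)` as in [fit_independent].
#' @export
fit_pairwise <- function(d, tol = 1e-6, max_iter = 1e4) {
  N <- d$N
  mom <- distribution_moments(d)
  ut <- upper.tri(diag(N))
  target <- c(clip_moments(mom$first, d$n_samples),
              if (N > 1) clip_moments(mom$second[ut], d$n_samples))
  # start from the independent closed form
  h0 <- log(target[seq_len(N)] / (1 - target[seq_len(N)]))
  theta <- c(h0, rep(0, sum(ut)))
  D <- length(theta)
  nll <- function(th, st) st$logZ - sum(th * target)
  st <- model_feature_stats(theta, N)
  f <- nll(theta, st)
  mismatch <- max(abs(st$mu - target))
  iter <- 0L
  while (mismatch > tol && iter < max_iter) {
    iter <- iter + 1L
    grad <- st$mu - target                 # gradient of the NLL
    step <- tryCatch(solve(st$H + diag(1e-10, D), grad),
                     error = function(e) grad)
    alpha <- 1
    repeat {                               # backtracking line search
      theta_new <- theta - alpha * step
      st_new <- model_feature_stats(theta_new, N)
      f_new <- nll(theta_new, st_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { st_new <- st; theta_new <- theta; f_new <- f; break }
    }
    theta <- theta_new; st <- st_new; f <- f_new
    mismatch <- max(abs(st$mu - target))
    if (alpha < 1e-12) break               # no descent possible
  }
  model <- theta_to_model(theta, N, order = 2L)
  list(model = model,
       report = list(iterations = iter, moment_mismatch = mismatch,
                     converged = mismatch <= tol))
}

#' Kullback-Leibler divergence between pattern distributions
#'
#' `D(empirical || model) = sum_k p_emp(k) log2(p_emp(k) / p_model(k))` in
#' bits; terms with `p_emp = 0` contribute 0. Infinite when the model assigns
#' zero probability to an observed pattern (cannot occur for maximum-entropy
#' models, whose probabilities are strictly positive); a warning is raised.
#'
#' @param empirical,model `pattern_distribution`s over the same N.
#' @return divergence in bits (non-negative).
#' @export
kld <- function(empirical, model) {
  if (empirical$N != model$N) stop("distributions must share N")
  idx <- empirical$p > 0
  if (any(model$p[idx] == 0)) {
    warning("model assigns zero probability to an observed pattern; KLD infinite")
    return(Inf)
  }
  sum(empirical$p[idx] * log2(empirical$p[idx] / model$p[idx]))
}

#' Coactivity spectrum of a pattern distribution
#'
#' Probability of observing exactly `k` simultaneously active units,
#' `k = 0..N`: the sum of pattern probabilities over patterns with popcount k.
#'
#' @param d a `pattern_distribution`.
#' @return numeric vector of length `N + 1`, named `"0".."N"`, summing to 1.
#' @export
coactivity_spectrum <- function(d) {
  N <- d$N
  out <- numeric(N + 1)
  K <- 2^N
  for (lo in seq(0, K - 1, by = .CHUNK)) {
    codes <- lo:min(lo + .CHUNK - 1, K - 1)
    k <- rowSums(state_bits(codes, N))
    out <- out + as.numeric(tapply(d$p[codes + 1], factor(k, levels = 0:N),
                                   sum, default = 0))
  }
  names(out) <- 0:N
  out
}

#' Sample a binary raster from a maximum-entropy model
#'
#' Bins are i.i.d. draws from the model's exact pattern distribution
#' (delegates to [gen_ising_raster]).
#'
#' @param m a `maxent_model` (N <= 20).
#' @param n_bins number of bins to draw.
#' @param seed optional integer seed.
#' @param bin_width bin width in seconds for the resulting raster.
#' @return A [binary_raster].
#' @export
sample_model <- function(m, n_bins, seed = NULL, bin_width = 0.010) {
  gen_ising_raster(m, n_bins, seed = seed, bin_width = bin_width)$raster
}

#' Shannon entropy of a maximum-entropy model's distribution
#'
#' @param m a `maxent_model`.
#' @return entropy in bits.
#' @export
model_entropy <- function(m) shannon_entropy(model_pattern_probs(m))
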