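#' Scaling context: mutation rate and generation time
#'
#' @param mu mutation rate per site per generation (default 2.5e-8, the
#'   mid-range estimate for Picea/Pinus adjusted to a 25-50 year generation
#'   time).
#' @param generation_time generation time in years (default 25).
#' @return list with `mu` and `generation_time`.
#' @export
scaling_context <- function(mu = 2.5e-8, generation_time = 25) {
  if (mu <= 0 || generation_time <= 0) stop("mu and generation_time must be > 0")
  list(mu = mu, generation_time = generation_time)
}

#' Effective population size from theta
#'
#' `N = theta / (4 mu)` for theta per bp.
#'
#' @param theta population-scaled mutation rate per bp.
#' @param ctx a [scaling_context()].
#' @export
ne_from_theta <- function(theta, ctx = scaling_context()) {
  if (any(theta < 0)) stop("theta must be >= 0")
  theta / (4 * ctx$mu)
}

#' Theta from an effective population size
#' @param N effective size. @param ctx a [scaling_context()].
#' @export
theta_from_ne <- function(N, ctx = scaling_context()) 4 * N * ctx$mu

#' Generations from coalescent time
#'
#' `T = 4 N t` for t in units of 4N generations.
#'
#' @param t time in coalescent units (4N generations).
#' @param N effective population size.
#' @export
generations_from_tau <- function(t, N) {
  if (any(t < 0) || any(N < 0)) stop("inputs must be >= 0")
  4 * N * t
}

#' Years from generations
#' @param T_gen time in generations. @param ctx a [scaling_context()].
#' @export
years_from_generations <- function(T_gen, ctx = scaling_context()) {
  if (any(T_gen < 0)) stop("inputs must be >= 0")
  T_gen * ctx$generation_time
}

#' Percent reduction in effective population size
#'
#' `100 (1 - n_present / n_past)`; negative values (growth) are allowed but
#' flagged with a warning.
#'
#' @param n_past past effective size (> 0).
#' @param n_present present effective size.
#' @export
reduction_percent <- function(n_past, n_present) {
  if (any(n_past <= 0)) stop("n_past must be > 0")
  out <- 100 * (1 - n_present / n_past)
  if (any(out < 0)) warning("n_present exceeds n_past: negative reduction (growth)")
  out
}

#' Evanno's delta-K from clustering likelihood traces
#'
#' Second-order rate of change of the mean log-likelihood across consecutive
#' K, normalized by its standard deviation across runs:
#' `deltaK(K) = |L(K+1) - 2 L(K) + L(K-1)| / sd(K)`.
#'
#' @param K consecutive integer cluster counts (>= 3 values).
#' @param mean_lnl mean log-likelihood per K across runs.
#' @param sd_lnl standard deviation of the log-likelihood per K.
#' @return data.frame of interior K and `delta_k` (`NA` where sd = 0,
#'   flagged by a warning).
#' @export
evanno_delta_k <- function(K, mean_lnl, sd_lnl) {
  if (length(K) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(K) != 1)) stop("K values must be consecutive integers")
  if (length(mean_lnl) != length(K) || length(sd_lnl) != length(K))
    stop("mean_lnl and sd_lnl must match K in length")
  i <- 2:(length(K) - 1)
  dk <- abs(mean_lnl[i + 1] - 2 * mean_lnl[i] + mean_lnl[i - 1]) / sd_lnl[i]
  if (any(sd_lnl[i] == 0)) {
    warning("sd = 0 at some K: delta-K undefined there")
    dk[sd_lnl[i] == 0] <- NA_real_
  }
  data.frame(K = K[i], delta_k = dk)
}
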