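# a hand-built reference table for conjugate toy problems: one parameter
# "theta" ~ U(0, 10) observed through a single noisy statistic
toy_table <- function(nsims, seed, noise = 1, informative = TRUE) {
  set.seed(seed)
  th <- stats::runif(nsims, 0, 10)
  st <- if (informative) th + stats::rnorm(nsims, 0, noise) else stats::rnorm(nsims)
  structure(list(model = "toy", params = cbind(theta = th),
                 stats = cbind(y = st), nsims = nsims, seed = seed),
            class = "ref_table")
}
toy_bounds <- matrix(c(0, 10), 2, 1, dimnames = list(c("lo", "hi"), "theta"))

test_that("rejection acceptance counts, weights and edge cases behave as specified", {
  tb <- toy_table(2000, 1)
  ps <- abc_reject(c(y = 5), tb, tolerance = 1)
  expect_equal(ps$n_accept, 2000)
  expect_true(all(ps$weights >= 0))
  expect_equal(max(ps$weights), ps$weights[1])
  # an observation equal to one row's stats gives that row distance 0 and
  # maximal weight
  obs <- c(y = unname(tb$stats[123, 1]))
  ps2 <- abc_reject(obs, tb, tolerance = 0.05)
  expect_equal(min(ps2$distances), 0)
  expect_equal(ps2$weights[which.min(ps2$distances)], max(ps2$weights))
  # acceptance count is the ceiling of tolerance x table size
  expect_equal(abc_reject(c(y = 5), tb, tolerance = 0.013)$n_accept, 26)
  # constant statistic columns are dropped with a warning
  tb2 <- tb
  tb2$stats <- cbind(tb$stats, flat = rep(1, 2000))
  expect_warning(abc_reject(c(y = 5, flat = 1), tb2, tolerance = 0.1), "constant")
})

test_that("the ABC posterior converges to the analytic truncated-normal posterior", {
  tb <- toy_table(40000, 2)
  obs <- c(y = 5)
  # analytic posterior for y ~ N(theta, 1), theta ~ U(0,10): N(5, 1) (truncation
  # negligible at 5 sigma)
  err <- vapply(c(0.5, 0.1, 0.01), function(tol) {
    ps <- abc_reject(obs, tb, tolerance = tol)
    q <- oracle_weighted_q(ps$params[, 1], ps$weights, c(0.25, 0.5, 0.75))
    sqrt(mean((q - stats::qnorm(c(0.25, 0.5, 0.75), 5, 1))^2))
  }, numeric(1))
  # the acceptance-window bias shrinks as the tolerance decreases, down to
  # the Monte-Carlo floor of the accepted sample
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.15)
})

test_that("regression adjustment shrinks RMSE on the linear-Gaussian oracle", {
  # RMSE of the weighted posterior draws around the generating value: the
  # local-linear correction removes the spread contributed by the acceptance
  # window
  tb <- toy_table(5000, 3, noise = 0.5)
  set.seed(4)
  truth <- stats::runif(60, 2, 8)
  est <- t(vapply(truth, function(th) {
    obs <- c(y = th + stats::rnorm(1, 0, 0.5))
    ps <- abc_reject(obs, tb, tolerance = 0.1)
    psa <- regression_adjust(ps, model = toy_bounds)
    w <- ps$weights / sum(ps$weights)
    c(rej = sum(w * (ps$params[, 1] - th)^2),
      adj = sum(w * (psa$adjusted[, 1] - th)^2))
  }, numeric(2)))
  rmse <- sqrt(colMeans(est))
  expect_lt(rmse["adj"], rmse["rej"])
})

test_that("uninformative statistics leave the rejection sample unadjusted", {
  tb <- toy_table(3000, 5, informative = FALSE)
  ps <- abc_reject(c(y = 0), tb, tolerance = 0.2)
  psa <- regression_adjust(ps, model = toy_bounds)
  expect_gt(stats::cor(psa$adjusted[, 1], ps$params[, 1]), 0.99)
  expect_lt(mean(abs(psa$adjusted[, 1] - ps$params[, 1])) / stats::sd(ps$params[, 1]), 0.25)
})

test_that("adjusted draws may leave the prior box and are counted, not clipped", {
  tb <- toy_table(4000, 6, noise = 2)
  ps <- abc_reject(c(y = 9.9), tb, tolerance = 0.1)
  psa <- regression_adjust(ps, model = toy_bounds)
  expect_true(!is.null(attr(psa$adjusted, "n_outside_prior")))
  expect_gte(attr(psa$adjusted, "n_outside_prior"), 0)
})

test_that("posterior summaries recover known modes and percentiles", {
  # weighted draws from Beta(2,5): analytic mode 0.2
  set.seed(7)
  x <- stats::rbeta(20000, 2, 5)
  ps <- structure(list(model = "toy", params = cbind(b = x), adjusted = NULL,
                       weights = rep(1, length(x)), obs = c(y = 0),
                       stats = cbind(y = x), scales = c(y = 1),
                       n_accept = length(x), tolerance = 1),
                  class = "posterior_sample")
  sm <- summarize_posterior(ps)
  expect_lt(abs(sm$mode - 0.2), 0.03)
  # uniform draws: percentiles near 0.05 and 0.95 of the range
  ps$params <- cbind(u = stats::runif(20000))
  sm2 <- summarize_posterior(ps)
  expect_lt(abs(sm2$q05 - 0.05), 0.01)
  expect_lt(abs(sm2$q95 - 0.95), 0.01)
  # symmetric unimodal sample: mode near mean
  ps$params <- cbind(z = stats::rnorm(20000, 3, 0.5))
  sm3 <- summarize_posterior(ps)
  expect_lt(abs(sm3$mode - 3), 0.08)
  # degenerate sample collapses to the common value
  ps$params <- cbind(c = rep(2.5, 20000))
  expect_equal(summarize_posterior(ps)$mode, 2.5)
})

test_that("reference tables are reproducible and the estimator is unbiased in theta", {
  des <- study_design("within")[c(1, 5, 9), ]
  rt1 <- build_reference_table("constant", des, nsims = 30, seed = 5)
  rt2 <- build_reference_table("constant", des, nsims = 30, seed = 5)
  expect_identical(rt1$stats, rt2$stats)
  expect_identical(rt1$params, rt2$params)
  # regressing the mean Watterson estimate on theta over prior draws gives
  # slope ~ 1 (unbiasedness of the estimator)
  rt <- build_reference_table("constant", study_design("within"), nsims = 3000, seed = 6)
  fit <- stats::lm(rt$stats[, "thW_mean"] ~ rt$params[, "theta"])
  expect_lt(abs(stats::coef(fit)[2] - 1), 0.05)
})

test_that("a recent severe decline produces positive Tajima's D on average", {
  # the intermediate-variant excess needs lineages surviving across the size
  # change, i.e. a decline younger than the compressed coalescent time scale
  # (t below about alpha in units of 4N generations)
  rt <- build_reference_table("decline", study_design("within"), nsims = 4000, seed = 7)
  sel <- rt$params[, "alpha"] > 0.05 & rt$params[, "alpha"] < 0.4 &
    rt$params[, "t"] < 0.5 * rt$params[, "alpha"] & rt$params[, "theta"] > 0.002
  expect_gt(sum(sel), 20)
  expect_gt(mean(rt$stats[sel, "D_mean"]), 0)
})
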