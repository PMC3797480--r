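#' Posterior predictive check
#'
#' Resamples parameter vectors from the (regression-adjusted, weighted)
#' posterior, simulates a study-shaped data set for each, and compares the
#' predictive distribution of every summary statistic with its observed
#' value. Draws that fall outside the model's validity region after
#' adjustment (e.g. a non-positive size scaling) are resampled and counted.
#'
#' @param sample a `posterior_sample` (adjusted draws are used if present).
#' @param design study design data.frame.
#' @param ndraws number of posterior predictive simulations (default 1000).
#' @param seed master integer seed.
#' @param model model name or spec; defaults to the sample's model.
#' @return a `ppc_report` data.frame: per statistic the observed value,
#'   predictive quantiles (2.5/50/97.5%), and the two-sided tail probability
#'   `2 min(P(sim <= obs), P(sim >= obs))` capped at 1. The number of
#'   resampled invalid draws is recorded as an attribute.
#' @export
posterior_predictive <- function(sample, design, ndraws = 1000, seed = 1,
                                 model = sample$model) {
  spec <- model_spec(model)
  p <- if (!is.null(sample$adjusted)) sample$adjusted else sample$params
  if (nrow(p) < 1) stop("empty posterior sample")
  w <- sample$weights / sum(sample$weights)
  valid <- function(x) {
    all(x > 0 | names(x) %in% c("log_M")) &&
      (is.null(spec$constraint) || spec$constraint(x))
  }
  sims <- NULL
  n_invalid <- 0L
  got <- 0L
  idx <- with_seed(seed, sample.int(nrow(p), 50 * ndraws, replace = TRUE, prob = w))
  ptr <- 0L
  while (got < ndraws) {
    ptr <- ptr + 1L
    if (ptr > length(idx)) stop("could not find enough valid posterior draws")
    par <- p[idx[ptr], ]
    names(par) <- colnames(p)
    if (!valid(par)) { n_invalid <- n_invalid + 1L; next }
    demo <- build_demography_unchecked(spec, par)
    st <- simulate_study(design, demo, seed = cpp_mix_seed(seed, ptr),
                         output = "stats")
    if (is.null(sims)) sims <- matrix(NA_real_, ndraws, length(st),
                                      dimnames = list(NULL, names(st)))
    got <- got + 1L
    sims[got, ] <- st
  }
  obs <- sample$obs[colnames(sims)]
  out <- data.frame(stat = colnames(sims), observed = as.numeric(obs),
                    q025 = NA_real_, q50 = NA_real_, q975 = NA_real_,
                    p_tail = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(sims))) {
    x <- sims[, j]
    qq <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    out$q025[j] <- qq[1]; out$q50[j] <- qq[2]; out$q975[j] <- qq[3]
    lo <- mean(x <= obs[j]); hi <- mean(x >= obs[j])
    out$p_tail[j] <- min(1, 2 * min(lo, hi))
  }
  structure(out, class = c("ppc_report", "data.frame"),
            ndraws = ndraws, n_invalid = n_invalid)
}

# adjusted posterior draws may lie outside the prior box, which
# build_demography rejects by design; the predictive step only requires
# structural validity
build_demography_unchecked <- function(spec, params) {
  g <- spec$build(params)
  evm <- g$events
  if (nrow(evm) > 1) evm <- evm[order(evm[, 1]), , drop = FALSE]
  structure(list(model = spec$name, kind = spec$kind, params = params,
                 theta = params[["theta"]], rho = params[["rho"]],
                 sizes = g$sizes, mig = g$mig, events = evm,
                 split_samples = isTRUE(spec$split_samples)),
            class = "demography")
}

#' Power and false-positive-rate study for ABC model choice
#'
#' Simulates pseudo-observed data sets (PODs) under a generating model with
#' parameters drawn from its priors, runs model choice against a shared set
#' of reference tables, and tabulates how often the decline model is
#' favoured by a Bayes factor of at least `bf_threshold` (and, optionally,
#' at least an observed Bayes factor). When the generating model is the
#' decline model the rates are its power against each competing model; when
#' the generating model is a competing (null) model the rate at which it is
#' itself rejected in favour of decline is its false-positive rate.
#'
#' The reference tables are built once and shared across replicates; only
#' the pseudo-observed data set varies.
#'
#' @param tables named list of `ref_table`s (must include `"decline"`).
#' @param data_model name of the generating model for the PODs.
#' @param design study design used for the PODs.
#' @param nreps number of pseudo-observed data sets (default 100).
#' @param tolerance model-choice tolerance.
#' @param bf_threshold Bayes-factor rejection threshold (default 3).
#' @param observed_bf optional named vector of observed Bayes factors
#'   (decline vs model) for the `rate_ge_obs` column.
#' @param seed master integer seed.
#' @param method model-choice method.
#' @param focal_model the model whose Bayes factor against the others is
#'   tracked (default `"decline"`).
#' @return a `power_report` data.frame: one row per comparison model with
#'   the rate of BF >= threshold (named `power` when `data_model` is the
#'   focal model, `fpr` otherwise) and the replicate count; the matrix of
#'   per-replicate Bayes factors is attached as attribute `bf`.
#' @export
power_study <- function(tables, data_model, design, nreps = 100,
                        tolerance = 0.01, bf_threshold = 3,
                        observed_bf = NULL, seed = 1,
                        method = c("mnlogistic", "rejection"),
                        focal_model = "decline") {
  method <- match.arg(method)
  stopifnot(nreps >= 1)
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- vapply(tables, `[[`, character(1), "model")
  if (!focal_model %in% names(tables))
    stop("tables must include the focal model '", focal_model, "'")
  others <- setdiff(names(tables), focal_model)
  spec <- model_spec(data_model)
  pods <- draw_prior(spec, nreps, seed = cpp_mix_seed(seed, 0))
  bf <- matrix(NA_real_, nreps, length(others),
               dimnames = list(NULL, others))
  for (r in seq_len(nreps)) {
    demo <- build_demography(spec, pods[r, ])
    obs <- simulate_study(design, demo, seed = cpp_mix_seed(seed, r),
                          output = "stats")
    mc <- model_choice(obs, tables, tolerance = tolerance, method = method)
    bf[r, ] <- mc$prob[focal_model] / mc$prob[others]
  }
  rate <- colMeans(bf >= bf_threshold)
  out <- data.frame(comparison = others, rate_ge_threshold = as.numeric(rate),
                    threshold = bf_threshold, nreps = nreps,
                    stringsAsFactors = FALSE)
  names(out)[2] <- if (data_model == focal_model) "power" else "fpr"
  if (!is.null(observed_bf)) {
    out$rate_ge_obs <- vapply(others, function(m) {
      if (!m %in% names(observed_bf)) return(NA_real_)
      mean(bf[, m] >= observed_bf[[m]])
    }, numeric(1))
  }
  structure(out, class = c("power_report", "data.frame"),
            bf = bf, data_model = data_model, focal_model = focal_model)
}
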