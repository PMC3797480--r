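#' Build an ABC reference table for one model
#'
#' Draws `nsims` parameter vectors from the model's priors, simulates a
#' study-shaped data set for each, and records the summary-statistic vector.
#' Fully deterministic under the master seed (per-row simulation streams are
#' derived from it).
#'
#' @param model model name or spec.
#' @param design study design data.frame (see [study_design()]).
#' @param nsims number of simulations (the original analysis used 1e6; the
#'   package default workflows use 2e4, which pairs with tolerance 0.01 to
#'   give acceptance counts comparable to 1e6 x 0.001).
#' @param seed master integer seed.
#' @return a `ref_table`: list with `model`, `params` (nsims x p), `stats`
#'   (nsims x k), `nsims`, `seed`, `design`.
#' @export
build_reference_table <- function(model, design, nsims, seed = 1) {
  spec <- model_spec(model)
  stopifnot(nsims >= 1)
  draws <- draw_prior(spec, nsims, seed = seed)
  k <- if (spec$kind == "between") 21L else 9L
  stats <- matrix(NA_real_, nsims, k)
  for (i in seq_len(nsims)) {
    demo <- build_demography(spec, draws[i, ])
    stats[i, ] <- simulate_study(design, demo, seed = cpp_mix_seed(seed, i),
                                 output = "stats")
  }
  colnames(stats) <- if (spec$kind == "between") BETWEEN_STAT_NAMES else WITHIN_STAT_NAMES
  structure(list(model = spec$name, params = draws, stats = stats,
                 nsims = nsims, seed = seed, design = design),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat("<ref_table> model ", x$model, ": ", x$nsims, " simulations, ",
      ncol(x$stats), " statistics, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# match an observed vector to the table's statistic columns
align_obs <- function(obs, nm) {
  if (is.null(names(obs))) {
    if (length(obs) != length(nm))
      stop("observed vector has ", length(obs), " values; table has ", length(nm))
    names(obs) <- nm
    return(obs)
  }
  if (!all(nm %in% names(obs)))
    stop("observed vector is missing statistic(s): ",
         paste(setdiff(nm, names(obs)), collapse = ", "))
  obs[nm]
}

# robust per-statistic scales: median absolute deviation with a standard
# deviation fallback where the MAD degenerates to 0
stat_scales <- function(stats, robust = TRUE) {
  sc <- if (robust) apply(stats, 2, stats::mad) else apply(stats, 2, stats::sd)
  zero <- sc <= 0 | !is.finite(sc)
  if (any(zero) && robust) sc[zero] <- apply(stats[, zero, drop = FALSE], 2, stats::sd)
  sc
}

#' ABC rejection step
#'
#' Standardizes every summary statistic by its table-wide median absolute
#' deviation (falling back to the standard deviation where the MAD is zero;
#' columns with no spread at all are dropped with a warning), computes
#' Euclidean distances to the observed vector, accepts the `tolerance`
#' quantile of the table and attaches Epanechnikov weights
#' `w_i = 1 - (d_i/d_max)^2`.
#'
#' @param obs observed summary-statistic vector.
#' @param table a `ref_table`.
#' @param tolerance accepted fraction of the table, in (0, 1].
#' @param robust use MAD scaling (default) or plain standard deviations.
#' @return a `posterior_sample`: accepted parameters, weights, distances.
#' @export
abc_reject <- function(obs, table, tolerance = 0.01, robust = TRUE) {
  stopifnot(tolerance > 0, tolerance <= 1)
  obs <- align_obs(obs, colnames(table$stats))
  sc <- stat_scales(table$stats, robust)
  drop <- sc <= 0 | !is.finite(sc)
  if (any(drop)) {
    warning("dropping constant statistic(s) from the distance: ",
            paste(colnames(table$stats)[drop], collapse = ", "))
  }
  keep <- which(!drop)
  z <- sweep(table$stats[, keep, drop = FALSE], 2, sc[keep], "/")
  zo <- obs[keep] / sc[keep]
  d <- sqrt(rowSums(sweep(z, 2, zo)^2))
  nacc <- ceiling(tolerance * table$nsims)
  ord <- order(d)[seq_len(nacc)]
  dmax <- d[ord[nacc]]
  w <- if (dmax > 0) 1 - (d[ord] / dmax)^2 else rep(1, nacc)
  # keep the boundary point usable when all weights would otherwise vanish
  if (all(w == 0)) w <- rep(1, nacc)
  structure(list(model = table$model, params = table$params[ord, , drop = FALSE],
                 adjusted = NULL, weights = w, distances = d[ord],
                 tolerance = tolerance, n_accept = nacc, obs = obs,
                 scales = sc, stats = table$stats[ord, , drop = FALSE],
                 stat_names = colnames(table$stats)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("<posterior_sample> model ", x$model, ": ", x$n_accept, " draws",
      if (!is.null(x$adjusted)) ", regression-adjusted" else "",
      ", tolerance ", x$tolerance, "\n", sep = "")
  invisible(x)
}

#' Local-linear regression adjustment of an ABC posterior
#'
#' Beaumont-style correction: parameters are log-transformed (with a small
#' offset epsilon = 1e-8 times the prior range, so bounds at zero are
#' handled), regressed by weighted least squares on the accepted statistics
#' centred at the observation, and replaced by the fitted value at the
#' observation plus the residual. Adjusted draws are back-transformed and
#' are deliberately not clipped to the prior bounds; excursions are counted
#' in the attribute `n_outside_prior`.
#'
#' @param sample a `posterior_sample` from [abc_reject()].
#' @param model model name or spec (for the prior ranges); defaults to the
#'   sample's model.
#' @return the sample with an `adjusted` parameter matrix.
#' @export
regression_adjust <- function(sample, model = sample$model) {
  b <- if (is.matrix(model)) model else prior_bounds(model_spec(model))
  p <- sample$params
  if (nrow(p) < ncol(sample$stats) + 2)
    stop("too few accepted draws for the local-linear regression")
  sc <- sample$scales
  keep <- which(sc > 0 & is.finite(sc))
  X <- sweep(sample$stats[, keep, drop = FALSE], 2, sample$obs[keep])
  X <- sweep(X, 2, sc[keep], "/")
  eps <- 1e-8 * (b["hi", ] - b["lo", ])
  adj <- p
  ok <- TRUE
  for (j in seq_len(ncol(p))) {
    y <- log(p[, j] + eps[j])
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), y, sample$weights),
                    error = function(e) NULL)
    # aliased (pivoted-out) statistic columns are harmless: the adjustment
    # only needs the intercept and the residuals
    if (is.null(fit) || is.na(fit$coefficients[1])) { ok <- FALSE; break }
    yadj <- fit$coefficients[1] + fit$residuals
    adj[, j] <- exp(yadj) - eps[j]
  }
  if (!ok) {
    warning("singular local-linear design: returning the unadjusted rejection sample")
    sample$adjusted <- p
    return(sample)
  }
  outside <- sum(sweep(adj, 2, b["hi", ], ">") | sweep(adj, 2, b["lo", ], "<"))
  sample$adjusted <- adj
  attr(sample$adjusted, "n_outside_prior") <- outside
  sample
}

#' Summarize an ABC posterior sample
#'
#' Point estimate = mode of a weighted Gaussian kernel density (Silverman's
#' rule bandwidth, 512-point grid spanning the draws); interval = weighted
#' 5 and 95 percentiles. Uses the regression-adjusted draws when present.
#'
#' @param sample a `posterior_sample`.
#' @return data.frame with one row per parameter: `mode`, `q05`, `q95`.
#' @export
summarize_posterior <- function(sample) {
  p <- if (!is.null(sample$adjusted)) sample$adjusted else sample$params
  if (nrow(p) < 10) stop("need at least 10 posterior draws")
  w <- sample$weights / sum(sample$weights)
  out <- data.frame(param = colnames(p), mode = NA_real_, q05 = NA_real_,
                    q95 = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(p))) {
    x <- p[, j]
    if (max(x) - min(x) < .Machine$double.eps * max(1, abs(max(x)))) {
      out$mode[j] <- x[1]; out$q05[j] <- x[1]; out$q95[j] <- x[1]
      next
    }
    den <- stats::density(x, weights = w, bw = stats::bw.nrd0(x), n = 512,
                          from = min(x), to = max(x))
    out$mode[j] <- den$x[which.max(den$y)]
    qq <- weighted_quantile(x, w, c(0.05, 0.95))
    out$q05[j] <- qq[1]; out$q95[j] <- qq[2]
  }
  out
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}

#' ABC model choice with Bayes factors
#'
#' Pools the reference tables of the candidate models, accepts the
#' `tolerance` quantile of the pooled standardized distances, and estimates
#' posterior model probabilities either by the acceptance frequencies
#' (`method = "rejection"`) or, by default, by a weighted multinomial
#' logistic regression of the model label on the summary statistics within
#' the accepted pool, evaluated at the observation (`method =
#' "mnlogistic"`). Bayes factors are ratios of posterior model
#' probabilities (equal prior weight on models), and a Bayes factor of at
#' least 3 is conventionally taken as sufficient to reject the disfavoured
#' model.
#'
#' @param obs observed summary-statistic vector.
#' @param tables named list (>= 2) of `ref_table`s with identical
#'   statistic sets and simulation counts.
#' @param tolerance accepted fraction of the pooled table.
#' @param method `"mnlogistic"` (default) or `"rejection"`.
#' @return a `model_choice_result`: `prob` (posterior probabilities summing
#'   to one), `bf` (Bayes-factor matrix, `bf[i, j]` favouring model i over
#'   model j), the rejection-count probabilities, and acceptance counts.
#' @export
model_choice <- function(obs, tables, tolerance = 0.01,
                         method = c("mnlogistic", "rejection")) {
  method <- match.arg(method)
  if (length(tables) < 2) stop("need at least two models")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- vapply(tables, `[[`, character(1), "model")
  nsims <- vapply(tables, `[[`, numeric(1), "nsims")
  if (length(unique(nsims)) != 1)
    stop("reference tables must have equal simulation counts (equal prior weight)")
  stats_all <- do.call(rbind, lapply(tables, `[[`, "stats"))
  label <- factor(rep(names(tables), times = nsims), levels = names(tables))
  obs <- align_obs(obs, colnames(stats_all))

  sc <- stat_scales(stats_all)
  keep <- which(sc > 0 & is.finite(sc))
  if (length(keep) < length(sc))
    warning("dropping constant statistic(s) from the distance")
  z <- sweep(stats_all[, keep, drop = FALSE], 2, sc[keep], "/")
  zo <- obs[keep] / sc[keep]
  d <- sqrt(rowSums(sweep(z, 2, zo)^2))
  nacc <- ceiling(tolerance * nrow(stats_all))
  ord <- order(d)[seq_len(nacc)]
  dmax <- d[ord[nacc]]
  w <- if (dmax > 0) 1 - (d[ord] / dmax)^2 else rep(1, nacc)
  if (all(w == 0)) w <- rep(1, nacc)
  lab_acc <- label[ord]

  counts <- table(lab_acc)
  p_rej <- as.numeric(counts) / nacc
  names(p_rej) <- names(counts)
  if (any(p_rej == 0)) {
    warning("model(s) with zero accepted simulations: flooring probabilities")
    p_rej[p_rej == 0] <- 1 / (nacc + length(tables))
    p_rej <- p_rej / sum(p_rej)
  }

  prob <- p_rej
  if (method == "mnlogistic") {
    prob <- tryCatch({
      df <- as.data.frame(sweep(z[ord, , drop = FALSE], 2, zo))
      names(df) <- paste0("s", seq_along(df))
      df$.label <- lab_acc
      fit <- nnet::multinom(.label ~ ., data = df, weights = w, trace = FALSE,
                            maxit = 500)
      nd <- as.data.frame(matrix(0, 1, ncol(df) - 1))
      names(nd) <- setdiff(names(df), ".label")
      pr <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(pr)) && length(pr) == 1) {
        # two-model fit returns P(second level)
        pr <- c(1 - pr, pr)
        names(pr) <- levels(lab_acc)
      }
      full <- stats::setNames(rep(0, length(tables)), names(tables))
      full[levels(droplevels(lab_acc))] <- pr[levels(droplevels(lab_acc))]
      if (any(full == 0)) full[full == 0] <- 1 / (nacc + length(tables))
      full / sum(full)
    }, error = function(e) {
      warning("multinomial regression failed (", conditionMessage(e),
              "): falling back to rejection counts")
      p_rej
    })
  }
  prob <- prob[names(tables)]
  prob[is.na(prob)] <- 1 / (nacc + length(tables))
  prob <- prob / sum(prob)
  bf <- outer(prob, prob, "/")
  structure(list(prob = prob, bf = bf, method = method,
                 rejection_prob = p_rej[names(tables)],
                 accepted = as.numeric(counts)[match(names(tables), names(counts))],
                 tolerance = tolerance, n_accept = nacc),
            class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, digits = 4, ...) {
  cat("<model_choice_result> method ", x$method, ", tolerance ", x$tolerance,
      "\n  posterior probabilities:\n", sep = "")
  print(round(x$prob, digits))
  cat("  Bayes factors (row model vs column model):\n")
  print(round(x$bf, digits))
  invisible(x)
}
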