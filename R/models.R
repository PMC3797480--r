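#' Registry of demographic models and their uniform priors
#'
#' Four within-species models describe a single population of Taiwan spruce:
#' `constant` (null, parameters theta and rho only), `bottleneck`
#' (instantaneous reduction to alpha*N at time t0, lasting a fixed 0.2
#' coalescent time units), `decline` (present size alpha*N, recovering to N
#' at time t backwards) and `structure2` (two demes of size N exchanging
#' migrants at symmetric scaled rate M, the sample split evenly between
#' them). Five between-species models describe the split of the focal
#' species (deme 1, P. morrisonicola) from its mainland relative (deme 2,
#' P. wilsonii) at time t1, with instant-change (IC) and delayed-decline (D)
#' size scalings and, for `IM`, post-split symmetric migration. All sizes are
#' relative to the reference (ancestral) size N, all times in units of 4N
#' generations, and theta/rho are shared across species within a locus.
#'
#' Priors are uniform: theta ~ U(0, 0.01) per bp, rho ~ U(0, 0.02) per bp,
#' times ~ U(0, 1.5), size scalings alpha ~ U(0, 1.5) and M ~ U(0.05, 1)
#' for the structured model. Split models with both a divergence time t1 and
#' a later decline time t0 enforce t0 < t1 by resampling. The `IM` model uses
#' a wider mutation-rate bound suited to the ancestral population
#' (theta ~ U(0, 0.015))
#' and a log-uniform migration rate, ln M ~ U(-5, 1).
#'
#' @return named list of model specifications.
#' @export
model_registry <- function() {
  U <- function(lo, hi) c(lo = lo, hi = hi)
  th <- U(0, 0.01); rh <- U(0, 0.02); al <- U(0, 1.5); tm <- U(0, 1.5)
  reg <- list(
    constant = list(
      kind = "within", params = list(theta = th, rho = rh),
      build = function(p) list(sizes = 1, mig = 0, events = no_events())),
    bottleneck = list(
      kind = "within", params = list(theta = th, rho = rh, alpha = al, t0 = tm),
      build = function(p) list(sizes = 1, mig = 0,
                               events = rbind(ev(p[["t0"]], "size", 1, p[["alpha"]]),
                                              ev(p[["t0"]] + 0.2, "size", 1, 1)))),
    decline = list(
      kind = "within", params = list(theta = th, rho = rh, alpha = al, t = tm),
      build = function(p) list(sizes = p[["alpha"]], mig = 0,
                               events = ev(p[["t"]], "size", 1, 1))),
    structure2 = list(
      kind = "within", params = list(theta = th, rho = rh, M = U(0.05, 1)),
      split_samples = TRUE,
      build = function(p) list(sizes = c(1, 1), mig = p[["M"]], events = no_events())),
    split_ICm = list(
      kind = "between", params = list(theta = th, rho = rh, alpha_m = al, t1 = tm),
      build = function(p) list(sizes = c(p[["alpha_m"]], 1), mig = 0,
                               events = rbind(ev(p[["t1"]], "join", 1, 2),
                                              ev(p[["t1"]], "size", 2, 1)))),
    split_Dm = list(
      kind = "between",
      params = list(theta = th, rho = rh, alpha_m = al, t1 = tm, t0 = tm),
      constraint = function(p) p[["t0"]] < p[["t1"]],
      build = function(p) list(sizes = c(p[["alpha_m"]], 1), mig = 0,
                               events = rbind(ev(p[["t0"]], "size", 1, 1),
                                              ev(p[["t1"]], "join", 1, 2),
                                              ev(p[["t1"]], "size", 2, 1)))),
    split_ICmw = list(
      kind = "between",
      params = list(theta = th, rho = rh, alpha_m = al, alpha_w = al, t1 = tm),
      build = function(p) list(sizes = c(p[["alpha_m"]], p[["alpha_w"]]), mig = 0,
                               events = rbind(ev(p[["t1"]], "join", 1, 2),
                                              ev(p[["t1"]], "size", 2, 1)))),
    split_ICmw_Dm = list(
      kind = "between",
      params = list(theta = th, rho = rh, alpha_m0 = al, alpha_m1 = al,
                    alpha_w = al, t1 = tm, t0 = tm),
      constraint = function(p) p[["t0"]] < p[["t1"]],
      build = function(p) list(sizes = c(p[["alpha_m0"]], p[["alpha_w"]]), mig = 0,
                               events = rbind(ev(p[["t0"]], "size", 1, p[["alpha_m1"]]),
                                              ev(p[["t1"]], "join", 1, 2),
                                              ev(p[["t1"]], "size", 2, 1)))),
    IM = list(
      kind = "between",
      params = list(theta = U(0, 0.015), rho = rh, log_M = U(-5, 1), t1 = tm),
      build = function(p) list(sizes = c(1, 1), mig = exp(p[["log_M"]]),
                               events = rbind(ev(p[["t1"]], "join", 1, 2),
                                              ev(p[["t1"]], "mig", 1, 0))))
  )
  for (nm in names(reg)) reg[[nm]]$name <- nm
  reg
}

no_events <- function() matrix(numeric(0), 0, 4)

# one demographic event row: time, code (1 size / 2 join / 3 migration),
# 1-based deme, value
ev <- function(time, what, deme, x) {
  code <- match(what, c("size", "join", "mig"))
  matrix(c(time, code, deme - 1, if (what == "join") x - 1 else x), 1, 4)
}

#' Look up one model specification
#'
#' @param model model name or a specification returned by [model_registry()].
#' @export
model_spec <- function(model) {
  if (is.list(model) && !is.null(model$build)) return(model)
  reg <- model_registry()
  if (!model %in% names(reg))
    stop("unknown model '", model, "'; available: ", paste(names(reg), collapse = ", "))
  reg[[model]]
}

#' Prior bounds of a model
#'
#' @param model model name or spec.
#' @return 2 x p matrix with rows `lo`, `hi`.
#' @export
prior_bounds <- function(model) {
  spec <- model_spec(model)
  vapply(spec$params, identity, numeric(2))
}

#' Draw parameter vectors from a model's priors
#'
#' Independent uniform draws within each parameter's bounds; draws violating
#' a model constraint (t0 < t1 in the delayed-decline split models) are
#' resampled, and the number of rejected draws is recorded as an attribute.
#'
#' @param model model name or spec.
#' @param n number of draws.
#' @param seed optional integer seed (isolated from the caller's RNG state).
#' @return n x p matrix of draws, one column per parameter.
#' @export
draw_prior <- function(model, n = 1, seed = NULL) {
  spec <- model_spec(model)
  b <- prior_bounds(spec)
  draw <- function(k) {
    m <- vapply(seq_len(ncol(b)),
                function(j) stats::runif(k, b["lo", j], b["hi", j]),
                numeric(k))
    if (k == 1) m <- matrix(m, 1)
    colnames(m) <- colnames(b)
    m
  }
  run <- function() {
    m <- draw(n)
    rejected <- 0L
    if (!is.null(spec$constraint)) {
      repeat {
        bad <- which(!apply(m, 1, spec$constraint))
        if (length(bad) == 0) break
        rejected <- rejected + length(bad)
        m[bad, ] <- draw(length(bad))[seq_along(bad), , drop = FALSE]
      }
    }
    structure(m, rejected = rejected)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Build the demography implied by one parameter draw
#'
#' Maps a parameter vector to the concrete demography consumed by the
#' simulator: initial relative deme sizes, symmetric migration rate, and a
#' time-sorted event table (size changes, backwards joins, migration-rate
#' changes).
#'
#' @param model model name or spec.
#' @param params named parameter vector (one row of [draw_prior()]).
#' @return a `demography` object; carries `theta` and `rho` for convenience.
#' @export
build_demography <- function(model, params) {
  spec <- model_spec(model)
  params <- unlist(params)[names(spec$params)]
  if (anyNA(params)) stop("missing parameters for model ", spec$name)
  b <- prior_bounds(spec)
  if (any(params < b["lo", ] - 1e-12) || any(params > b["hi", ] + 1e-12))
    stop("parameter draw outside prior bounds for model ", spec$name)
  if (!is.null(spec$constraint) && !spec$constraint(params))
    stop("draw violates model constraint (resample the prior)")
  g <- spec$build(params)
  evm <- g$events
  if (nrow(evm) > 1) evm <- evm[order(evm[, 1]), , drop = FALSE]
  structure(list(model = spec$name, kind = spec$kind, params = params,
                 theta = params[["theta"]], rho = params[["rho"]],
                 sizes = g$sizes, mig = g$mig, events = evm,
                 split_samples = isTRUE(spec$split_samples)),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography> model ", x$model, ": ", length(x$sizes), " deme(s), ",
      nrow(x$events), " event(s), M=", signif(x$mig, 3), "\n", sep = "")
  invisible(x)
}

# evaluate expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
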