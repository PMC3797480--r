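#' Simulate one locus under a demography
#'
#' Hudson-style ancestral recombination graph: lineages coalesce within
#' demes (pairwise rate 2/x for relative deme size x, time in units of 4N
#' generations), recombine at rate rho per bp times the ancestral span,
#' and migrate between demes at rate M/2; mutations arise at rate theta per
#' bp per unit branch length under the infinite-sites model, mapped onto L
#' discrete positions with collisions redrawn. The derived state is the
#' mutant, so simulated site tables are fully polarized.
#'
#' @param n haploid sample size (single-deme), or use `n1`/`n2`.
#' @param L locus length in bp.
#' @param demography a `demography` from [build_demography()], which carries
#'   theta and rho per bp.
#' @param seed integer seed; the locus stream is derived from it and
#'   `locus_name`, so loci simulated with distinct names are independent and
#'   insensitive to ordering.
#' @param locus_name label used both in the output and in seed derivation.
#' @param n1,n2 per-deme haploid sample sizes for two-deme demographies.
#' @return a `site_table` with all sites polarized, a `hap_counts`
#'   attribute, and attributes `mask` (per-site descendant bitmasks) and
#'   `tree_len_bp` (total branch length weighted by ancestral bp).
#' @export
simulate_locus <- function(n = NULL, L, demography, seed = 1,
                           locus_name = "locus", n1 = NULL, n2 = NULL) {
  if (is.null(n1)) {
    if (is.null(n)) stop("give n (single deme) or n1/n2")
    if (demography$split_samples) {
      n1 <- ceiling(n / 2); n2 <- floor(n / 2)
    } else if (length(demography$sizes) == 2) {
      stop("two-deme demography: give per-deme sample sizes n1 and n2")
    } else {
      n1 <- n; n2 <- 0
    }
  }
  if (is.null(n2)) n2 <- 0
  raw <- cpp_simulate_study(as.integer(n1), as.integer(n2), as.numeric(L),
                            as.character(locus_name), demography$theta,
                            demography$rho, as.numeric(demography$sizes),
                            demography$mig, demography$events,
                            as.numeric(seed), 0L)[[1]]
  wrap_sim_table(raw, locus_name)
}

#' Derive an independent seed from a master seed
#'
#' Counter-based seed splitting (splitmix64): deterministic, and distinct
#' counters give effectively independent simulation streams. Used to give
#' every reference-table row, pseudo-observed data set and locus its own
#' stream.
#'
#' @param seed master integer seed.
#' @param i stream counter.
#' @return an integer-valued seed below 2^31.
#' @export
derive_seed <- function(seed, i) cpp_mix_seed(seed, i) %% 2^31

wrap_sim_table <- function(raw, locus_name) {
  two <- raw$n1 > 0 && raw$n1 < raw$n
  tb <- site_table(locus_name, n = raw$n, L = raw$L, L_effective = raw$L,
                   pos = raw$pos, d = raw$d,
                   polarized = rep(TRUE, length(raw$pos)),
                   d1 = if (two) raw$d1 else NULL,
                   n1 = if (two) raw$n1 else NULL,
                   hap_counts = hap_counts_from_masks(raw$mask, raw$n))
  attr(tb, "mask") <- raw$mask
  attr(tb, "tree_len_bp") <- raw$tree_len_bp
  tb
}

# haplotype multiplicities implied by per-site descendant bitmasks
hap_counts_from_masks <- function(masks, n) {
  if (length(masks) == 0) return(n)
  key <- vapply(seq_len(n) - 1L,
                function(i) paste(floor(masks / 2^i) %% 2, collapse = ""),
                character(1))
  as.integer(table(key))
}

#' Simulate a whole multilocus study
#'
#' Simulates every locus of a study design independently (the loci are
#' physically unlinked) under one demography, with per-locus random streams
#' derived from the master seed and the locus names.
#'
#' @param design data.frame with columns `locus`, `n`, `L` and, for
#'   two-species designs, `n2` (see [study_design()]).
#' @param demography a `demography` object.
#' @param seed master integer seed.
#' @param output `"tables"` for a list of `site_table`s, `"stats"` for the
#'   ABC summary-statistic vector matching the demography's kind (9
#'   within-species statistics or 21 between-species statistics).
#' @return list of site tables, or a named statistic vector.
#' @export
simulate_study <- function(design, demography, seed = 1,
                           output = c("tables", "stats")) {
  output <- match.arg(output)
  ns <- split_design_samples(design, demography)
  mode <- if (output == "tables") 0L else if (demography$kind == "between") 2L else 1L
  res <- cpp_simulate_study(ns$n1, ns$n2, as.numeric(design$L),
                            as.character(design$locus), demography$theta,
                            demography$rho, as.numeric(demography$sizes),
                            demography$mig, demography$events,
                            as.numeric(seed), mode)
  if (output == "tables") {
    out <- lapply(seq_along(res), function(j) wrap_sim_table(res[[j]], design$locus[j]))
    names(out) <- design$locus
    out
  } else {
    stats::setNames(res, if (mode == 2L) BETWEEN_STAT_NAMES else WITHIN_STAT_NAMES)
  }
}

split_design_samples <- function(design, demography) {
  n <- as.integer(design$n)
  if (length(demography$sizes) == 1) {
    list(n1 = n, n2 = integer(length(n)))
  } else if (demography$split_samples) {
    list(n1 = as.integer(ceiling(n / 2)), n2 = as.integer(floor(n / 2)))
  } else {
    if (is.null(design$n2)) stop("two-species demography needs an n2 column in the design")
    list(n1 = n, n2 = as.integer(design$n2))
  }
}
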