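#' Harmonic-number constants of the Watterson and Tajima estimators
#'
#' @param n haploid sample size (>= 2).
#' @return named vector with `a1` = sum 1/i and `a2` = sum 1/i^2 for
#'   i = 1..n-1.
#' @export
harmonic_numbers <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  c(a1 = sum(1 / i), a2 = sum(1 / i^2))
}

#' Watterson's estimator of theta per bp
#'
#' @param S number of segregating sites.
#' @param n haploid sample size.
#' @param L sequence length in bp (effective length).
#' @return S / (a1 * L).
#' @export
watterson_theta <- function(S, n, L) {
  if (L <= 0) stop("L must be > 0")
  if (S < 0) stop("S must be >= 0")
  S / (harmonic_numbers(n)[["a1"]] * L)
}

#' Nucleotide diversity (pi) per bp from a site table
#'
#' Average number of pairwise differences per bp,
#' `sum over sites of 2 d (n-d) / (n (n-1))` divided by the effective length.
#' Equals the mean Hamming distance over all sequence pairs; invariant to
#' folding since `d(n-d)` is symmetric in `d` and `n-d`.
#'
#' @param table a `site_table`.
#' @return per-bp pi.
#' @export
nucleotide_diversity <- function(table) {
  pi_total(table) / table$L_effective
}

pi_total <- function(table) {
  n <- table$n; d <- table$sites$d
  sum(2 * d * (n - d) / (n * (n - 1)))
}

#' Fay and Wu's theta_H per bp
#'
#' High-frequency-weighted estimator `sum 2 d^2 / (n (n-1)) / L`. Requires
#' derived-allele orientation: unpolarized sites are skipped and the skipped
#' fraction recorded as an attribute. If no site is polarized the statistic
#' is undefined (`NA`).
#'
#' @param table a `site_table`.
#' @return per-bp theta_H with attribute `skipped_frac`.
#' @export
fay_wu_theta_h <- function(table) {
  pol <- table$sites$polarized
  if (table$S > 0 && !any(pol)) {
    return(structure(NA_real_, skipped_frac = 1))
  }
  d <- table$sites$d[pol]
  n <- table$n
  structure(sum(2 * d^2 / (n * (n - 1))) / table$L_effective,
            skipped_frac = if (table$S > 0) mean(!pol) else 0)
}

tajima_constants <- function(n) {
  h <- harmonic_numbers(n)
  a1 <- h[["a1"]]; a2 <- h[["a2"]]
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standard normalization contrasting mean pairwise differences with the
#' Watterson estimate. Undefined (`NA`) for monomorphic loci, matching the
#' convention of reporting "-" for loci without variation.
#'
#' @param S number of segregating sites.
#' @param pi_total total (per-locus, not per-bp) mean pairwise difference.
#' @param n haploid sample size.
#' @export
tajimas_d <- function(S, pi_total, n) {
  if (S < 1) return(NA_real_)
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  (pi_total - S / k$a1) / denom
}

#' Fay and Wu's H (non-normalized, per-locus total)
#'
#' `H = pi_total - thetaH_total`, both restricted to polarized sites.
#' Negative values indicate an excess of high-frequency derived variants.
#'
#' @param table a `site_table`.
#' @export
fay_wu_h <- function(table) {
  if (table$S < 1) return(NA_real_)
  pol <- table$sites$polarized
  if (!any(pol)) return(structure(NA_real_, skipped_frac = 1))
  d <- table$sites$d[pol]
  n <- table$n
  pit <- sum(2 * d * (n - d) / (n * (n - 1)))
  tht <- sum(2 * d^2 / (n * (n - 1)))
  structure(pit - tht, skipped_frac = mean(!pol))
}

#' Zeng's normalized H
#'
#' Normalized contrast between pi and the high-frequency estimator
#' `thetaL = sum(d) / (n-1)` following Zeng, Fu, Shi & Wu (2006), with
#' theta-hat estimated by S/a1 and theta-squared by S(S-1)/(a1^2+a2).
#' Restricted to polarized sites; undefined when none are.
#'
#' @param table a `site_table`.
#' @export
zeng_z <- function(table) {
  if (table$S < 1) return(NA_real_)
  pol <- table$sites$polarized
  if (!any(pol)) return(structure(NA_real_, skipped_frac = 1))
  d <- table$sites$d[pol]
  S <- length(d)
  n <- table$n
  h <- harmonic_numbers(n)
  a1 <- h[["a1"]]; a2 <- h[["a2"]]
  bn1 <- a2 + 1 / n^2   # sum_{i=1}^{n} 1/i^2
  th <- S / a1
  th2 <- S * (S - 1) / (a1^2 + a2)
  pit <- sum(2 * d * (n - d) / (n * (n - 1)))
  thL <- sum(d) / (n - 1)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * th2
  structure((pit - thL) / sqrt(v), skipped_frac = mean(!pol))
}

#' Haplotype diversity with small-sample correction
#'
#' `He = n/(n-1) * (1 - sum (c_i/n)^2)` for haplotype multiplicities `c_i`.
#'
#' @param counts haplotype multiplicities summing to `n`.
#' @param n haploid sample size (defaults to `sum(counts)`).
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  if (sum(counts) != n) stop("haplotype counts must sum to n")
  if (n < 2) stop("n must be >= 2")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Per-locus summary statistics
#'
#' Computes the full per-locus panel: Watterson's theta, pi and Fay & Wu's
#' theta_H per bp, Tajima's D, Fay & Wu's H (per-locus total), Zeng's
#' normalized H, and haplotype diversity. Statistics that are undefined for
#' a monomorphic locus are `NA` (rendered "-" in reports); per-bp estimators
#' use the effective post-filtering length.
#'
#' @param table a `site_table` (with a `hap_counts` attribute for He).
#' @return one-row data.frame.
#' @export
locus_stats <- function(table) {
  hap <- attr(table, "hap_counts")
  he <- if (table$S == 0) 0 else if (is.null(hap)) NA_real_ else haplotype_diversity(hap, table$n)
  data.frame(locus = table$locus_name, n = table$n, L = table$L,
             L_effective = table$L_effective, S = table$S,
             theta_w = watterson_theta(table$S, table$n, table$L_effective),
             pi = nucleotide_diversity(table),
             theta_h = as.numeric(fay_wu_theta_h(table)),
             D = tajimas_d(table$S, pi_total(table), table$n),
             H = as.numeric(fay_wu_h(table)),
             Z = as.numeric(zeng_z(table)),
             He = he,
             stringsAsFactors = FALSE)
}

#' Multilocus averages with the study's reporting conventions
#'
#' Diversity estimators (theta_W, pi, theta_H, He) are averaged over all loci
#' with monomorphic loci contributing 0; the SFS-shape statistics (D, H, Z)
#' are averaged over the loci where they are defined (polymorphic loci) only.
#' Standard deviations follow the same convention. Means over an empty set
#' are `NA` and flagged, never silently zero.
#'
#' @param stats data.frame of per-locus rows as returned by [locus_stats()].
#' @return list with `mean`, `sd`, `n_used` (named vectors) and the
#'   convention description.
#' @export
multilocus_summary <- function(stats) {
  if (nrow(stats) < 1) stop("need at least one locus")
  all_loci <- c("theta_w", "pi", "theta_h", "He")
  poly_only <- c("D", "H", "Z")
  mean_ <- sd_ <- n_used <- stats::setNames(numeric(0), character(0))
  for (v in all_loci) {
    x <- stats[[v]]
    x[is.na(x)] <- 0   # monomorphic loci contribute 0 to diversity averages
    mean_[v] <- mean(x)
    sd_[v] <- if (length(x) > 1) stats::sd(x) else NA_real_
    n_used[v] <- length(x)
  }
  for (v in poly_only) {
    x <- stats[[v]][!is.na(stats[[v]])]
    mean_[v] <- if (length(x) > 0) mean(x) else NA_real_
    sd_[v] <- if (length(x) > 1) stats::sd(x) else NA_real_
    n_used[v] <- length(x)
  }
  list(mean = mean_, sd = sd_, n_used = n_used,
       convention = "theta_w/pi/theta_h/He over all loci (monomorphic = 0); D/H/Z over polymorphic loci")
}

#' Simulation-based neutrality p-value for Tajima's D or Fay & Wu's H
#'
#' Simulates constant-size, no-recombination coalescent genealogies
#' conditional on the observed number of segregating sites (S mutations
#' placed on branches proportionally to length), computes the chosen
#' statistic for each replicate, and returns the tail probability in the
#' direction of the observed value: the lower tail for negative observations
#' and the upper tail for positive ones.
#'
#' @param stat "D" (Tajima's D) or "H" (Fay & Wu's H, per-locus total).
#' @param observed observed value of the statistic.
#' @param n haploid sample size.
#' @param S number of segregating sites (>= 1).
#' @param reps number of coalescent replicates (default 1e4; fewer than 100
#'   triggers a warning as the p-value is then unstable).
#' @param seed integer seed for the simulation stream.
#' @return the Monte-Carlo tail probability.
#' @export
neutrality_pvalue <- function(stat = c("D", "H"), observed, n, S,
                              reps = 10000, seed = 1) {
  stat <- match.arg(stat)
  if (S < 1) stop("S must be >= 1 for a defined statistic")
  if (reps < 100) warning("fewer than 100 replicates: p-value is unstable")
  sims <- cpp_fixed_s_reps(n, S, reps, seed)[, if (stat == "D") 1 else 2]
  if (observed < 0) mean(sims <= observed) else mean(sims >= observed)
}

# names of the within-species ABC summary-statistic vector
WITHIN_STAT_NAMES <- c("thW_mean", "thW_sd", "pi_mean", "pi_sd",
                       "He_mean", "He_sd", "D_mean", "D_sd", "prop_mono")

BETWEEN_STAT_NAMES <- c("S1_mean", "S1_sd", "S2_mean", "S2_sd", "Ss_mean",
                        "Ss_sd", "Sf_mean", "Sf_sd", "pi1_mean", "pi1_sd",
                        "pi2_mean", "pi2_sd", "fst_mean", "fst_sd",
                        "D1_mean", "D1_sd", "S1_tot", "S2_tot", "Ss_tot",
                        "Sf_tot", "nloc_Sf")

#' Within-species ABC summary statistics for a set of loci
#'
#' The 9-statistic vector used for model choice and parameter estimation:
#' across-locus mean and standard deviation of Watterson's theta, pi,
#' haplotype diversity and Tajima's D, plus the proportion of monomorphic
#' loci. For this vector Tajima's D of a monomorphic locus enters as 0 (the
#' proportion of monomorphic loci acts as the companion indicator), keeping
#' the vector width constant across simulated data sets.
#'
#' @param tables list of `site_table` objects (with `hap_counts`).
#' @return named numeric vector of length 9.
#' @export
abc_stats_within <- function(tables) {
  thw <- pw <- he <- dd <- numeric(length(tables))
  mono <- logical(length(tables))
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    thw[i] <- watterson_theta(tb$S, tb$n, tb$L_effective)
    pw[i] <- nucleotide_diversity(tb)
    hap <- attr(tb, "hap_counts")
    he[i] <- if (tb$S == 0) 0 else haplotype_diversity(hap, tb$n)
    d <- tajimas_d(tb$S, pi_total(tb), tb$n)
    dd[i] <- if (is.na(d)) 0 else d
    mono[i] <- tb$S == 0
  }
  stats::setNames(c(mean(thw), stats::sd(thw), mean(pw), stats::sd(pw),
                    mean(he), stats::sd(he), mean(dd), stats::sd(dd),
                    mean(mono)), WITHIN_STAT_NAMES)
}

#' Between-species ABC summary statistics
#'
#' Wakeley-Hey style summaries of the joint site frequency spectrum of two
#' species plus Tajima's D within the first (focal) species: across-locus
#' mean and sd of the exclusive polymorphism counts S1 and S2, shared
#' polymorphisms Ss, fixed differences Sf, per-bp pi within each species,
#' Hudson's FST (1 - mean within-species pi / between-species pi) and focal
#' D; then study-wide totals of S1/S2/Ss/Sf and the number of loci carrying
#' fixed differences (21 statistics).
#'
#' @param tables list of two-deme `site_table` objects carrying `d1` and
#'   `n1`.
#' @return named numeric vector of length 21.
#' @export
abc_stats_between <- function(tables) {
  k <- length(tables)
  s1 <- s2 <- ss <- sf <- p1 <- p2 <- fst <- d1s <- numeric(k)
  for (i in seq_len(k)) {
    tb <- tables[[i]]
    if (is.null(tb$sites$d1) || is.null(tb$n1)) stop("two-deme site table required")
    n1 <- tb$n1; n2 <- tb$n - n1
    dd1 <- tb$sites$d1; dd2 <- tb$sites$d - dd1
    po1 <- dd1 > 0 & dd1 < n1
    po2 <- dd2 > 0 & dd2 < n2
    s1[i] <- sum(po1 & !po2); s2[i] <- sum(po2 & !po1); ss[i] <- sum(po1 & po2)
    sf[i] <- sum((dd1 == 0 & dd2 == n2) | (dd1 == n1 & dd2 == 0))
    pi1 <- sum(2 * dd1 * (n1 - dd1) / (n1 * (n1 - 1)))
    pi2 <- sum(2 * dd2 * (n2 - dd2) / (n2 * (n2 - 1)))
    pib <- sum((dd1 * (n2 - dd2) + dd2 * (n1 - dd1)) / (n1 * n2))
    p1[i] <- pi1 / tb$L_effective; p2[i] <- pi2 / tb$L_effective
    fst[i] <- if (pib > 0) 1 - 0.5 * (pi1 + pi2) / pib else 0
    pt1 <- sum(2 * dd1[po1] * (n1 - dd1[po1]) / (n1 * (n1 - 1)))
    d1 <- tajimas_d(sum(po1), pt1, n1)
    d1s[i] <- if (is.na(d1)) 0 else d1
  }
  stats::setNames(c(mean(s1), stats::sd(s1), mean(s2), stats::sd(s2),
                    mean(ss), stats::sd(ss), mean(sf), stats::sd(sf),
                    mean(p1), stats::sd(p1), mean(p2), stats::sd(p2),
                    mean(fst), stats::sd(fst), mean(d1s), stats::sd(d1s),
                    sum(s1), sum(s2), sum(ss), sum(sf), sum(sf > 0)),
                  BETWEEN_STAT_NAMES)
}
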