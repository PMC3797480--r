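mk_table <- function(n, d, L, hap = NULL, pol = TRUE) {
  site_table("toy", n = n, L = L, pos = seq_along(d) - 1L, d = d,
             polarized = rep(pol, length(d)), hap_counts = hap)
}

test_that("harmonic constants match direct summation", {
  expect_equal(harmonic_numbers(2), c(a1 = 1, a2 = 1))
  expect_equal(harmonic_numbers(8)[["a1"]], sum(1 / (1:7)))
  expect_equal(harmonic_numbers(15)[["a1"]], sum(1 / (1:14)))
  expect_error(harmonic_numbers(1), "n must be")
})

test_that("Watterson's theta reproduces the printed per-locus values", {
  expect_equal(round(watterson_theta(8, 8, 604), 5), 0.00511)
  expect_equal(round(watterson_theta(8, 12, 468), 5), 0.00566)
  expect_equal(round(watterson_theta(1, 15, 445), 5), 0.00069)
  expect_equal(watterson_theta(0, 9, 1000), 0)
  expect_error(watterson_theta(1, 5, 0), "L must be")
})

test_that("single-site statistics reproduce the PCH locus exactly", {
  # n=10, one site at derived count 3, L=605
  tb <- mk_table(10, 3L, 605, hap = c(3L, 7L))
  expect_equal(round(nucleotide_diversity(tb), 5), 0.00077)
  expect_equal(round(as.numeric(fay_wu_theta_h(tb)), 5), 0.00033)
  expect_equal(round(tajimas_d(1, 2 * 3 * 7 / 90, 10), 4), 0.8198)
  expect_equal(round(as.numeric(fay_wu_h(tb)), 4), 0.2667)
  expect_equal(round(as.numeric(zeng_z(tb)), 3), 0.583)
})

test_that("m002's printed D, H and Z follow from n=9, one site at d=7", {
  tb <- mk_table(9, 7L, 518, hap = c(2L, 7L))
  st <- locus_stats(tb)
  expect_equal(round(st$D, 4), 0.1565)
  expect_equal(round(st$H, 4), -0.9722)
  expect_equal(round(st$Z, 4), -2.0986)
  expect_equal(round(st$He, 4), 0.3889)
})

test_that("pi equals the all-pairs Hamming average on random tables", {
  set.seed(5)
  demo <- build_demography("constant", c(theta = 0.008, rho = 0.004))
  for (r in 1:15) {
    tb <- simulate_locus(n = sample(4:12, 1), L = 300, demo, seed = 100 + r)
    hm <- oracle_hap_matrix(tb)
    expect_equal(nucleotide_diversity(tb) * tb$L_effective, oracle_pi_pairs(hm))
    # theta_H by direct summation
    expect_equal(as.numeric(fay_wu_theta_h(tb)) * tb$L_effective,
                 sum(2 * tb$sites$d^2 / (tb$n * (tb$n - 1))))
  }
})

test_that("Tajima's D and Zeng's Z match independent formula transcriptions", {
  d1 <- c(1L, 1L, 2L, 5L)
  pit <- sum(2 * d1 * (6 - d1) / 30)
  expect_equal(tajimas_d(4, pit, 6), oracle_tajd(6, d1))
  # numerator zero => D = 0
  a1 <- harmonic_numbers(12)[["a1"]]
  expect_equal(tajimas_d(5, 5 / a1, 12), 0)
  set.seed(9)
  for (r in 1:10) {
    n <- sample(c(6, 8, 11), 1)
    d <- sample(seq_len(n - 1), sample(2:7, 1), replace = TRUE)
    tb <- mk_table(n, d, 500)
    expect_equal(tajimas_d(tb$S, pi_total <- sum(2 * d * (n - d) / (n * (n - 1))), n),
                 oracle_tajd(n, d))
    expect_equal(as.numeric(zeng_z(tb)), oracle_zengz(n, d))
  }
})

test_that("H vanishes when the polarized spectrum balances pi against theta_H", {
  # d and n-d contributions symmetric: pi_total == thetaH_total at d = n/2...
  # use the identity H = sum 2d(n-2d)/(n(n-1)): zero when every site has d = n/2
  tb <- mk_table(8, c(4L, 4L), 100)
  expect_equal(as.numeric(fay_wu_h(tb)), 0)
  # singleton-only spectrum with large n: theta_H ~ 0 and far below theta_W
  tb2 <- mk_table(40, rep(1L, 6), 1000)
  expect_lt(as.numeric(fay_wu_theta_h(tb2)), watterson_theta(6, 40, 1000))
})

test_that("haplotype diversity matches the printed sb62 and m002 values", {
  expect_equal(round(haplotype_diversity(c(3, 10)), 4), 0.3846)
  expect_equal(round(haplotype_diversity(c(2, 7)), 4), 0.3889)
  expect_equal(haplotype_diversity(c(9), 9), 0)
  expect_error(haplotype_diversity(c(3, 3), 5), "sum to n")
})

test_that("statistics are invariant under permutation of sequences", {
  set.seed(12)
  demo <- build_demography("constant", c(theta = 0.009, rho = 0))
  tb <- simulate_locus(n = 8, L = 400, demo, seed = 5)
  hm <- oracle_hap_matrix(tb)
  for (r in 1:5) {
    hmp <- hm[sample(nrow(hm)), , drop = FALSE]
    d <- colSums(hmp)
    expect_equal(sort(d), sort(tb$sites$d))
  }
})

test_that("monomorphic loci yield zero or flagged-undefined statistics, never NaN", {
  tb <- mk_table(10, integer(0), 500, hap = 10L)
  st <- locus_stats(tb)
  expect_equal(st$theta_w, 0)
  expect_equal(st$pi, 0)
  expect_equal(st$He, 0)
  expect_true(is.na(st$D) && is.na(st$H) && is.na(st$Z))
  expect_false(any(is.nan(unlist(st[, c("theta_w", "pi", "theta_h", "He")]))))
})

test_that("multilocus averages follow the all-loci / polymorphic-only conventions", {
  o <- observed_study_stats()
  rows <- lapply(1:15, function(i) {
    data.frame(locus = paste0("l", i), n = 10, L = 600, L_effective = 600,
               S = as.integer(o$thw[i] > 0), theta_w = o$thw[i], pi = o$pi[i],
               theta_h = NA, D = NA_real_, H = NA, Z = NA, He = o$he[i])
  })
  df <- do.call(rbind, rows)
  df$D[df$theta_w > 0] <- o$d_poly
  ms <- multilocus_summary(df)
  expect_equal(round(ms$mean[["pi"]], 5), 0.00146)
  expect_equal(round(ms$mean[["theta_w"]], 5), 0.00147)
  expect_equal(round(ms$mean[["D"]], 4), 0.2805)
  expect_equal(ms$n_used[["D"]], 8)
  expect_equal(ms$n_used[["pi"]], 15)
  # one locus: mean = that locus, sd flagged NA
  one <- multilocus_summary(df[1, ])
  expect_equal(one$mean[["pi"]], df$pi[1])
  expect_true(is.na(one$sd[["pi"]]))
  # all-monomorphic input: D average undefined and flagged
  mono <- df[df$S == 0, ]
  msm <- multilocus_summary(mono)
  expect_true(is.na(msm$mean[["D"]]))
  expect_equal(msm$n_used[["D"]], 0)
})

test_that("the within-species ABC vector matches its C++ fast path", {
  des <- study_design("within")
  for (m in c("constant", "decline", "bottleneck", "structure2")) {
    pars <- draw_prior(m, 1, seed = 3)[1, ]
    demo <- build_demography(m, pars)
    tabs <- simulate_study(des, demo, seed = 99, output = "tables")
    fast <- simulate_study(des, demo, seed = 99, output = "stats")
    slow <- abc_stats_within(tabs)
    expect_equal(slow, fast, tolerance = 1e-12)
  }
})

test_that("the between-species ABC vector matches its C++ fast path", {
  des <- study_design("between")
  pars <- draw_prior("split_Dm", 1, seed = 4)[1, ]
  demo <- build_demography("split_Dm", pars)
  tabs <- simulate_study(des, demo, seed = 17, output = "tables")
  fast <- simulate_study(des, demo, seed = 17, output = "stats")
  slow <- abc_stats_between(tabs)
  expect_equal(slow, fast, tolerance = 1e-12)
})
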