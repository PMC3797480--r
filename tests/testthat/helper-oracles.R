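# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: brute-force pairwise scans, direct
# transcriptions of the estimator formulas, and a plain pure-R Kingman
# coalescent.

# 0/1 haplotype matrix (samples x sites) recovered from a simulated site
# table's descendant bitmasks
oracle_hap_matrix <- function(tb) {
  masks <- attr(tb, "mask")
  n <- tb$n
  if (length(masks) == 0) return(matrix(0L, n, 0))
  vapply(masks, function(m) as.integer(floor(m / 2^(seq_len(n) - 1)) %% 2),
         integer(n))
}

# mean pairwise Hamming distance over all C(n,2) sequence pairs
oracle_pi_pairs <- function(hm) {
  n <- nrow(hm)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + sum(hm[i, ] != hm[j, ])
  tot / choose(n, 2)
}

# direct transcription of the Tajima (1989) normalization, written
# independently of the package implementation
oracle_tajd <- function(n, dvec) {
  S <- length(dvec)
  aa <- sum(1 / seq_len(n - 1))
  bb <- sum(1 / seq_len(n - 1)^2)
  pihat <- sum(dvec * (n - dvec)) * 2 / (n * (n - 1))
  v1 <- ((n + 1) / (3 * (n - 1)) - 1 / aa) / aa
  v2 <- (2 * (n^2 + n + 3) / (9 * n * (n - 1)) - (n + 2) / (aa * n) + bb / aa^2) /
    (aa^2 + bb)
  (pihat - S / aa) / sqrt(v1 * S + v2 * S * (S - 1))
}

# independent transcription of the Zeng et al. (2006) normalized H
oracle_zengz <- function(n, dvec) {
  S <- length(dvec)
  aa <- sum(1 / seq_len(n - 1))
  bb <- sum(1 / seq_len(n - 1)^2)
  bb1 <- bb + 1 / n^2
  th <- S / aa
  thsq <- S * (S - 1) / (aa^2 + bb)
  pihat <- sum(dvec * (n - dvec)) * 2 / (n * (n - 1))
  thL <- sum(dvec) / (n - 1)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bb1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * thsq
  (pihat - thL) / sqrt(v)
}

# plain Kingman coalescent (constant size, no recombination): vector of S
# over replicates, with mutations Poisson(theta*L * total branch length),
# pairwise coalescence rate 2 in units of 4N generations
oracle_kingman_S <- function(n, thetaL, reps) {
  ltot <- numeric(reps)
  for (k in n:2) ltot <- ltot + k * stats::rexp(reps, rate = k * (k - 1))
  stats::rpois(reps, thetaL * ltot)
}

# pure-R fixed-S replicates of (D, H): constant-size genealogy, S mutations
# placed on branches proportionally to length
oracle_fixed_s <- function(n, S, reps) {
  out <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    len <- numeric(n); nd <- rep(1L, n)
    blen <- numeric(0); bnd <- integer(0)
    k <- n
    while (k > 1) {
      tt <- stats::rexp(1, rate = k * (k - 1))
      len <- len + tt
      pair <- sample.int(k, 2)
      blen <- c(blen, len[pair]); bnd <- c(bnd, nd[pair])
      nd[pair[1]] <- sum(nd[pair]); len[pair[1]] <- 0
      nd <- nd[-pair[2]]; len <- len[-pair[2]]
      k <- k - 1L
    }
    d <- bnd[sample.int(length(blen), S, replace = TRUE, prob = blen)]
    pit <- sum(2 * d * (n - d) / (n * (n - 1)))
    tht <- sum(2 * d^2 / (n * (n - 1)))
    out[r, 1] <- oracle_tajd(n, d)
    out[r, 2] <- pit - tht
  }
  out
}

# write a FASTA file from named sequences, return the path
write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]]))),
             path)
  path
}

# Table-1-shaped observed per-locus values used by several tests
observed_study_stats <- function() {
  list(
    thw = c(0.00511, 0, 0, 0, 0.00058, 0, 0.00444, 0, 0.00069, 0, 0.00072,
            0.00362, 0, 0.00119, 0.00566),
    pi = c(0.00361, 0, 0, 0, 0.00077, 0, 0.00629, 0, 0.00094, 0, 0.00076,
           0.00519, 0, 0.00142, 0.00285),
    he = c(0.75, 0, 0, 0, 0.4667, 0, 0.7091, 0, 0.419, 0, 0.3889, 0.4615, 0,
           0.3846, 0.1667),
    d_poly = c(-1.4213, 0.8198, 1.6842, 0.7421, 0.1565, 1.7028, 0.5437, -1.9834))
}

# the 9-statistic observed vector under the package's ABC conventions
observed_abc_stats <- function() {
  o <- observed_study_stats()
  d0 <- c(-1.4213, 0, 0, 0, 0.8198, 0, 1.6842, 0, 0.7421, 0, 0.1565, 1.7028,
          0, 0.5437, -1.9834)
  c(thW_mean = mean(o$thw), thW_sd = sd(o$thw), pi_mean = mean(o$pi),
    pi_sd = sd(o$pi), He_mean = mean(o$he), He_sd = sd(o$he),
    D_mean = mean(d0), D_sd = sd(d0), prop_mono = 7 / 15)
}

# weighted empirical quantiles (left-continuous inverse)
oracle_weighted_q <- function(x, w, p) {
  o <- order(x); cw <- cumsum(w[o]) / sum(w)
  vapply(p, function(q) x[o][which(cw >= q)[1]], numeric(1))
}
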