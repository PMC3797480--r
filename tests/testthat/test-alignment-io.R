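test_that("FASTA alignments are parsed with order and case preserved", {
  p <- write_tmp_fasta(list(a = "acgt", b = "ACGA"))
  aln <- read_fasta_alignment(p, locus_name = "toy")
  expect_equal(aln$n, 2)
  expect_equal(aln$L, 4)
  expect_equal(aln$sample_ids, c("a", "b"))
  expect_equal(aln$seqs, c("ACGT", "ACGA"))

  bad <- write_tmp_fasta(list(a = "ACGT", b = "ACGTA"))
  expect_error(read_fasta_alignment(bad), "length mismatch")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta_alignment(empty))
})

test_that("an 8-sequence 604 bp file matches the 4cl locus configuration", {
  seqs <- stats::setNames(as.list(replicate(8, paste(rep("A", 604), collapse = ""))),
                          paste0("s", 1:8))
  aln <- read_fasta_alignment(write_tmp_fasta(seqs))
  expect_equal(aln$n, 8)
  expect_equal(aln$L, 604)
})

test_that("outgroup polarization distinguishes derived from minor alleles", {
  # singleton, outgroup carries the ancestral allele
  aln <- locus_alignment("l1", paste0("s", 1:4), c("AAAA", "AAAA", "AAAA", "GAAA"),
                         outgroup = "AAAA")
  tb <- polarize_sites(aln)
  expect_equal(tb$S, 1)
  expect_equal(tb$sites$d, 1)
  expect_true(tb$sites$polarized)

  # third-state outgroup: site kept folded
  aln <- locus_alignment("l2", paste0("s", 1:4), c("AAAA", "GAAA", "AAAA", "GAAA"),
                         outgroup = "CAAA")
  tb <- polarize_sites(aln)
  expect_equal(tb$S, 1)
  expect_equal(tb$sites$d, 2)
  expect_false(tb$sites$polarized)

  # derived = non-outgroup allele even when it is the majority
  aln <- locus_alignment("l3", paste0("s", 1:4), c("GAAA", "GAAA", "GAAA", "AAAA"),
                         outgroup = "AAAA")
  tb <- polarize_sites(aln)
  expect_equal(tb$sites$d, 3)
  expect_true(tb$sites$polarized)

  expect_error(polarize_sites(locus_alignment("l4", c("a", "b"), c("AC", "AG"),
                                              outgroup = "A")),
               "mismatch")
})

test_that("columns with ingroup missing data are excluded, matching a brute-force scan", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:10, 1); L <- 60
    m <- matrix(sample(c("A", "G"), n * L, replace = TRUE, prob = c(0.9, 0.1)), n, L)
    m[sample(length(m), 10)] <- "N"
    m[sample(length(m), 5)] <- "-"
    aln <- locus_alignment("r", paste0("s", seq_len(n)),
                           apply(m, 1, paste, collapse = ""),
                           outgroup = paste(rep("A", L), collapse = ""))
    tb <- polarize_sites(aln)
    # independent column-by-column scan
    bad <- apply(m, 2, function(col) any(col %in% c("N", "-")))
    seg <- !bad & apply(m, 2, function(col) length(unique(col)) == 2)
    expect_equal(tb$S, sum(seg))
    expect_equal(tb$L_effective, L - sum(bad))
    expect_equal(tb$sites$pos, which(seg) - 1L)
  }
})

test_that("polarization is idempotent and independent of sequence order", {
  set.seed(7)
  n <- 6; L <- 80
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                     prob = c(0.85, 0.05, 0.05, 0.05)), n, L)
  og <- paste(sample(c("A", "C"), L, replace = TRUE, prob = c(0.9, 0.1)), collapse = "")
  aln <- locus_alignment("p", paste0("s", 1:n), apply(m, 1, paste, collapse = ""),
                         outgroup = og)
  tb1 <- polarize_sites(aln)
  tb2 <- polarize_sites(aln)
  expect_identical(tb1$sites, tb2$sites)
  perm <- sample(n)
  tbp <- polarize_sites(locus_alignment("p", paste0("s", 1:n)[perm],
                                        apply(m, 1, paste, collapse = "")[perm],
                                        outgroup = og))
  expect_identical(tb1$sites, tbp$sites)
  # removing the outgroup folds counts but keeps S and positions
  tbn <- polarize_sites(locus_alignment("p", paste0("s", 1:n),
                                        apply(m, 1, paste, collapse = "")))
  expect_equal(tbn$S, tb1$S)
  expect_equal(tbn$sites$pos, tb1$sites$pos)
  expect_false(any(tbn$sites$polarized))
  expect_equal(tbn$sites$d, pmin(tb1$sites$d, n - tb1$sites$d))
})

test_that("greedy SNP thinning returns the canonical maximal prefix-greedy set", {
  expect_equal(thin_snps(integer(0), 50), integer(0))
  expect_equal(thin_snps(c(10, 40, 100, 140, 200), 50), c(10, 100, 200))
  x <- c(0, 3, 7, 20, 21, 60)
  expect_equal(thin_snps(x, 0), x)
  expect_error(thin_snps(c(5, 5, 10), 50), "strictly increasing")

  # enumeration oracle: greedy result is the prefix-greedy subset among all
  # feasible subsets (first element kept, each kept >= spacing from previous)
  set.seed(11)
  for (rep in 1:25) {
    pos <- sort(sample(0:300, sample(3:9, 1)))
    sp <- sample(c(10, 50, 120), 1)
    got <- thin_snps(pos, sp)
    subsets <- lapply(seq_len(2^length(pos)) - 1, function(b) pos[bitwAnd(b, 2^(seq_along(pos) - 1)) > 0])
    feas <- Filter(function(s) length(s) > 0 && s[1] == pos[1] &&
                     (length(s) == 1 || all(diff(s) >= sp)), subsets)
    # prefix-greedy: among feasible subsets, repeatedly the earliest next pick
    pick <- pos[1]; ref <- pos[1]
    for (p in pos[-1]) if (p - ref >= sp) { pick <- c(pick, p); ref <- p }
    expect_equal(got, pick)
    expect_true(list(got) %in% lapply(feas, identity) ||
                  any(vapply(feas, function(s) identical(s, got), logical(1))))
    if (length(got) > 1) expect_true(all(diff(got) >= sp))
  }
})

test_that("the exported genotype matrix thins per locus and codes missing as -9", {
  mk <- function(name, seqs, og) locus_alignment(name, paste0("i", seq_along(seqs)), seqs, og)
  base <- strrep("A", 150)
  seq_at <- function(pos, alt) {
    s <- strsplit(base, "")[[1]]
    s[pos + 1] <- alt
    paste(s, collapse = "")
  }
  # 3 SNPs at 10/40/100 -> thinned to 10/100 at spacing 50
  a1 <- mk("locA", c(seq_at(c(10, 40, 100), "G"), base, base), base)
  f <- tempfile()
  n1 <- export_genotype_matrix(list(a1), f, min_spacing = 50)
  expect_equal(as.numeric(n1), 2)
  m <- utils::read.table(f)
  expect_equal(ncol(m), 2 + 2)
  expect_equal(sort(unique(unlist(m[, 3:4]))), c(1, 3))  # A=1, G=3

  # positions reset per locus: two loci with close positions are never
  # thinned against each other
  a2 <- mk("locB", c(seq_at(2, "C"), base, base), base)
  n2 <- export_genotype_matrix(list(a1, a2), f, min_spacing = 50)
  expect_equal(as.numeric(n2), 3)

  # no segregating sites at all: warning and a valid empty matrix
  expect_warning(n3 <- export_genotype_matrix(list(mk("locC", c(base, base), base)), f),
                 "empty")
  expect_equal(as.numeric(n3), 0)
})
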