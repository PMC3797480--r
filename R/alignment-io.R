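#' Read a per-locus haploid FASTA alignment
#'
#' Reads one locus worth of pre-aligned haploid sequences (conifer
#' megagametophyte sequencing yields phase-known haploid data). All records
#' must have equal length; residues are upper-cased. Optionally one record is
#' set aside as the outgroup used for allele polarization.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @param locus_name name for the locus; defaults to the file name without
#'   extension.
#' @param outgroup_id optional record id to treat as the outgroup sequence
#'   rather than an ingroup sample.
#' @return a `locus_alignment`: list with `locus_name`, `sample_ids`, `seqs`
#'   (character vector of residue strings), `n`, `L` and `outgroup` (string or
#'   `NULL`).
#' @export
read_fasta_alignment <- function(path, locus_name = NULL, outgroup_id = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("FASTA format error: no records in ", path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (is.null(locus_name)) locus_name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                             basename(path), ignore.case = TRUE)
  og <- NULL
  if (!is.null(outgroup_id)) {
    hit <- which(ids == outgroup_id)
    if (length(hit) != 1) stop("outgroup id '", outgroup_id, "' not found exactly once")
    og <- unname(seqs[hit])
    seqs <- seqs[-hit]
    ids <- ids[-hit]
  }
  locus_alignment(locus_name, ids, unname(seqs), outgroup = og)
}

#' Construct a locus alignment object
#'
#' @param locus_name locus label.
#' @param sample_ids unique sample identifiers.
#' @param seqs character vector of equal-length residue strings over
#'   `A,C,G,T,N,-`.
#' @param outgroup optional outgroup residue string of the same length.
#' @return a `locus_alignment` object.
#' @export
locus_alignment <- function(locus_name, sample_ids, seqs, outgroup = NULL) {
  lens <- nchar(seqs)
  if (length(seqs) < 2) stop("alignment needs >= 2 sequences")
  if (length(unique(lens)) != 1)
    stop("length mismatch: sequences have unequal lengths (", paste(unique(lens), collapse = ", "), ")")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != length(seqs)) stop("one id per sequence required")
  L <- lens[1]
  if (!is.null(outgroup) && nchar(outgroup) != L)
    stop("outgroup length mismatch: ", nchar(outgroup), " vs alignment length ", L)
  structure(list(locus_name = locus_name, sample_ids = sample_ids,
                 seqs = toupper(seqs), n = length(seqs), L = L,
                 outgroup = if (is.null(outgroup)) NULL else toupper(outgroup)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_name, ": n=", x$n, ", L=", x$L,
      if (!is.null(x$outgroup)) ", outgroup present" else "", "\n", sep = "")
  invisible(x)
}

#' Extract and polarize segregating sites from an alignment
#'
#' Scans alignment columns and builds the per-locus site table that carries
#' the (un)folded site frequency spectrum. Columns where any ingroup sequence
#' has `N` or `-` are excluded entirely and the effective length reduced
#' (complete-case convention for haploid Sanger data). Tri-allelic ingroup
#' columns are excluded from the segregating-site count (the downstream
#' infinite-sites models cannot represent them) and counted in a diagnostic.
#' At biallelic columns the derived allele is identified from the outgroup
#' where possible; when the outgroup is absent, gapped or carries a third
#' state, the site is kept with its minor-allele count and flagged
#' unpolarized.
#'
#' @param aln a `locus_alignment`.
#' @return a `site_table`: list with `locus_name`, `n`, `L`, `L_effective`,
#'   `S`, `sites` (data.frame of 0-based `pos`, derived/minor count `d`,
#'   logical `polarized`), diagnostic counts, and a `hap_counts` attribute
#'   holding haplotype multiplicities over the retained segregating sites.
#' @export
polarize_sites <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  n <- aln$n; L <- aln$L
  og <- if (is.null(aln$outgroup)) NULL else strsplit(aln$outgroup, "")[[1]]

  missing_col <- colSums(m == "N" | m == "-") > 0
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(bases, function(b) colSums(m == b), numeric(L))  # L x 4
  nall <- rowSums(cnt > 0)

  keep <- !missing_col & nall == 2
  tri <- sum(!missing_col & nall > 2)
  pos <- integer(0); d <- integer(0); polar <- logical(0)
  for (j in which(keep)) {
    ab <- bases[cnt[j, ] > 0]
    ca <- cnt[j, ab[1]]; cb <- cnt[j, ab[2]]
    if (!is.null(og) && og[j] %in% ab) {
      derived <- setdiff(ab, og[j])
      d <- c(d, if (derived == ab[1]) ca else cb)
      polar <- c(polar, TRUE)
    } else {
      d <- c(d, min(ca, cb))
      polar <- c(polar, FALSE)
    }
    pos <- c(pos, j - 1L)
  }
  hap <- if (length(pos) > 0) {
    table(apply(m[, pos + 1L, drop = FALSE], 1, paste, collapse = ""))
  } else table(rep("ref", n))

  site_table(aln$locus_name, n = n, L = L,
             L_effective = L - sum(missing_col),
             pos = pos, d = d, polarized = polar,
             n_excluded_missing = sum(missing_col), n_triallelic = tri,
             hap_counts = as.integer(hap))
}

#' Construct a site table
#'
#' Low-level constructor for the per-locus carrier of segregating-site
#' frequencies; normally produced by [polarize_sites()] or [simulate_locus()].
#'
#' @param locus_name locus label.
#' @param n haploid sample size.
#' @param L alignment length in bp.
#' @param L_effective bp retained after site filtering.
#' @param pos 0-based positions, strictly increasing.
#' @param d derived (or minor, if unpolarized) allele counts, in `1..n-1`.
#' @param polarized logical flags per site.
#' @param n_excluded_missing,n_triallelic diagnostics.
#' @param hap_counts optional haplotype multiplicities (integer vector summing
#'   to `n`).
#' @param d1 optional derived counts within the first deme (two-species data).
#' @param n1 haploid sample size of the first deme, if two demes.
#' @export
site_table <- function(locus_name, n, L, L_effective = L, pos = integer(0),
                       d = integer(0), polarized = logical(0),
                       n_excluded_missing = 0L, n_triallelic = 0L,
                       hap_counts = NULL, d1 = NULL, n1 = NULL) {
  if (length(pos) != length(d) || length(d) != length(polarized))
    stop("pos, d, polarized must have equal length")
  if (length(pos) > 1 && any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  if (any(d < 1 | d > n - 1)) stop("derived counts must lie in 1..n-1")
  if (L_effective > L) stop("L_effective cannot exceed L")
  out <- structure(list(locus_name = locus_name, n = as.integer(n), L = L,
                        L_effective = L_effective, S = length(pos),
                        sites = data.frame(pos = as.integer(pos), d = as.integer(d),
                                           polarized = polarized),
                        n_excluded_missing = n_excluded_missing,
                        n_triallelic = n_triallelic, n1 = n1),
                   class = "site_table")
  if (!is.null(d1)) out$sites$d1 <- as.integer(d1)
  if (!is.null(hap_counts)) {
    if (sum(hap_counts) != n) stop("haplotype counts must sum to n")
    attr(out, "hap_counts") <- as.integer(hap_counts)
  }
  out
}

#' @export
print.site_table <- function(x, ...) {
  cat("<site_table> ", x$locus_name, ": n=", x$n, ", L=", x$L,
      " (effective ", x$L_effective, "), S=", x$S, "\n", sep = "")
  invisible(x)
}

#' Thin SNP positions to a minimum spacing
#'
#' Greedy left-to-right scan: the first position is kept, and each subsequent
#' position is kept iff it lies at least `min_spacing` bp from the last kept
#' one. This is the canonical maximal prefix-greedy subset, the rule used to
#' prepare unlinked markers for clustering programs.
#'
#' @param positions ordered 0-based positions (strictly increasing).
#' @param min_spacing minimum spacing in bp (>= 0).
#' @return the retained positions, order preserved.
#' @export
thin_snps <- function(positions, min_spacing) {
  if (length(positions) == 0) return(positions)
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (min_spacing < 0) stop("min_spacing must be >= 0")
  keep <- logical(length(positions))
  keep[1] <- TRUE
  last <- positions[1]
  for (i in seq_along(positions)[-1]) {
    if (positions[i] - last >= min_spacing) { keep[i] <- TRUE; last <- positions[i] }
  }
  positions[keep]
}

#' Export a thinned genotype matrix for clustering programs
#'
#' Thins each locus independently (positions reset per locus), then writes a
#' flat whitespace-delimited haploid matrix: one row per individual with its
#' id, a population label and one integer-coded allele per retained SNP
#' (A=1, C=2, G=3, T=4; missing or absent individual = -9). This is the input
#' layout consumed by Structure-style clustering software.
#'
#' @param alns list of `locus_alignment` objects.
#' @param file output path.
#' @param min_spacing bp spacing used for per-locus thinning (default 50).
#' @param pop population label per individual: a single string, or a named
#'   vector keyed by sample id.
#' @return the number of SNP columns written (invisibly the file path as an
#'   attribute).
#' @export
export_genotype_matrix <- function(alns, file, min_spacing = 50, pop = "pop1") {
  if (length(alns) < 1) stop("need at least one alignment")
  ids <- unique(unlist(lapply(alns, `[[`, "sample_ids")))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  cols <- list()
  for (aln in alns) {
    tab <- polarize_sites(aln)
    kept <- thin_snps(tab$sites$pos, min_spacing)
    if (length(kept) == 0) next
    m <- do.call(rbind, strsplit(aln$seqs, ""))
    rownames(m) <- aln$sample_ids
    for (p in kept) {
      g <- rep(-9L, length(ids))
      names(g) <- ids
      here <- code[m[, p + 1L]]
      here[is.na(here)] <- -9L
      g[aln$sample_ids] <- here
      cols[[length(cols) + 1L]] <- g
    }
  }
  nsnp <- length(cols)
  labels <- if (length(pop) == 1) rep(pop, length(ids)) else unname(pop[ids])
  if (nsnp == 0) {
    warning("no segregating sites anywhere: writing an empty genotype matrix")
    body <- data.frame(id = ids, pop = labels)
  } else {
    body <- data.frame(id = ids, pop = labels, do.call(cbind, cols))
  }
  utils::write.table(body, file, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  structure(nsnp, file = file)
}
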