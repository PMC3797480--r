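#' The study's multilocus sampling design
#'
#' The 15 nuclear loci of the Taiwan-spruce study with their haploid sample
#' sizes (8-15) and alignment lengths (419-1590 bp). The two-species design
#' adds a second deme (P. wilsonii) with 20 haploid samples per locus, the
#' mid-range of the 12-29 successfully sequenced individuals reported per
#' locus for that species.
#'
#' @param kind `"within"` (one species) or `"between"` (two species).
#' @return data.frame with columns `locus`, `n`, `L` (+ `n2` for
#'   `"between"`).
#' @export
study_design <- function(kind = c("within", "between")) {
  kind <- match.arg(kind)
  d <- data.frame(
    locus = c("4cl", "GI2", "GI4", "GI6", "PCH", "SE1107", "SE1390", "SE1464",
              "SE6", "ebs", "m002", "sbl6", "sb29", "sb62", "SE1427"),
    n = c(8L, 9L, 10L, 14L, 10L, 12L, 11L, 15L, 15L, 8L, 9L, 13L, 13L, 13L, 12L),
    L = c(604L, 1590L, 985L, 1215L, 605L, 426L, 551L, 419L, 445L, 785L, 518L,
          804L, 515L, 540L, 468L),
    stringsAsFactors = FALSE)
  if (kind == "between") d$n2 <- 20L
  d
}

#' Generate a synthetic multilocus data set (FASTA + truth record)
#'
#' Stand-in for the study's archived sequences: simulates site tables under
#' a registered demographic model, embeds the derived alleles into random
#' monomorphic background sequences, and writes one FASTA per locus (the
#' ingroup haplotypes plus one outgroup sequence carrying the ancestral
#' state at every site) together with a JSON truth record (model,
#' parameters, seed, per-locus segregating sites). Reading the files back
#' through [read_fasta_alignment()] and [polarize_sites()] recovers the
#' simulated site tables exactly, with every site polarized.
#'
#' @param design a [study_design()]-shaped data.frame.
#' @param model model name or spec.
#' @param params named parameter vector (within the model's priors).
#' @param seed master integer seed; output is bit-reproducible given the
#'   seed.
#' @param outdir output directory (created if needed).
#' @return list with `fasta` (named file paths), `truth_file`, `truth`, and
#'   the simulated `tables`.
#' @export
make_synthetic_dataset <- function(design, model, params, seed, outdir) {
  spec <- model_spec(model)
  demo <- build_demography(spec, params)
  tables <- simulate_study(design, demo, seed = seed, output = "tables")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ns <- split_design_samples(design, demo)
  bases <- c("A", "C", "G", "T")
  paths <- character(nrow(design))
  for (j in seq_len(nrow(design))) {
    tb <- tables[[j]]
    L <- design$L[j]
    n1 <- ns$n1[j]; n2 <- ns$n2[j]
    n <- n1 + n2
    bg <- with_seed(cpp_mix_seed(seed, 10000 + j) %% 2^31, {
      anc <- sample(bases, L, replace = TRUE)
      der <- vapply(tb$sites$pos + 1L,
                    function(p) sample(setdiff(bases, anc[p]), 1), character(1))
      list(anc = anc, der = der)
    })
    m <- matrix(rep(bg$anc, n), nrow = n, byrow = TRUE)
    masks <- attr(tb, "mask")
    for (s in seq_len(tb$S)) {
      carriers <- which(floor(masks[s] / 2^(seq_len(n) - 1)) %% 2 == 1)
      m[carriers, tb$sites$pos[s] + 1L] <- bg$der[s]
    }
    ids <- if (n2 > 0) {
      c(sprintf("P1_h%02d", seq_len(n1)), sprintf("P2_h%02d", seq_len(n2)))
    } else sprintf("P1_h%02d", seq_len(n1))
    seqs <- c(apply(m, 1, paste, collapse = ""), paste(bg$anc, collapse = ""))
    ss <- Biostrings::DNAStringSet(stats::setNames(seqs, c(ids, "outgroup")))
    paths[j] <- file.path(outdir, paste0(design$locus[j], ".fasta"))
    Biostrings::writeXStringSet(ss, paths[j], width = 70L)
  }
  names(paths) <- design$locus
  truth <- list(model = spec$name, params = as.list(params), seed = seed,
                loci = data.frame(locus = design$locus, n = design$n,
                                  L = design$L,
                                  S = vapply(tables, `[[`, numeric(1), "S")))
  truth_file <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(fasta = paths, truth_file = truth_file, truth = truth, tables = tables)
}
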