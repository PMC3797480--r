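#!/usr/bin/env Rscript
# Step 1 — synthesize the study data set.
#
# The original sequences live in an external archive; the analysis instead
# runs on a synthetic stand-in generated under a recent tenfold population
# decline (alpha = 0.1 at t = 0.05 coalescent time units) with theta chosen
# so the simulated data match the study's observed diversity level
# (multilocus Watterson's theta near 0.0015 per bp, a sizeable monomorphic
# fraction, positive mean Tajima's D). Layout (locus names, haploid sample
# sizes 8-15, lengths 419-1590 bp) matches the real 15-locus design; one
# outgroup sequence per locus carries the ancestral allele at every site.

library(spruceABC)

seed <- 20130815
outdir <- "results/data"
params <- c(theta = 0.004, rho = 0.005, alpha = 0.1, t = 0.05)

design <- study_design("within")
out <- make_synthetic_dataset(design, "decline", params, seed = seed,
                              outdir = outdir)

cat("Wrote", length(out$fasta), "locus FASTA files +", basename(out$truth_file),
    "to", outdir, "\n")
print(out$truth$loci)
cat("Total segregating sites:", sum(out$truth$loci$S), "\n")
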