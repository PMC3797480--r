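# spruceABC

Demographic inference for small multilocus sequence data sets, built around
the study design used for the endemic Taiwan spruce (*Picea
morrisonicola*): 15 nuclear loci (419–1590 bp) sequenced in 8–15 haploid
megagametophytes. The package asks the questions such data can answer —
how much variation is there, does it deviate from neutral-equilibrium
expectations, which demographic history explains it, and how much should a
model-choice result from so small a sample be trusted — and provides every
computational step needed to answer them:

* **Per-locus statistics** — Watterson's θ_W = S/(a₁L), nucleotide
  diversity π, Fay & Wu's θ_H and H, Tajima's D, Zeng's normalized H, and
  haplotype diversity H_e, with outgroup-based allele polarization and
  fixed-S coalescent p-values for D and H.
* **A coalescent simulator** — Hudson-style ancestral recombination graph
  with piecewise-constant deme sizes, population splits and symmetric
  migration; infinite-sites mutation on L discrete positions. Time is
  measured in units of 4N generations, θ = 4Nμ and ρ = 4Nr per bp.
* **Demographic models** — constant size, instantaneous bottleneck
  (fixed duration 0.2 × 4N generations), population decline (present size
  αN recovering to N at time t backwards), two-deme structure, and five
  two-species split models with instant-change/delayed-decline size
  scalings and an isolation-with-migration variant; all with the uniform
  priors θ ~ U(0, 0.01), ρ ~ U(0, 0.02), α ~ U(0, 1.5), t ~ U(0, 1.5),
  M ~ U(0.05, 1).
* **ABC** — rejection sampling on MAD-standardized summary statistics with
  Epanechnikov weights, Beaumont-style local-linear regression adjustment
  of log-transformed parameters, weighted-KDE posterior modes with 5–95%
  intervals, and Bayes-factor model choice via weighted multinomial
  logistic regression (Fagundes-style) or rejection counts.
* **Validation** — posterior predictive checks and a power /
  false-positive-rate study for model choice on pseudo-observed data sets.
* **Synthetic data** — a generator that emits per-locus FASTA (with an
  outgroup carrying the ancestral states) plus a JSON truth record under
  any registered model, so the whole pipeline runs without external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
data set; each is a thin driver over the package functions and writes its
tables under `results/`. Running them in order:

`01_synthesize_data.R` simulates the 15-locus design under a tenfold
recent decline (θ = 0.004, ρ = 0.005, α = 0.1, t = 0.05) and writes one
FASTA per locus. `02_summary_statistics.R` reads them back and prints the
per-locus panel, e.g.

```
     locus  n    L  S theta_w      pi        D      He    p_D
8   SE1464 15  419  2 0.00147 0.00227  1.44289 0.47619 0.1106
15  SE1427 12  468  3 0.00212 0.00350  2.12303 0.54545 0.0000
16 Average NA   NA NA 0.00102 0.00120  0.30417 0.32457     NA
```

— eleven of fifteen loci are polymorphic, diversity is low
(θ_W ≈ 0.001/bp) and mean Tajima's D is positive (+0.30), the
intermediate-frequency excess a population decline leaves behind.
`03_model_choice.R` builds a 2 × 10⁴-row reference table per within-species
model and compares the observed statistics at tolerance 0.01:

```
  posterior probabilities:
  constant bottleneck    decline structure2
    0.0421     0.0316     0.7975     0.1288
```

so the decline model is retained (Bayes factors ≥ 3 against every
competitor). `04_decline_posterior.R` estimates its parameters
(here mode α ≈ 0.12 and θ ≈ 0.0022 against generating values 0.1 and
0.004, the truth inside every 5–95% interval), converts them to natural
units with μ = 2.5 × 10⁻⁸ and a 25–50 year generation time, and runs a
1000-draw posterior predictive check (8 of 9 statistics fit; none below
p = 0.04). `05_power_fpr.R` measures the operating characteristics of the
model choice itself on 100 prior-drawn pseudo-observed data sets per
model:

```
           constant bottleneck structure2
Power          0.15       0.21       0.91
FPR_ge3        0.05       0.04       0.05
FPR_ge_obs     0.00       0.00       0.03
```

Read: hidden population structure is almost always rejected when the data
are a decline (0.91), but a decline drawn from the full prior is often
indistinguishable from a constant-size or bottlenecked population — while
the false-positive rate stays at the few-percent level, so a *high*
observed Bayes factor is unlikely to be an artifact of the small sample.

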