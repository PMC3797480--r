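---
title: "Coalescent models, summary statistics and ABC: how spruceABC works"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent models, summary statistics and ABC: how spruceABC works}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spruceABC)
```

This vignette is the package's own account of its models, conventions and
design choices. It is written for a reader who wants to know exactly what
is computed, under which parameterization, and what the validation results
do and do not show.

## The inference problem

The package targets the typical design of a conifer population-genetic
study: a modest number of unlinked nuclear loci (here 15, of 419–1590 bp)
sequenced in few haploid samples (8–15 megagametophytes per locus; haploid
seed tissue gives phase-known sequences without calling heterozygotes).
Such data carry little information per locus, but the loci are independent
replicates of the same ancestral process, so multilocus summaries can
discriminate between demographic histories — provided the analysis is
honest about how much power so small a sample actually has. That is why
the pipeline treats the power/false-positive study as a first-class
product rather than an afterthought.

## Simulator conventions

All model parameters follow the standard coalescent scalings, and it is
worth being pedantic about the time unit because published software
differs internally by factors of two:

* **Time** is in units of $4N$ generations, where $N$ is the reference
  (ancestral) effective population size. A pair of lineages in a deme of
  relative size $x$ coalesces at rate $2/x$; equivalently the expected
  pairwise coalescence time in a deme of size $N$ is $2N$ generations.
* **Mutation**: $\theta = 4N\mu$ per bp; mutations arise on branches at
  rate $\theta$ per bp per unit branch length. This pair of conventions is
  anchored by the two identities the tests verify by simulation:
  $E[\pi_{\mathrm{total}}] = \theta L$ and
  $E[S] = \theta L\, a_1(n)$, with $a_1 = \sum_{i<n} 1/i$.
* **Recombination**: $\rho = 4Nr$ per bp; a lineage recombines at rate
  $\rho \times$ (its ancestral span in bp), with continuous breakpoints.
* **Migration**: $M = 4Nm$; each lineage migrates at rate $M/2$ (the
  convention of the classical `ms` simulator). Only the two-deme models
  use it.
* A time $t$ converts to generations as $T = 4Nt$ and to years via the
  generation time, with $N = \theta/(4\mu)$.

The simulator is a Hudson-style ancestral recombination graph: lineages
carry sorted lists of ancestral segments tagged with descendant sets;
coalescence merges segment lists and drops material that has reached its
local most recent common ancestor; recombination splits a lineage at a
uniform point of its span; demographic events (size changes, backwards
joins, migration-rate changes) are applied in time order, with exponential
waiting times recomputed across event boundaries (valid by memorylessness).
Mutations are laid down along the way at rate $\theta\times$(ancestral bp)
per lineage and mapped to $L$ discrete positions; the rare collisions are
redrawn within the originating segment so linkage to the local marginal
tree is preserved. Because the derived state is the mutant, simulated site
tables are perfectly polarized — the synthetic FASTA generator therefore
writes an outgroup sequence carrying the ancestral state at every site, and
re-polarizing the files reproduces the simulated tables exactly.

During development the simulator was checked against an exact
master-equation computation of $E[S]$ under a size change (agreement to
0.05% at 2×10⁵ replicates), against closed-form two-lineage expectations,
and against first-step-analysis theory for the two-island model
($E[T_{\text{within}}] = 1$, $E[T_{\text{between}}] = 1 + 1/M$ in these
units). The shipped test suite re-verifies the expectations with pure-R
oracles: a plain Kingman implementation (Kolmogorov–Smirnov on the $S$
distribution), numerical integration of the lineage-count process
(deSolve), and a conditional-dispersion check that $S$ is Poisson given
the realized branch length.

## Demographic models and priors

Within-species (one population of Taiwan spruce):

| model | parameters | structure |
|---|---|---|
| `constant` | θ, ρ | single deme, size N |
| `bottleneck` | θ, ρ, α, t₀ | size αN during [t₀, t₀+0.2], else N |
| `decline` | θ, ρ, α, t | size αN from the present until t, then N |
| `structure2` | θ, ρ, M | two demes of size N, symmetric M |

The bottleneck duration is fixed at 0.2 coalescent time units because
severity and duration are confounded in such models. "Decline" is
parameterized so that the *present* size is αN and the ancestral size is
the reference N — hence the ancestral size is N₁ = θ/(4μ) and the
present-day size N₀ = αθ/(4μ). (A caption formula reading N₀ = θ/(4αμ)
is treated as a typo: only N₀ = αN₁ is consistent with α ∈ (0, 1.5) and
with a fitted α ≈ 0.014 describing a ≈98.6% reduction.) For `structure2`
the haploid sample of each locus is split as evenly as possible between
the demes (the odd sample goes to deme 1); nothing in the data fixes this
choice, so it is exposed as a convention rather than estimated.

Between-species (split of the focal species m from its relative w at t₁):
`split_ICm`, `split_Dm`, `split_ICmw`, `split_ICmw_Dm` scale the daughter
sizes by α's at the split (IC) and/or let species m decline at a later
t₀ < t₁ (D), and `IM` adds post-split symmetric migration with a
log-uniform prior ln M ~ U(−5, 1). θ and ρ are shared across the two
species within a locus — species differences in diversity arise only
through the α scalings, the most parsimonious reading of the model set.
The t₀ < t₁ constraint is enforced by resampling the prior.

Priors are uniform: θ ~ U(0, 0.01) per bp (U(0, 0.015) for `IM`),
ρ ~ U(0, 0.02), all α ~ U(0, 1.5), times ~ U(0, 1.5), M ~ U(0.05, 1) for
`structure2`.

## Summary statistics

Per locus the package computes θ_W, π, θ_H, Tajima's D, Fay & Wu's H
(per-locus total), Zeng's normalized H and haplotype diversity. Per-bp
estimators divide by the *effective* length after filtering: columns with
any ingroup N/gap are excluded entirely (complete-case, appropriate for
haploid Sanger data), tri-allelic columns are excluded from S (the
infinite-sites machinery downstream cannot represent them) but counted in
a diagnostic. Sites that cannot be oriented against the outgroup fall back
to folded minor-allele counts; θ_H, H and Z then skip them and record the
skipped fraction, while π and D (folding-invariant) use all sites.
Multilocus report averages follow the conventions of the original study
design: diversity measures (θ_W, π, θ_H, H_e) average over all loci with
monomorphic loci contributing 0, while the SFS-shape statistics (D, H, Z)
average over the loci where they are defined.

Significance of D and H per locus uses fixed-S simulation: constant-size,
no-recombination genealogies with exactly S mutations placed on branches
proportionally to branch length, and a tail probability in the direction
of the observed sign. Conditioning on S (rather than on θ) matches the
default of the classical summary-statistic libraries and removes the
nuisance mutation rate.

The ABC statistic vectors are fixed-width so every simulated data set
produces the same columns. Within-species (9 statistics): across-locus
mean and SD of θ_W, π, H_e and D, plus the proportion of monomorphic loci;
in this vector a monomorphic locus contributes D = 0, with the monomorphic
proportion acting as the companion indicator. Between-species
(21 statistics): mean and SD of the Wakeley–Hey classes (private
polymorphisms S₁ and S₂, shared Ss, fixed differences Sf), per-species π,
Hudson's F_ST = 1 − π̄_within/π̄_between and focal-species D, plus
study-wide totals of the four site classes and the number of loci with
fixed differences.

## The ABC engine

*Rejection.* Statistics are standardized by their table-wide median
absolute deviation (robust to the long tails prior-predictive simulation
produces; SD is the fallback where the MAD degenerates, and spread-free
columns are dropped with a warning). The tolerance quantile of Euclidean
distances is accepted — acceptance count ⌈tolerance × table size⌉ — with
Epanechnikov weights $w_i = 1 - (d_i/d_{\max})^2$.

*Regression adjustment.* Weighted local-linear regression of
log-transformed parameters on the accepted statistics centred at the
observation (log(x + ε) with ε = 10⁻⁸ × prior range handles bounds at 0).
Adjusted draws are deliberately **not** clipped to the prior box: the
adjustment is a local model, clipping would pile mass on the bounds, and
excursions are counted and reported instead. Aliased statistic columns are
harmless (the correction needs only the intercept and residuals); a
genuinely singular fit falls back to the unadjusted sample with a warning.

*Summaries.* Mode of a weighted Gaussian KDE (Silverman bandwidth,
512-point grid spanning the draws) and weighted 5/95 percentiles.

*Model choice.* Reference tables of equal size are pooled (equal prior
probability on models), the pooled tolerance quantile accepted, and model
probabilities estimated either by acceptance frequencies (`rejection`) or
by a weighted multinomial logistic regression of the model label on the
statistics evaluated at the observation (`mnlogistic`, the default,
following the Fagundes-style implementation; `nnet::multinom` does the
fitting). Zero-count models are floored at 1/(accepted + k) before
renormalizing so Bayes factors stay finite. BF[i,j] = p_i/p_j by
construction, so the matrix is exactly antisymmetric
(BF[i,j]·BF[j,i] = 1).

At the package's default desk scale — 2 × 10⁴ simulations per model with
tolerance 0.01 — the accepted pool (200–800 rows) is comparable to a 10⁶ ×
0.001 run, and the four-table build takes under a minute on one CPU.
The paper-scale settings are plain arguments (`nsims = 1e6`,
`tolerance = 0.001`).

*Validation of the engine.* The tests include a conjugate toy problem
(uniform prior, Gaussian likelihood, the statistic sufficient) where the
ABC posterior quantiles approach the analytic posterior as the tolerance
decreases; a linear-Gaussian oracle where the regression adjustment
provably shrinks the posterior-draw RMSE; and a parameter-recovery
experiment under the constant model where the adjusted 90% intervals cover
the generating θ in ≥ 85/100 replicates.

## Posterior predictive checks and the power study

The PPC resamples the regression-adjusted weighted posterior, simulates a
study-shaped data set per draw (default 1000), and reports predictive
quantiles plus a two-sided tail probability per statistic; structurally
invalid adjusted draws (a non-positive size after back-transformation)
are resampled and counted. This machinery doubles as the goodness-of-fit
step for the two-species isolation-with-migration scenario.

The power study simulates pseudo-observed data sets (PODs) under a
generating model with parameters drawn from its **priors** — the
prior-predictive choice standard for ABC model-choice calibration — runs
the identical model-choice procedure, and tabulates how often the decline
model wins at BF ≥ 3 (and at an observed BF, when supplied). One set of
reference tables is built per study and shared across all replicates; only
the POD varies, which is what makes the experiment tractable and does not
change the distribution of any single replicate's result.

Two structural facts about this design are worth stating because the
numbers surprise people. First, a decline drawn from the full prior is
often *informationally indistinguishable* from a constant-size population:
if the decline is old relative to its compressed coalescent time scale
(t ≳ α in these units) every lineage coalesces inside the present-size
epoch and the genealogy is exactly that of a constant population with a
smaller θ; and α near 1 is no decline at all. Under prior-drawn PODs the
measured power against the constant model is therefore modest (≈0.15 at
the default scale) — detection concentrates where t ≲ α and α ≪ 1, and
PODs simulated at a strong recent decline (α ≈ 0.014, t ≈ 0.022) are
detected ≈90% of the time. Second, the same experiment run with null
models generating shows the false-positive rate staying at the few-percent
level (≈0.04–0.07 against the constant model). The practical reading for
small samples: failing to reject a null is weakly informative, but a high
observed Bayes factor is very unlikely to be a small-sample artifact.

## Synthetic data: what it emulates and what it does not

The generator reproduces the study *design* — locus names, per-locus
haploid sample sizes and lengths, an outgroup per locus — and embeds
simulated segregating sites in random uniform-composition backgrounds
(irrelevant to every downstream statistic, which depend only on the site
table). It does not emulate sequencing error, alignment gaps, indels,
base-composition or mutation-rate heterogeneity among sites or loci, or
outgroup misorientation; consequently, passing tests demonstrate the
correctness of the statistics and inference machinery on clean polarized
data, not robustness to those artifacts. The second species' per-locus
sample size is fixed at 20 haploids (the mid-range of what such designs
report) since exact counts are design-specific.

## Numerical and reproducibility choices

* Master seeds split via counter-based splitmix64 streams
  (`derive_seed`): every reference-table row, POD and locus gets an
  independent stream keyed by the master seed and, for loci, the locus
  *name* — so locus realizations are invariant to the order of the design
  table, and fixture output is bit-reproducible.
* Infinite sites are approximated on L discrete positions with collision
  redraw inside the originating segment; with θL ≪ L collisions are rare
  and at most a handful of mutations per locus are ever dropped.
* Demographies that cannot reach a common ancestor (two demes, no
  migration, no join) raise an error rather than loop.
* Weighted KDE bandwidth is Silverman's rule computed on the unweighted
  draws; degenerate (all-equal) samples short-circuit to the common value.
* Tied distances at the acceptance boundary are resolved by stable order;
  if every accepted weight would be zero (all distances equal) uniform
  weights are used.

## Known limitations

Single-locus recombination is a nuisance parameter, never estimated from
data. No gene conversion, growth curves, selection or more than two demes.
Sample sizes are capped at 63 haploids total per locus (descendant sets
live in 64-bit masks). The between-species statistic set is a 21-statistic
Wakeley–Hey panel; richer joint-SFS summaries are possible but not
implemented. And, as measured above, the power of model choice under
prior-drawn declines is intrinsically limited by the prior's mass on
undetectable histories — a property of the design, not of the
implementation.
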