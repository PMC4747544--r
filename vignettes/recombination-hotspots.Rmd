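---
title: "Inferring recombination rate maps and hotspots with rhomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring recombination rate maps and hotspots with rhomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`rhomap` estimates the population-scaled recombination rate
ρ = 4·Nₑ·c along a genomic region from unphased or phased SNP genotypes of
unrelated individuals. Population data inform ρ, not c: the same linkage
disequilibrium pattern arises from a small population with frequent
crossing-over and a large population with rare crossing-over. Conversion to
cM/Mb (`rho_to_cm_per_mb()`) therefore requires an external Nₑ and is kept
out of the inference itself.

The rate map is a constant background b (ρ/Mb) overlaid with hotspots. A
hotspot is an interval with an intensity multiplier λ ≥ 1; inside one
hotspot the local rate is b·λ, and overlapping hotspots act additively on
the excess, ρ(x) = b·(1 + Σ (λ_h − 1)). Hotspots arise from a homogeneous
marked Poisson process:

* count K ~ Poisson(rate · region length), default rate 1 per Mb;
* centers uniform on the region (intervals clipped at the edges);
* widths ~ Uniform(0.5 kb, 5 kb) — mammalian hotspots are generally 1–2 kb,
  and the widths called in the cat survey bundled with the package span
  1.8–4.6 kb, so the bounds bracket both;
* multipliers λ ~ log-uniform(5, 500).

The background prior is Exponential with mean 100 ρ/Mb (the ten cat survey
regions span 77–309 ρ/Mb, so the prior is weakly informative on that
scale); θ per site is log-uniform on (10⁻⁴, 10⁻²). All bounds are arguments
of `prior_spec()`.

Internally hotspots are stored as (center, width, multiplier) with the
center allowed anywhere in the region and the interval clipped at
evaluation time. This keeps every per-hotspot prior density a constant, so
reversible-jump acceptance ratios stay simple, and it makes the prior
probability that a bin is covered translation invariant away from the
edges — a property the test suite checks, since Bayes factors compare
posterior to prior occupancy bin by bin.

# The two-locus composite likelihood

Full-likelihood inference under the coalescent with recombination
integrates over ancestral recombination graphs and is cluster-scale. The
engine here is deliberately cheaper: a composite likelihood that multiplies
two-locus sampling probabilities over marker pairs, the approximation
family used by LDhat-style estimators.

For n haplotypes, a pair of biallelic sites is summarized by the haplotype
counts (n₀₀, n₀₁, n₁₀, n₁₁). `two_locus_table()` estimates the distribution
of these configurations at each node of a ρ grid by simulating the
two-locus structured coalescent (lineages carry ancestral material at the
left locus, right locus, or both; recombination at rate ρ/2 per
doubly-ancestral lineage splits the loci; coalescence at rate k(k−1)/2).
Mutation is handled in the low-θ limit appropriate for ascertained array
SNPs: exactly one mutation per locus, placed on a branch with probability
proportional to branch length. Each simulated graph contributes its exact
conditional configuration distribution (the mutation placement is
integrated analytically — Rao-Blackwellization), so a few thousand
replicates per grid node give usable tables where naive draws would need
millions; the naive sampler is retained (`method = "naive"`) as an
independent estimator of the same distribution and the two are compared in
the tests.

Configurations are folded to a canonical form invariant to allele
relabelling at either locus and to locus exchange — exactly the
symmetries unpolarized genotype data cannot resolve. Raw table
probabilities at a node sum to 1 over the canonical space, and at the exact
ρ = 0 node four-gamete-complete configurations have probability exactly
zero (a single tree cannot produce them). Smoothing (add-α with α = 0.5
over the enumerated space) is applied only at likelihood lookup so these
structural zeros are preserved in the table itself.

Three further choices matter:

* **Ascertainment conditioning.** Markers enter analyses only at sample
  MAF ≥ 0.1 (matching the array filters). Conditional on passing,
  intermediate-frequency configurations are relatively likelier at low ρ,
  and an unconditioned composite likelihood is systematically biased
  toward too little recombination — we observed the background posterior
  collapsing several-fold below the generating value before conditioning.
  The engine therefore renormalizes each pair's probabilities, per grid
  node, over the configurations that pass the MAF threshold
  (`maf_condition`, default 0.1; `NULL` disables).
* **Pairs and missing data.** Pairs further apart than `max_pair_span`
  (default 100 kb) are excluded: distant pairs carry almost no rate
  information and would dominate the sum. Haplotypes missing at either
  marker of a pair are dropped and the pair is scored against the table
  projected to the reduced sample size by exact multivariate
  hypergeometric downsampling (the coalescent is sampling-consistent, so
  the projection is exact, not an approximation).
* **Grid and interpolation.** The ρ grid has an exact node at 0 and is
  geometric up to 1000 (`default_rho_grid()`); log-probabilities are
  interpolated linearly in ρ between nodes and clamped above the last node
  (clamp events are counted and reported). On a tiny instance we measured
  the interpolation error of the default grid at roughly ten ρ/Mb units of
  posterior-mean background; analyses that need exactness at specific ρ
  values can supply a custom grid.

θ is retained in the model state and sampled, but under the
one-mutation-per-locus conditioning the configuration distribution is
θ-free, so its posterior reproduces its prior. This is deliberate: array
SNP counts carry almost no usable θ information after ascertainment, and
pretending otherwise would only add noise. A full-likelihood engine would
identify θ; this one does not.

# The sampler

`infer_rhomap()` runs Metropolis–Hastings with reversible-jump moves: add a
hotspot (drawn from the prior), remove one (uniformly), move a center,
resize a width, rescale an intensity, and log-scale random walks on
background and θ. Default move weights are (0.15, 0.15, 0.2, 0.15, 0.15,
0.1, 0.1); proposal scales were set so acceptance rates on benchmark runs
sit in the 20–50% band. For the marked Poisson prior the Janossy density
gives birth acceptance L-ratio × Λ/(K+1) and death its exact inverse, which
the tests verify directly.

Center moves are a mixture kernel: with probability `move_jump_prob`
(default 0.25) the center is redrawn uniformly over the region
(independence proposal, Hastings ratio 1) instead of a local Gaussian step.
The composite likelihood surface has well-separated modes wherever the
realized genealogy concentrates breakpoints, and purely local moves leave
hotspots stranded on secondary modes.

The first half of the chain is discarded as burn-in and the remainder
thinned to about 2000 retained samples by default; both are
`chain_settings()` arguments. Convergence is monitored with trace effective
sample sizes computed by Geyer's initial-positive-sequence estimator
(`compute_ess()`), implemented directly from the truncated autocorrelation
pair-sum definition; a constant trace is reported as ESS = length with a
warning. Seeds are explicit everywhere; rerunning any function with the
same seed reproduces its output byte for byte, and the chain aborts with a
diagnostic if the initial posterior is non-finite.

# Bins, Bayes factors and calls

`bin_probability()` tiles the region with 200-bp half-open bins starting at
the region start; a final partial bin is kept and flagged. pⱼ is the
fraction of posterior samples in which any hotspot interval intersects bin
j. qⱼ comes from `prior_chain()` — the same sampler with constant
likelihood, same region, same marker positions. The Bayes factor is the
posterior-to-prior odds ratio with both probabilities clamped to
[ε, 1 − ε], ε = 1/(2 × sample count): prior chains routinely give qⱼ = 0,
and the clamp keeps BF finite while preserving order. Calls
(`call_hotspots()`) are maximal runs of at least two consecutive bins with
BF ≥ 100, reported with the outer bin coordinates, size, bin count, mean
posterior probability and mean BF; everything else is "neutral".

Bin–hotspot overlap uses half-open intervals, so a hotspot touching only a
bin's end coordinate does not cover it and nothing is double-counted at bin
boundaries.

# The synthetic-data generator

`simulate_haplotypes()` is a Hudson-style back-in-time ancestral
recombination graph simulator with recombination breakpoints placed by
inverse-CDF on the cumulative rate map and infinite-sites mutations dropped
on ancestral material proportionally to length; crossing-over only, no gene
conversion, no demography (growth, structure, migration), no selection.
`ascertain_markers()` then emulates array genotyping: sites below sample
MAF 0.1 are dropped, the rest thinned uniformly at random to a target
density, and haplotypes paired into diploids. `degrade_genotypes()` adds
missingness to exercise the ≥ 80% call-rate filter. The default preset
(`simulate_region_preset()`) mirrors the bundled survey's structure: 44
haplotypes (22 diploids), 850 kb, ~70 markers.

What passing tests on these data do **not** show: robustness to demography
and selection (the coalescent here is neutral and panmictic), to gene
conversion, to genotyping error, or to the array's real ascertainment
scheme (discovered in a small panel, not the study sample). Results on real
data inherit those caveats.

Phase is a genuine gap in array data: the package resolves unphased
genotypes by seeded random phase assignment (`phase_genotypes()`), with a
logged caveat. Random phasing destroys between-marker LD carried by double
heterozygotes, which weakens recombination signal; simulated presets carry
their true haplotypes, so this cost is paid only on real unphased input.
Statistical phasing is explicitly out of scope.

# Benchmarks and problem sizes

The test suite's standing benchmarks, chosen as the package's canonical
configurations:

* **Closed forms:** n = 20, L = 10 kb, θ = 0.001/site, 2000 replicates for
  Watterson's E[S] and E[π] = θL; the four-gamete theorem must hold without
  exception at ρ = 0. Smaller replicate counts of the same checks run in
  the unit tests, plus an msprime cross-check at identical parameters.
* **Prior recovery:** Λ = 1 over 1 Mb; occupancy must match
  1 − e⁻¹ ≈ 0.632 within Monte-Carlo error, counts match Poisson(1), and
  widths/intensities/background recover their priors.
* **Hotspot recovery:** 50-kb region, background 200 ρ/Mb, θ = 0.002/site,
  40 haplotypes, ~60 markers (1200/Mb), one 2-kb hotspot with λ = 30 at
  the region center; 40 000 iterations. The pⱼ track must peak within
  ±2 kb of the true center in at least 8 of 10 seeded replicates. This
  geometry was fixed by an identifiability analysis *at the true
  parameters* (profile argmax over candidate centers): sparser layouts
  (3-kb spacing over 100–200 kb) leave a 30× hotspot carrying only ~3 ρ
  units, indistinguishable from chance background breakpoint clusters, and
  no sampler can recover what the likelihood cannot see.
* **Tiny-instance equivalence:** n = 4, k = 3. The grid posterior mean of
  the background under the Exp(100) prior computed through the package
  engine (table on exact pairwise-ρ nodes) must agree with an independent
  pure-R Rao-Blackwellized two-locus oracle within 3 combined Monte-Carlo
  standard errors (batched on both sides).

# Known limitations

* **Composite overconfidence.** Marker pairs share one genealogy; the
  composite likelihood multiplies them as if independent. Posterior
  credible intervals are too narrow, the background is typically
  under-estimated (local breakpoint clusters of the single realized
  genealogy are absorbed as spurious secondary hotspots with small b),
  and BF magnitudes should be read as ranks, not calibrated evidence. The
  BF ≥ 100 rule with a prior-matched qⱼ is retained as the calling
  criterion precisely because it is a relative comparison. Localization of
  a dominant hotspot is robust in the benchmark above.
* **One region, one θ, one hotspot set.** Blocks partitioned by
  `partition_blocks()` (20 markers per block, remainders under 5 merged
  into the preceding block — a one-marker block carries no recombination
  information) share θ; hotspot configurations are modelled per region,
  not per block.
* **θ is not estimated** (see above); report it as its prior if at all.
* **Bin-count conventions.** Region bin totals depend on where tiling
  starts and how partial bins are handled; the package starts at the
  region's first coordinate and flags a partial final bin. Published bin
  totals from other tools may differ by one under other conventions.
* **X-chromosome data.** Hemizygous males are not modelled; an X region is
  treated like an autosome with whatever ploidy the input encodes.
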