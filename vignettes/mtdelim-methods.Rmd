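---
title: "Methods: multi-method mtDNA species delimitation with mtdelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-method mtDNA species delimitation with mtdelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdelim)
```

`mtdelim` packages the analysis chain commonly applied to mitochondrial
barcode surveys of low-vagility arthropods (tarantulas, trapdoor spiders and
similar taxa with deep population structure): delimit candidate species by
several mutually independent criteria, test the focal species for recent
range expansion, date the splits under a fixed pairwise clock, and estimate
where the ancestral population lived. This vignette explains each model, the
parameters that matter, and the design choices made where the methods leave
room.

## Data model

An alignment is a plain character matrix (specimens x columns) with named
locus partitions. Two mitochondrial fragments (defaults 1165 bp and 886 bp,
concatenated to 2051 bp) ride on a single genealogy because mtDNA does not
recombine; `concatenate()` joins loci on specimen ids and pads specimens
missing one locus with `N`. `?` and terminal gap runs are canonicalized to
`N` (truncated reads, not indels); internal `-` is kept as a gap. Distances,
site counts and haplotype identity use only unambiguous `A/C/G/T` states.

Haplotype identity has to tolerate truncated and ambiguous sequences: two
sequences are the same haplotype iff they agree at every column where both
are resolved, and a partially resolved sequence joins the haplotype of its
closest fully resolved match (ties to the lowest specimen id; assignment
order is by decreasing resolved-site count, so fragments join fuller
sequences, not the reverse). This mirrors how network programs treat
truncated mtDNA and keeps `collapse_haplotypes()` deterministic and
idempotent.

## Barcode gap on uncorrected p-distances

`pdist_matrix()` computes uncorrected p-distances with pairwise deletion;
`group_distance_summary()` averages them within and between labelled groups
(arithmetic means over specimen pairs; a `unique_sequences` switch averages
over distinct sequences instead, which makes the summary invariant to
resampling the same haplotype). `barcode_gap_delimit()` passes a group pair
when its mean between-group distance exceeds the gap, 6% by default — the
threshold used in the tarantula study this pipeline emulates, chosen there
to exceed the largest observed intraspecific distance. Distances are
reported as percentages with two decimals; internally everything is a
proportion.

## Tree-based exclusivity and consensus

`tree_exclusivity()` asks whether each labelled species is genealogically
exclusive (its tips form a clade). Near-exclusivity (exactly one intruding
tip) is reported separately rather than being collapsed into failure,
because single misplaced tips are usually introgression, misidentification
or a rogue sequence and deserve inspection. `consensus_delimit()` encodes
the study-style policy: a group is ratified when it is exclusive (or a
singleton) and passes the gap against every other group; GMYC splitting
inside a ratified group is flagged as intraspecific structure, not new
species; GMYC lumping across gap-passing groups is flagged for review. The
policy is a documented default, not a claim that expert judgment can be
automated away.

## GMYC: mixed Yule–coalescent delimitation

On an ultrametric tree of unique haplotypes, the generalized mixed
Yule–coalescent model assumes branching before a threshold time `T` follows
a Yule process and branching after it is within-species coalescence.
Between successive branching events the total rate is

  b_i = lambda_1 * k_i^{p_1} + lambda_2 * sum_j [n_ij (n_ij - 1)]^{p_2},

where `k_i` counts species lineages (branches whose parent node is at or
above `T`, which includes singleton lineages that cross `T` without
coalescing — without this convention the first coalescence in each cluster
would have zero rate) and `n_ij` counts lineages of cluster `j`. An interval
of length `x_i` ending in a branching event contributes `b_i exp(-b_i x_i)`;
the final interval to the present contributes the survival term. Scaling
exponents are constrained to `[0, 2]`; rates are optimized on the log scale
by bounded quasi-Newton from two starts.

Candidate thresholds are the node heights, plus one candidate above the
root under which the whole tree is a single coalescent cluster — that
candidate reproduces the null model exactly, so `logL(single) >=
logL(null)` by construction and the likelihood-ratio test is well defined.
Ties between equally good thresholds resolve toward the older one. The
`2 logL` confidence sets collect the cluster and entity counts of all
thresholds within 2 log-units of the optimum. Clusters are delimited groups
with at least two sampled tips; entities add the singleton lineages. The
single-vs-null test uses chi-square with df = 3 (four threshold-model
parameters against two, the threshold itself not counted) — a convention,
switchable via the `df` argument.

The multiple-threshold variant lets the transition vary across the tree: a
greedy search from the single-threshold optimum either splits a cluster
into its child subtrees or merges/grows clusters at any eligible node,
accepting the best likelihood improvement until none remains. The
comparison with the single-threshold fit uses df equal to the difference in
the number of distinct local transition times.

Identical haplotypes must be removed before fitting (zero-length branches
are rejected with an instruction to collapse haplotypes first); tied node
heights are legal and handled as zero-length intervals.

## Neutrality tests with a coalescent null

Tajima's D is computed from the segregating-site count and the mean number
of pairwise differences with the standard 1989 constants; it is undefined
(returned as `NA`, never 0) when there is no variation. Fu's Fs uses the
Ewens sampling formula: `S'` is the probability of at least the observed
number of haplotypes given theta estimated from pairwise differences, with
unsigned Stirling numbers of the first kind and the rising factorial
evaluated in log space (stable well past n = 40), and `Fs = ln(S'/(1-S'))`.
A monomorphic sample forces `S' = 1` and is flagged as `+Inf`.

Significance comes from `neutrality_pvalues()`: samples of the same size are
simulated under a constant-size Kingman coalescent with mutations Poisson on
branches at rate theta/2 (Hudson convention), conditioning on the
pairwise-difference theta of the data (conditioning on the observed number
of segregating sites is available as an option; the choice is stated
explicitly because published tables rarely say which was used). P-values
are one-tailed toward negative values — the population-expansion direction:
`p = P(stat_sim <= stat_obs)`. Following common practice, Fs is described
as significant at p < 0.02.

## Chronograms and the fixed pairwise clock

`ultrametricize()` wraps penalized-likelihood rate smoothing (Poisson branch
likelihood plus `lambda` times a squared rate-change roughness penalty) and
rescales the root height to exactly 1, the convention the GMYC stage
expects. The default `lambda = 1` keeps moderate rate variation; a
cross-validated log-grid choice is available (`cv = TRUE`).

Absolute dating uses a fixed *pairwise* clock, by default 4% pairwise
divergence per million years (a mygalomorph 16S estimate): two lineages
diverging from a node accumulate `rate` difference per MY, so `age = pairwise
divergence / rate`, i.e. the per-lineage rate is 2%/MY. The pairwise
vs per-lineage convention is applied explicitly because published clock
descriptions often leave it implicit. `estimate_rate()` inverts the same
relation by weighted least squares over calibration nodes and reports a
curvature-based interval; on a noise-free clock it round-trips the rate
exactly. Full Bayesian dating (MCMC with tree priors and calibration
densities) is deliberately out of scope; the deterministic transforms are
the package's account of what a fixed clock implies.

## Statistical-parsimony networks

The 95% connection limit follows the statistical-parsimony logic: the
probability that `j` observed differences over `m` sites all arose from
single substitutions. Under a Jukes–Cantor per-site process with expected
divergence `d = j/m`, a differing site is single-hit with probability
`lambda e^{-lambda} / ((3/4)(1 - e^{-4 lambda/3}))` where `lambda` inverts
the JC formula at `d`; the parsimony probability of a j-step connection is
that ratio to the j-th power, and the limit is the largest `j` keeping it at
or above the confidence level (17 steps for 2051 sites at 95%). The paper
trail for this quantity prints no reference value, so it is validated by an
independently coded oracle and by monotonicity in both arguments.

`build_network()` links haplotypes in increasing order of Hamming distance
over mutually resolved sites, materializing unsampled intermediates so every
edge is one mutational step; a pair is linked only if no equally short path
already exists, so equally minimal alternative connections between
previously separate parts are retained (reticulation) while exact duplicate
paths are not re-added. `ancestral_haplotype()` scores observed haplotypes
by equally weighted normalized frequency and degree — the "internal,
frequent, many lineages radiating" criterion — and reports ties jointly;
`steps_from_ancestor()` is a shortest-path count.

## Ancestral locations under a Brownian random walk

`fit_dispersal()` models displacement along each branch as bivariate normal
with variance `psi` times branch duration per axis. Coordinates are first
projected to a local equirectangular plane in km about the tip centroid,
because a degree of longitude shrinks with latitude and an isotropic walk
in degrees would be anisotropic on the ground. The tip likelihood is
computed by continuous-trait peeling (verified against the full-covariance
Gaussian to 1e-8 in the tests) and maximized by Nelder–Mead hill-climbing
over (root x, root y, log psi) with seeded random restarts — the
"optimization replicates". "Smoothing replicates" re-run the fit from
independent penalized-likelihood smoothings when the input is a phylogram
(for an already ultrametric tree they are identical, and the replicate
spread collapses to numerical noise). The best replicate is reported and
all are retained; `replicate_consensus()` summarizes replicate agreement
and flags optima spread over more than a configurable radius (default
200 km).

## The synthetic-data generator

Every stage is testable offline because `generate_dataset()` produces data
with the statistical structure the analyses assume: an ultrametric Yule
species tree (forward pure-birth, cut one unobserved waiting time after the
k-th lineage appears, so the expected root age is `(H_k - 1)/birth_rate`); a
censored coalescent genealogy within it (per-species samples coalesce along
terminal branches, survivors merge and keep coalescing in ancestral
populations; a single species runs its — possibly exponentially growing —
coalescent to the MRCA); HKY (optionally +Gamma) sequences simulated along
the shared genealogy in two linked partitions; and Brownian tip coordinates.

The `paper` preset encodes the study-like conditions: 7 species; 120
specimens (42 in the focal species, 13 in each other — the focal sample size
matches the study's focal clade); loci of 1165 + 886 bp; within-species
theta 0.01/site with exponential growth 5, giving star-like genealogies,
negative-leaning Tajima's D and within-species divergence well under 3%;
and a species tree rescaled so the shallowest split yields 8% *observed*
divergence (the rescaling inverts Jukes–Cantor, because multiple hits
depress observed p-distances below the substitution load — without the
correction the realized gap undershoots its target). The expansion preset
(one species, n = 42, growth 20, theta 0.02/site) realizes diversity near
0.26% — the value observed in the study's expanded northern population —
and drives Tajima's D negative essentially always. Geography uses a root in
central Texas-like coordinates with dispersal variance 4 squared-degrees
per unit tree depth, giving a few-hundred-km cloud per species.

What the generator does *not* emulate: rate variation among lineages beyond
the optional Gamma site mix, saturation patterns of real mitochondrial
third positions, selection, introgression, and real sampling geography
(collections cluster along roads; the generator's clouds are isotropic).
Passing tests on synthetic data therefore show the estimators are correct
under the model they assume, not that the model captures every feature of
field data.

## Numerical choices and problem sizes

Optimizers are bounded (`L-BFGS-B` over log-rates with exponents in
`[0, 2]` for GMYC; Nelder–Mead for the geographic fit) and multi-started;
GMYC threshold ties break toward the older threshold. Ultrametricity is
asserted to 1e-9 in the tests. Undefined statistics are flagged (`NA`,
`Inf`) rather than silently zeroed. The acceptance script reports, among
other quantities, the null-calibration size of the D test (1000 outer
samples, 200-replicate inner nulls at n = 30, theta = 5), expansion power
over 50 datasets, GMYC entity-recovery over 60 paper-preset datasets and
type-I error over 100 single-population trees, a clock-rate round trip on
a 20-tip tree, and 10 replicate geographic fits — sizes chosen so the whole
report recomputes in a few minutes on one core while keeping Monte-Carlo
error well inside the margins being checked.

## Known limitations

Single-locus (mitochondrial) delimitation cannot separate deep population
structure from speciation — the GMYC oversplitting flag exists precisely
because the focal-species clusters in such studies are usually structure,
not species. The fixed clock is a strong assumption; the rate estimator is
provided mainly to expose implausible calibrations (biogeographic
calibrations in the emulated study implied a rate above 14%/MY, far above
the 4% prior). The network's gap handling treats unresolved sites as
uninformative, so heavily truncated haplotypes can appear closer than they
are; the reticulation retained in such cases is a display of uncertainty,
not evidence of recombination.
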