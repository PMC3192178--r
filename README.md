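# mtdelim

Multi-method species delimitation and phylogeography from mitochondrial DNA,
for taxa where morphology is unreliable and nuclear markers are scarce —
tarantulas, trapdoor spiders and other low-vagility arthropods with deep
population structure. The package bundles the full analysis chain such
surveys use, each method behind a tested function, plus a seeded synthetic
data generator so the whole pipeline is verifiable without any downloads.

The methods, in the field's standard notation:

- **Barcode gap.** Uncorrected p-distances `d = mismatches / compared sites`
  (pairwise deletion), averaged within and between candidate species; a pair
  of groups passes when its mean between-group distance exceeds the gap
  (default 6%).
- **Genealogical exclusivity** (Wiens–Penkrot style): each candidate species
  must form a clade; single stray tips are reported as near-exclusivity.
- **GMYC.** On an ultrametric haplotype tree, inter-node intervals have rate
  `b_i = λ₁k_i^{p₁} + λ₂Σ_j[n_{ij}(n_{ij}−1)]^{p₂}` — Yule branching among
  the `k_i` species lineages before the threshold `T`, coalescence within
  each cluster `j` after it; `T` and the four parameters are fit by maximum
  likelihood, with single- and multiple-threshold variants, a LR test
  against the one-species null (df = 3) and 2-logL confidence sets for the
  cluster/entity counts.
- **Neutrality and expansion.** Tajima's `D = (k − S/a₁)/√(e₁S + e₂S(S−1))`
  and Fu's `Fs = ln(S′/(1−S′))` with `S′ = P(K ≥ k_obs | θ̂_π)` from the
  Ewens sampling formula; one-tailed p-values from 10,000 constant-size
  coalescent simulations conditioned on θ̂_π.
- **Statistical-parsimony networks** with the 95% connection limit (largest
  step count whose all-single-hit probability stays ≥ 0.95; 17 steps for
  2051 sites), inferred intermediates, retained reticulation, and
  frequency/degree scoring of the ancestral haplotype.
- **Chronograms.** Penalized-likelihood ultrametricization with the root
  scaled to 1; ages from a fixed *pairwise* clock (default 4%/MY, i.e.
  `age = pairwise divergence / rate`), and a least-squares rate estimator
  from calibration nodes.
- **Ancestral locations.** Maximum-likelihood root coordinates and dispersal
  rate ψ under a Brownian random walk (displacement variance ψ × branch
  duration per axis), pruning likelihood, seeded hill-climbing restarts and
  replicated runs with a consensus report.

## Worked example

Simulate a survey with the study-like preset (7 species, 120 specimens, two
linked loci totalling 2051 bp, recent within-species expansion), then run
the delimitation chain:

```r
library(mtdelim)

ds <- generate_dataset(sim_preset("paper", seed = 33))
haps <- collapse_haplotypes(ds$concatenated)
print(haps)
#> mt_haplotypes: 76 haplotypes from 120 specimens; modal frequency 7

groups <- setNames(ds$specimens$species, ds$specimens$specimen_id)
bg <- barcode_gap_delimit(
  group_distance_summary(pdist_matrix(ds$concatenated), groups), gap = 0.06)
print(bg)
#> Barcode gap at 6.0%: 21/21 group pairs pass

net <- build_network(haps, connection_limit(2051))
print(net)
#> mt_network: 76 observed haplotypes, 618 inferred intermediates,
#> 756 edges; limit 17 steps; 7 component(s)

chrono <- as_chronogram(ape::keep.tip(ds$genealogy_coal, haps$representative))
gm <- fit_single_threshold(chrono)
print(gm)
#> GMYC single model: logL = 552.5993, 7 clusters, 7 entities
#> (2-logL CI: clusters 7-7, entities 7-7)
lt <- lr_test(gm, fit_null(chrono))
#> LR = 85.38, p = 2.15e-18

cons <- consensus_delimit(bg, tree_exclusivity(ds$genealogy_coal, groups),
                          gm, groups)
print(cons)
#>   group exclusivity gap_pass    gmyc   final
#> 1   sp1   exclusive     TRUE matched species
#> ...
#> Final species count: 7
```

Reading the output: 120 specimens collapse to 76 unique haplotypes; all 21
species pairs sit beyond the 6% barcode gap; the parsimony network splits
into exactly one component per species (between-species distances far exceed
the 17-step limit); the GMYC threshold model delimits 7 clusters/entities
with a decisive improvement over the one-species null; and the consensus
ratifies 7 species with no flags. The focal species can then be tested for
expansion:

```r
focal <- ds$specimens$specimen_id[ds$specimens$species == "sp1"]
sub <- mt_alignment(focal, ds$concatenated$matrix[focal, , drop = FALSE],
                    ds$concatenated$partitions)
neutrality_pvalues(sub, reps = 10000, seed = 7)
#> n = 42, S = 30, k = 6.698, K = 19
#> Tajima's D = -0.13422 (p = 0.5045)
#> Fu's Fs    = -3.10504 (p = 0.1507)  [10000 null replicates]
```

(Negative-leaning but non-significant here; the stronger `"expansion"`
preset yields strongly negative, significant D essentially always.)

A thin command-line front end covering the same stages ships in
`inst/cli/mtdelim.R`:

```sh
Rscript inst/cli/mtdelim.R simulate --preset paper --seed 3 --out simdata
Rscript inst/cli/mtdelim.R seqstats simdata/co1.fasta
Rscript inst/cli/mtdelim.R barcode-gap simdata/co1.fasta simdata/specimens.csv
```

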