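# rearnet

Analysis of host tree x wood-boring beetle interaction networks from
rearing experiments. In such experiments, branch sections of known tree
species are exposed in the field under contrasting spatio-temporal
treatments — rain-canopy (Rc), rain-ground (Rg), dry-canopy (Dc),
dry-ground (Dg) — then isolated until the saproxylic beetles (Cerambycidae)
developing inside emerge, attributing every adult to its host wood. The
package is aimed at community ecologists who want the full analysis chain
for this kind of weighted bipartite data:

- **Diversity** — Hill numbers $^qD = (\sum_k p_k^q)^{1/(1-q)}$
  (q = 0, 1, 2) with 100-bootstrap percentile CIs, Good-Turing sample
  coverage, and CI-overlap significance letters.
- **Beta diversity** — Baselga's partition
  $\beta_{sor} = \beta_{sim} + \beta_{sne}$ of Sorensen dissimilarity into
  turnover and nestedness-resultant components, per treatment pair.
- **Interaction dissimilarity** — the Poisot decomposition
  $\beta_{WN} = \beta_{OS} + \beta_{ST}$ of whole-network link
  dissimilarity into rewiring among shared species and species turnover.
- **Network structure** — weighted nestedness (WNODF, 0-100), Barber
  bipartite modularity $Q = \frac{1}{m}\sum_{ij}(a_{ij} - r_i c_j/m)\,
  \delta(g_i, g_j)$ maximized by seeded label propagation, network
  specialization $H_2' = (H_{2max} - H_2)/(H_{2max} - H_{2min})$, and Horn
  niche overlap per trophic level.
- **Species-level indices** — degree, specialization d' (standardized
  Kullback-Leibler divergence from partner availability), effective
  partners $e^{H}$, species strength.
- **Null models** — Patefield fixed-marginal randomizations
  (`stats::r2dtable`), add-one p-values, and z-scores with the z >= 2
  modularity rule.
- **Traits and ordination** — wood density, percent daily decomposition,
  body-size index, and a correlation-matrix PCA of traits against network
  roles with the |r| >= 0.6 loading rule; Kruskal-Wallis treatment
  comparisons.
- **Synthetic data** — a seeded generator of rearing experiments with
  latent modules, a nestedness gradient, tunable specialization and
  cross-treatment species retention, so the whole pipeline runs and is
  testable without field data.

## Worked example

```r
library(rearnet)

ds   <- generate_dataset(tdf_preset(seed = 20260923))
nets <- build_networks(ds$records)
nets
#> treatment_network_set:
#>   Rc: 22 hosts x 21 beetles, 236 emergences
#>   Rg: 28 hosts x 20 beetles, 252 emergences
#>   Dc: 47 hosts x 40 beetles, 459 emergences
#>   Dg: 41 hosts x 31 beetles, 366 emergences

network_structure(nets$Rc, n_trials = 20, seed = 7)
#>   hosts beetles network_size emergences    wnodf         Q  h2_prime
#> 1    22      21           43        236 8.486035 0.5889292 0.5925335
#>   niche_overlap_beetle niche_overlap_host
#> 1            0.1486214          0.1590704

null_test(nets$Rc, "modularity", n_rand = 200, seed = 11)
#> null_ensemble 'modularity': obs 0.5889, null 0.2175 +/- 0.0019 (n_rand 200)
#>   p = 0.004975 (upper tail), z = 193.23  [significant]
```

The structure row reads: a 43-species network whose interactions are
moderately nested (WNODF 8.5 on a 0-100 scale), organised in modules
(Q 0.59, far above the fixed-marginal null), specialized (H2' 0.59 of the
way from no selectivity to the maximum the marginals allow), with beetles
sharing little of their host niche (overlap 0.15).

The numbered scripts under `analysis/` run the same stages over a
simulated campaign and write tables under `results/`:
`01_simulate.R` (records, traits, latent truth), `02_diversity.R`,
`03_beta.R`, `04_structure_nulls.R`, `05_species_traits_pca.R`.

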