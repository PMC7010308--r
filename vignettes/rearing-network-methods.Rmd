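---
title: "Methods: spatio-temporal analysis of rearing interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal analysis of rearing interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system and the data model

`rearnet` analyses commensalistic interaction networks between wood-boring
beetles (Cerambycidae) and their host trees, assembled from rearing
experiments: branch sections of known tree species are exposed in the field
under four spatio-temporal treatments — rain-canopy (Rc), rain-ground (Rg),
dry-canopy (Dc), dry-ground (Dg) — then isolated, and every adult beetle
that emerges is attributed to the branch (and so the host species) it
developed in. The elementary datum is a long-format record
`(treatment, host, beetle, count[, interval])`; counts are whole emerged
individuals. Records aggregate by summation into one weighted host x beetle
matrix per treatment. Two conventions are fixed package-wide: rows are
hosts and columns are beetles, and labels sort lexicographically, so every
output is byte-stable. A species belongs to a treatment's network only if
at least one individual emerged there: all-zero rows and columns are
trimmed at construction, which never changes the grand total. Emergences
from the four collection intervals (2, 4, 6, 8 months) are pooled by
default; the interval column is retained so users can subset before
building networks if they want within-season resolution.

## Diversity

Per treatment, beetle abundances are the column totals (host diversity is
available but not the default, since the comparison of interest is the
beetle assemblage). Diversity is reported as Hill numbers
$^qD = (\sum_k p_k^q)^{1/(1-q)}$ for $q \in \{0, 1, 2\}$: richness,
exponential Shannon, inverse Simpson. Confidence intervals are percentile
intervals over 100 multinomial bootstrap resamples of the $n$ observed
individuals. No unseen-species correction is applied: the generator (and
the motivating design) operates at sample coverage well above 97%, where
the plug-in estimator is essentially unbiased; coverage itself is reported
via the Good-Turing singleton/doubleton estimator
$\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2f_2}$.
Treatments are compared by CI overlap: treatments whose intervals overlap,
directly or through a chain, share a significance letter (connected
components of the overlap graph), lettered by descending estimate. With
equal abundances the point estimate is the attainable maximum of $^1D$, so
the upper percentile can sit marginally below it; the package treats the
invariant `ci_low <= estimate <= ci_high` as holding to Monte-Carlo
tolerance.

## Beta diversity and interaction dissimilarity

Composition change between treatment pairs uses the Sorensen partition:
with $a$ shared and $b, c$ unique species,
$\beta_{sor} = (b+c)/(2a+b+c)$, turnover
$\beta_{sim} = \min(b,c)/(a+\min(b,c))$, and the nestedness-resultant
component $\beta_{sne} = \beta_{sor} - \beta_{sim}$, exactly additive by
construction. Interaction change uses binary link sets: $\beta_{WN}$ is the
Sorensen dissimilarity of the full link sets, $\beta_{OS}$ the same measure
restricted to links among species present in both networks (rewiring), and
$\beta_{ST} = \beta_{WN} - \beta_{OS}$ the contribution of species
turnover. Weighted variants are deliberately out of scope; binarization
makes $\beta_{OS}$ invariant to count magnitudes, which is tested. When two
networks share no species the rewiring term is undefined in the framework;
the package sets $\beta_{OS} = 0$ with a warning so the decomposition stays
additive. Summaries over the six treatment pairs report mean and sample SD
($n-1$); the sample-SD convention is validated by the cross-treatment
arithmetic of the reference structure table shipped in `extdata`.

## Network structure

**WNODF.** Rows and columns are sorted by decreasing marginal totals (ties:
decreasing number of non-zero cells, then label). A pair (i above j) with
strictly larger total scores $100 \times$ the fraction of j's non-zero
cells that are positive but strictly below i's corresponding cells; equal
totals score 0. WNODF is the mean over all row and column pairs, 0-100.

**Modularity.** Barber's weighted bipartite modularity
$Q = \frac{1}{m}\sum_{ij}\left(a_{ij} - \frac{r_i c_j}{m}\right)
\delta(g_i, g_j)$ is maximized by alternating label propagation (each
column, then each row, adopts the label with the largest gain; ties to the
smallest label), followed by an agglomerative phase that merges module
pairs while $Q$ increases. The search restarts from a
unique-label-per-host start plus seeded random initializations with
constrained module counts (20 trials by default) and reports the best $Q$
found. On all tiny matrices the suite checks the result against an
exhaustive search over every set partition of the nodes.

**H2'.** Interaction specialization standardizes the Shannon entropy of the
interaction proportions between the entropy extremes achievable by integer
tables with the observed marginals:
$H_2' = (H_{2max} - H_2)/(H_{2max} - H_{2min})$, clamped to $[0, 1]$. For
small webs (at most 16 cells, $m \le 40$) both extremes are computed
exactly by bounded exhaustive search over all integer tables with those
marginals. Larger webs use deterministic heuristics: $H_{2max}$ by
proportional apportionment of the independence table $r_i c_j / m$ (floor,
then repair marginal deficits at the largest fractional parts),
$H_{2min}$ by two greedy concentration schemes (largest-row with
largest-column, and largest-row with closest-fitting column), each refined
by 2x2 exchange hill-climbing on webs up to 64 cells, keeping the better
result. A continuous independence-table upper bound was considered for
$H_{2max}$ and rejected: at small totals it overshoots the integer optimum
enough to bias $H_2'$ upward by more than 0.1, outside the enumeration
tolerance the suite enforces (0.05). The extremes depend only on the
marginals and are memoized, so a null ensemble (thousands of tables with
one marginal set) pays the cost once.

**Niche overlap.** Horn's information-theoretic overlap for each unordered
species pair of a trophic level, on normalized usage vectors $p, q$:
$R = [\sum (p+q)\log(p+q) - \sum p\log p - \sum q\log q] / (2\log 2)$,
averaged unweighted over pairs (one value per level per network). The suite
cross-checks it against an independent Jensen-Shannon formulation.

**Species-level indices.** Degree; effective partners
$e^{H(p)}$; species strength (sum over partners of the partner's
proportional dependence, so host strengths sum exactly to the number of
beetle species); and $d'$, the Kullback-Leibler divergence of a species'
usage from partner availability $q_j = c_j/m$, standardized by
$d_{max}$ — the divergence of the best integer allocation of the species'
total onto the least-available partners (exhaustive over allocations for
totals up to 8, where it provably concentrates on the rarest partner;
direct concentration otherwise) — with $d_{min} = 0$ and clamping to
$[0, 1]$. Using 0 for $d_{min}$ slightly inflates $d'$ for species whose
availability-proportional allocation is not integer-attainable; this was
preferred over a heuristic minimum table because it keeps $d' = 0$
interpretable as "uses partners in proportion to availability".

## Null models

Significance uses the fixed-marginal (Patefield) null: random contingency
tables with the observed row and column totals, i.e. the multiple
hypergeometric distribution, drawn via `stats::r2dtable` (the same
algorithm the field's tooling wraps). Defaults follow the reporting
conventions of rearing-network studies: 1000 randomizations; add-one
p-values $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{rand})$ with
the tail auto-selected by the sign of the observed departure (the
convention is stated in the report because tail choice is not standardized
in the literature); significance at $p < 0.01$ for WNODF, H2' and overlap;
and a z-score rule $z \ge 2$ for modularity, with sample-SD in the
denominator. Null modularity re-optimizes each table with a reduced
5-restart search — re-optimization is the faithful (and costly) choice; the
reduced restart count biases null $Q$ slightly downward, which makes the
$z \ge 2$ call marginally liberal and is the main caveat on modularity
significance.

## The synthetic generator

The generator emulates the field design so the full pipeline runs without
the (unpublished) raw matrices: four treatments with configurable host and
beetle richness; species pools drawn from a regional pool sized
`round(mean(n)/rho)` so any two treatments share an expected fraction
`rho` of species (an explicit pool override reproduces the 65-host /
57-beetle regional pools of the motivating design; `rho` requests that
cannot fit the largest treatment error out). Each beetle has a lognormal
latent abundance and a Dirichlet($\kappa$)-style host preference,
up-weighted by a factor for hosts in its own latent module (K modules,
labels persistent across treatments with configurable rewiring) and by an
exponential gradient over host popularity ranks (nestedness). Counts are
Poisson with rate abundance x preference (a negative-binomial switch adds
overdispersion; off by default, as emergence tallies from isolated branch
sections show no obvious extra-Poisson clustering), then split
multinomially over the four collection intervals. Host wood density is
lognormal around 0.6 g/cm^3, decomposition rate is lognormally distributed
with a configurable negative association to realized degree, and beetle
body size is lognormal around 35 mm^2 — magnitudes a tropical dry forest
survey would call unremarkable. All randomness derives from one seed with
fixed per-treatment sub-streams, so a fixed seed is byte-reproducible.

The preset targets the motivating design's magnitudes (richness 22/28/47/42
hosts and 21/22/40/34 beetles, ~1,323 emergences, $\kappa = 0.3$, K = 4,
module boost 10, gradient 0.5, retention pools as above); realized sizes
sit within a few percent of the targets because species whose Poisson
draws are all zero are trimmed. What the generator does *not* emulate:
phylogenetic signal in host use, temporal autocorrelation within a season,
spatial arrangement of branches, and abundance-driven detectability — so
green tests certify the statistical machinery and the recoverability of
the generator's own latent structure, not fidelity to any particular
forest.

## Ordination and treatment comparisons

The trait stage computes wood density (dry weight / dry volume, g/cm^3),
percent daily decomposition (percent mass lost per exposure day — the
quantity's name fixes the reading; a literal "mass remaining per day"
variant is available behind a flag because the formula is typeset
ambiguously in parts of the literature), and beetle body-size index
(length x width, mm^2), each averaged per species. The correlation PCA
standardizes variables, eigen-decomposes the correlation matrix, reports
loadings as variable-component correlations $v_{jk}\sqrt{\lambda_k}$, and
flags variables at $|r| \ge 0.6$ — absolute value, because negative
loadings of that magnitude are equally "related" and component signs are
orientation-arbitrary (each component is oriented so its largest loading
is positive, for stable output). Beetle PCAs use degree, $d'$, effective
partners and BSI; host PCAs use degree, $d'$, species strength, wood
density and decomposition rate. Species-level indices are compared across
treatments with Kruskal-Wallis tests (`stats::kruskal.test`).

## Problem sizes and numerical choices

The shipped analysis scripts and the test suite run the preset networks
(up to 47 x 40) with 100 bootstrap replicates, 200 null randomizations in
the scripts (1000 remains the package default), and 20 modularity
restarts; parameter-recovery checks use 30 seeded replicates of 9 x 9 to
12 x 12 networks, sizes at which every metric has an exact or enumerative
oracle. Label propagation converges when a sweep improves $Q$ by less than
1e-10; clamping guards H2' and $d'$ against negative zero-width
denominators; degenerate inputs (single-cell webs, constant null
distributions, no shared species) return defined values with warnings
rather than NaN, and those conventions are part of the tested contract.
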