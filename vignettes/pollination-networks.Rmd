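---
title: "Individual-based pollination networks: models, null models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-based pollination networks: models, null models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The model of the system

Nodes are *individual plants* of one species, not species. Two plants are
linked when at least one pollinator species visited both; the link is the
potential for pollen transfer between them. Formally, from a binary incidence
matrix $M$ (plants $\times$ pollinator species) we take the unipartite
projection: the multiplicity of pair $(i,j)$ is
$|\{k : M_{ik} = M_{jk} = 1\}|$, self-loops excluded. All survey-level
architecture metrics are computed on the *simple reduction* (multiplicity
collapsed to 0/1), because the defining formulas — connectance as a
proportion of possible lines, degree as neighbourhood size, CC1 clustering —
are simple-graph quantities. Multiplicities are retained for export
(parallel lines in Pajek `.net`, edge weights in GraphML) and for users who
want weighted analyses elsewhere.

Three architecture axes are quantified:

- **Nestedness** (NODF): whether the pollinator sets of sparsely visited
  plants are subsets of those of richly visited plants. For every unordered
  pair of rows (and of columns) of $M$ with *strictly* different fills, the
  paired value is the percentage of the poorer line's presences found in the
  richer line; ties contribute zero; NODF is the mean over all row and
  column pairs (0–100).
- **Connectivity**: mean degree $\bar k$, normalized degree
  $\bar k / (n-1)$ with its standard error of the mean, and connectance
  $L / \binom{n}{2}$. These satisfy the identity
  connectance $= \bar k/(n-1)$, which the tests assert on every random graph.
- **Transitivity**: CC1 clustering, $C_i = e_i / \binom{k_i}{2}$ with
  $C_i := 0$ when $k_i \le 1$. The zero convention keeps the network average
  defined on sparse graphs; it mirrors the convention of the network tools
  this analysis descends from. The alternative (dropping such nodes) changes
  $\bar C$ on sparse networks — a caveat when comparing across software.

On the pollinator side, species are grouped into eight functional groups
(large bees, small bees, wasps, beeflies, hoverflies, beetles, butterflies,
other). The **functional specialization** FS of group A toward group B is
the mean, over A's species, of the mean shortest-path distance to B's
species in the pollinator projection; disconnected pairs are excluded from
the means with a warning (the alternative — imputing a large finite
distance — injects an arbitrary constant). **Hub scores** are
Kleinberg-style hub/authority scores; on a symmetric adjacency these
coincide with principal-eigenvector centrality, computed here by power
iteration on $A^2$ (the HITS update collapsed onto itself), which also
converges on bipartite-like components where iteration on $A$ would
oscillate. Tolerance $10^{-10}$ on the max absolute change, 1000 iterations,
error on non-convergence. Which exact "hub degree" routine the original
field analysis used is not recorded; eigenvector/HITS is our documented
choice.

## 2. Null models

Two distinct randomizations answer two distinct questions.

**CE null (for nestedness).** Cell $(i,k)$ is present with probability
$p_{ik} = \tfrac12 (P_i/C + P_k/R)$ — the average of its row and column fill
proportions. Observed NODF is compared against `reps` independent draws;
the p-value uses the add-one rule $(1+b)/(\text{reps}+1)$ and is never 0.
*Relative nestedness* is $(\text{NODF} - \overline{\text{null}})/
\overline{\text{null}}$. Draws with an all-zero row or column would hand
NODF degenerate lines, so they are redrawn (cap 1000, then an error advising
a denser matrix). The redraw conditioning slightly inflates expected fill in
small sparse matrices; in the regimes used here the effect is below the 2%
tolerance the tests assert.

**Random-visitation null (for connectivity and clustering).** To emulate
pollinators visiting plants with no phenotypic choosiness, each species
$k$ gets an interaction frequency $f_k$; a master matrix of
`master_rows` (default 100 000) virtual plants is filled with independent
Bernoulli($f_k$) columns, and `reps` (default 1000) subsamples of the
empirical plant count are drawn without replacement, projected, and
measured. $f_k$ defaults to *presence frequency* (share of empirical plants
the species visited), which preserves expected species prevalence in null
networks; a visit-count-based variant is available
(`frequency = "visits"`). Desk-scale runs (tests, examples) use a 10 000-row
master — a documented size deviation that leaves the distribution of
subsampled networks essentially unchanged since rows are independent.

**A calibration subtlety.** When the tested matrix is itself generated from
the random-visitation model, one may ask whether the test rejects at the
nominal 5% rate. It does — *if the ensemble is driven by the generating
frequencies* (`frequencies =` / `probs =` arguments), which makes observed
and null draws exchangeable. With frequencies re-estimated from the tested
matrix (the default, and the only option on field data), the observed
marginals sit exactly at the null's expectation while the null draws
scatter around it; because the projection metrics are convex in the column
fills, null values are biased upward and the one-tailed test becomes
strongly conservative (we measured a 0/200 rejection rate at $\alpha=0.05$).
The practical consequence: a significant result against this null is
trustworthy; a non-significant one is weak evidence of randomness. The
calibration tests in `test-acceptance.R` therefore supply the generating
frequencies, and this distinction is the reason those arguments exist.

## 3. Spatial statistics

Per-population performance is related to architecture with the
lagged-predictor spatial autoregression
$y = \rho W y + X\beta + WX\gamma + \varepsilon$. Estimation profiles
$\rho$ over its feasible interval (bounded by the reciprocal extreme
eigenvalues of $W$, which enter the log-Jacobian
$\log|I - \rho W| = \sum_i \log|1-\rho\lambda_i|$), then solves for
$\beta, \gamma$ by least squares on the filtered response. Standard errors
come from the inverse observed information (numeric central-difference
Hessian of the full log-likelihood); with `rho` fixed the fit collapses
exactly to OLS with classical standard errors, which the tests assert to
$10^{-6}$. Slope significance is asymptotically normal by default, with an
optional permutation test.

Design choices worth knowing:

- **Weight schemes.** Inverse distance (row-standardized) is the default for
  analysis; but in *parameter-recovery experiments* we use the Gabriel
  neighbour graph, because under a dense all-positive $W$ the autoregression
  parameter is weakly identified at $n = 50$ (measured 2-SE coverage ~0.89
  versus ~0.94–0.96 under Gabriel weights). The estimator is identical; only
  the experimental design differs.
- **Small samples.** At the field design's scale ($n = 8$ populations) SAR
  inference is fragile; the fit warns below $n = 10$ and the validation
  tests use $n = 30$–50 from the generator. At $n=30$ the asymptotic z-test
  is mildly anticonservative (null rejection ~0.1 rather than 0.05 in our
  end-to-end runs), which is why the null-coupling acceptance bound is 0.18
  rather than 0.05.
- **Residualization.** Because connectivity metrics depend on pollinator
  abundance and richness, connectance enters the performance model as OLS
  residuals on pollinator abundance, clustering as residuals on richness,
  before SAR fitting — so an architecture effect is not a disguised
  abundance effect.

Assemblage-composition correlates use the **partial Mantel test**: Spearman
partial correlation between the off-diagonal entries of a metric-difference
matrix and an assemblage dissimilarity matrix (Bray–Curtis or
Morisita–Horn), controlling geographic distance, with significance from
simultaneous row/column permutations of the first matrix (1000 by default;
only the permutation count, not the scheme, was recorded in the original
analysis — permuting the first matrix's objects is our documented choice).
The p-value again uses the add-one rule.

## 4. What the synthetic generator emulates — and what it does not

`simulate_study()` produces a full multi-population study with the
statistical structure the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_pops` | 8 | populations (km-scale coordinates in a 50-km square) |
| `n_plants` | 90 | plants marked per population (30 m plot) |
| `species_range` | 31–41 | per-population pollinator pool size |
| `surveys`, `minutes_per_plant` | 6, 5 min | census design (five-minute intervals) |
| `visit_rate` | 0.16 /plant-min | pool-total visit rate; calibrated once so mean per-plant richness ≈ 4 |
| `abundance_shape` | 0.7–1.2 | lognormal sdlog of species abundances |
| `architecture_effect` | 2 | log-fruit effect per unit normalized degree |
| `noise_sd`, `pop_noise_sd` | 0.3, 0.15 | plant-level and population-level (spatially autocorrelated) log-noise |
| `seeds_planted` | 10 | emergence-trial seeds per maternal plant |

Visits are Poisson given rate × minutes × flower attractiveness — the
simplest count process consistent with timed censuses. Foraging modes
modulate plant choice: *indiscriminate* species (beeflies) spread over all
plants by flower display; *distance-limited* species (hoverflies) weight
plants by an exponential kernel (range 5 m) around a per-survey anchor;
*within-plant* foragers (beetles) see only a small random plant subset per
survey. These kernels are stylized: the field literature describes the
contrast qualitatively, so the generator's job is to reproduce the *ordering*
(indiscriminate foragers produce better-connected plant networks than
within-plant foragers — a tested invariant), not movement trajectories.

The fitness chain is multiplicative, following the field protocol: seeds per
fruit are binomial over 25 ovules with SO ratio 0.6; fruits are Poisson with
log-mean shifted by `architecture_effect` × latent connectivity (the plant's
normalized degree in the realized, filtered network) plus autocorrelated
noise; emergence and survival rates come from binomial trials on 10 planted
seeds; juveniles = seeds × survivors / planted. `architecture_effect = 2`
was fixed a priori so that the realistic connectivity span (~0.4) yields
roughly two-fold performance differences between extreme populations,
matching the several-fold spread of recruitment seen across real
populations; `architecture_effect = 0` severs the coupling, which the
end-to-end null test exercises.

What a green test does **not** establish: the generator's networks are
denser (connectance ~0.2–0.6) than the field networks (~0.16–0.37); real
visitation is zero-inflated and temporally structured (weather, phenology)
where the generator is Poisson and stationary; real pollinator taxonomy,
phenology and greenhouse environments are not modelled; and pollen transport
itself is never simulated — shared pollinators remain a *proxy* for mating.
Green acceptance tests establish that the formulas are implemented exactly
(oracle equivalence), that the null machinery is calibrated, and that a
coupling injected at the plant level is recovered at the population level by
the full pipeline — not that the field system behaves like the generator.

## 5. Numerical and convention details

- The census filter is *strict*: a plant watched exactly 15.0 minutes is
  excluded; "at least one visit" means total visits ≥ 1 over all surveys.
  Filtering is idempotent, and plants that pass the filter but share no
  pollinator stay in the network as isolates (they are censused plants and
  belong in degree/connectance denominators).
- Node orderings are radix-sorted everywhere; outputs carry provenance
  headers (package version, seed, config digest) and no timestamps, so the
  whole pipeline is byte-identical under a fixed seed — asserted by the
  determinism test.
- Empirical p-values are never 0 (add-one rule); all-zero matrices have
  NODF defined as 0 with a warning; degenerate ANOVA (zero within-group
  variance) and all-zero interaction frequencies raise errors rather than
  returning NaN.
- Every stochastic operation takes an explicit `seed` and restores the
  caller's RNG state; child seeds are derived arithmetically and kept below
  $2^{31}$.

## 6. Known limitations

- SAR at $n = 8$ reproduces the original analysis *structurally*; its
  standard errors at that size should not be taken inferentially (the fit
  warns).
- The random-visitation null is conservative when frequencies are estimated
  from the tested data (section 2) — inherent to the procedure, not fixable
  without external frequency information.
- Weighted (visit-count) projection metrics and degree-preserving swap
  nulls are out of scope, as are species-accumulation corrections of
  richness.
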