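---
title: "From size-fractionated ASV tables to interdomain network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From size-fractionated ASV tables to interdomain network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracnet)
```

## The analysis, end to end

`fracnet` models how the structure of a coastal microbial food web — bacteria
plus two size classes of protists (pico, 0.8–2 µm, and nano, 2–20 µm) —
responds to its environment. The pipeline runs seven stages:

1. **Cross-fraction filtering.** An ASV observed in both protist size
   fractions is usually a filtration artifact (cell dislodging, filter
   clogging). For each shared ASV we compute the ratio of its mean relative
   abundance in the nano fraction to that in the pico fraction; a ratio
   strictly above 2 removes it from pico, strictly below 0.5 from nano,
   anything between keeps it in both. ASVs entering network inference must
   additionally occur in every season, in strictly more than 1/3 of samples,
   and at mean relative abundance strictly above 0.001.
2. **Diversity.** Shannon entropy (natural log), Chao1 richness
   (bias-corrected by default, so samples without doubletons are defined)
   and Pielou's evenness per sample; Bray–Curtis dissimilarities on
   Hellinger-transformed tables; NMDS ordination; PERMANOVA across seasons;
   Mantel and partial Mantel tests against environmental distances.
3. **Niche breadth.** Levins' index per ASV, `B = 1 / sum(P^2)`, computed
   within seasonal metacommunities, and its unweighted mean over the ASVs
   present in each sample as the community-level value.
4. **Network inference.** Modified CLR transform per fraction, then
   neighborhood (nodewise lasso) selection with StARS stability selection
   over a 20-point geometric penalty path (minimum ratio 0.005, instability
   threshold 0.05, 20 subsamples).
5. **Stability.** Topology metrics, keystone taxa, random-attack robustness
   `R` (10,000 random removal orders) with vulnerability `V = 0.5 − R`, and
   nodal/global efficiency.
6. **Biomass.** Cytometry/microscopy abundances × per-cell carbon factors
   (HB 20, Syn 178, PPE 1,500, HNF/PNF 4,700 fg C cell⁻¹), and the
   log10 predator/prey biomass ratios HNF/HB and HNF/PPE.
7. **Structural model.** A PLS path model linking water properties and
   nutrients to diversity, niche breadth, PPBR, and the seasonal networks'
   robustness and efficiency, with 1,000 bootstrap resamples and iterative
   removal of indicators loading below 0.7.

## Statistical models and their assumptions

### Compositional network inference

Amplicon counts are compositional: only relative information survives
sequencing, and naive correlations between relative abundances are biased.
We therefore transform counts with a *modified* centered log-ratio (mCLR):
non-zero entries are log-transformed and centered by the geometric mean of
the row's non-zero entries, zeros stay zero. This avoids a pseudocount whose
value would be arbitrary, at the cost of treating zeros as exact. The
transform is per-row scale invariant, so counts and relative abundances are
interchangeable here.

Conditional-dependence edges are estimated by Meinshausen–Bühlmann
neighborhood selection: each node is lasso-regressed on all others, and an
edge exists when either regression selects the partner (OR rule; the AND
rule is available). The OR rule is the default because it preserves more of
the sparse interdomain edges, which is where the scientific interest lies.
The penalty is chosen by StARS: over 20 random subsamples of size
`min(10·sqrt(n), 0.8·n)` we track each edge's selection frequency ξ along
the penalty path and define instability as the mean of `2ξ(1−ξ)` over all
node pairs; the selected penalty is the smallest whose monotonized
instability stays at or below 0.05. The per-node lasso fits use glmnet; the
subsampling, instability and selection logic, and the symmetrization are
implemented here.

A latent-variable (sparse + low rank) refinement of the inverse-covariance
model exists for confounded designs; its rank and solver are additional
free choices, so this package deliberately ships the canonical MB+StARS
member of the same framework and records the method in the network's
metadata. The inference honors the four standard printed parameters
(nlambda 20, minimum ratio 0.005, threshold 0.05, 20 subsamples).

StARS needs at least ~20 rows to subsample meaningfully. The seasonal
sub-networks in the shipped synthetic scenario have 10 samples each; the
function runs from 8 rows upward but warns below 20, and those warnings are
logged in the pipeline manifest. Interpret per-season networks from small
n as illustrative rather than inferential.

### Attack robustness and efficiency

Robustness removes nodes one at a time in a uniformly random order and
tracks σ_i, the relative size of the largest remaining connected component
after the i-th removal. `R` is the mean of σ over all N removal steps,
averaged over 10,000 random orders (a union-find over reverse insertions in
compiled code, so the default iteration count is cheap); `V = 0.5 − R`
exactly. For a complete graph σ after i removals is `(N−i)/N` regardless of
order, giving the closed form `R = (N−1)/(2N)` — the ceiling `0.5` explains
the normalization of `V`. Nodal efficiency is the mean inverse shortest-path
length to all other nodes (`1/∞ = 0` across components), computed on the
unweighted graph: edge weights are association strengths, not distances,
so weighting path lengths by them has no clear meaning.

Keystone taxa are nodes in the top 20% of *both* degree and betweenness.
The cutoff is the k-th largest value with `k = ceiling(0.2 N)`, ties
inclusive: in a star the hub alone qualifies, in a regular ring every node
does. A rank-from-the-bottom percentile would let the tied low values of a
skewed centrality distribution drag the whole graph in, which is why the
threshold is anchored at the top of the distribution.

### Permutation inference

All permutation tests use the add-one rule `p = (1 + #{perm ≥ obs}) /
(1 + n_perm)`, so p-values are never zero and are reproducible under a
seed. PERMANOVA uses Anderson's distance-based sums of squares with free
label permutation (the design is single-factor). The Mantel statistic
defaults to Spearman correlation of the distance upper triangles (Pearson
available); the partial Mantel uses the first-order partial correlation
formula, permuting only the first matrix. When the control matrix is
collinear with one of the tested matrices the partial correlation is
undefined; it is reported as 0.

### NMDS

Ordination minimizes Kruskal stress-1 by alternating isotonic regression
(disparities monotone in the observed dissimilarities) with a Guttman
transform update; both steps are non-increasing in stress, and the first
start is the classical metric-MDS configuration, with random restarts after
it. Non-convergence returns the best configuration found, flagged.

### PLS path modeling

All blocks are reflective (mode A): the latent is understood to cause its
indicators, which matches treating loadings as meaningful and pruning
indicators that load below 0.7. Estimation is Lohmöller's alternating
algorithm with the path weighting scheme by default (centroid and factor
available). Path coefficients are standardized OLS coefficients among the
latent scores; with single-indicator blocks the whole model collapses to
ordinary standardized path analysis, which the tests exploit as an exact
oracle. `gof = sqrt(mean communality × mean R²)`. Bootstrap confidence
intervals are percentile intervals; a path is significant when its interval
excludes zero. Each latent's sign is anchored so that its loadings sum to
a positive value, preventing sign flips across bootstrap resamples.

Network robustness and efficiency are one number per seasonal network; they
enter the per-sample model broadcast to that season's samples. That makes
their indicators 4-valued step functions — a deliberate, recorded
approximation that is the only way a per-sample structural model can
include network-level properties.

## The synthetic scenario

The generator produces data with the statistical structure the pipeline
assumes, plus known ground truth:

- **Counts** follow a logistic-normal-multinomial: latent log-abundances of
  the "core" ASVs (20 per fraction by default) are multivariate normal with
  covariance the inverse of a known sparse precision matrix (chain by
  default), softmax-ed within each fraction and sampled multinomially at a
  negative-binomial depth (mean 20,000, size 20), then Bernoulli
  zero-inflated (rate 0.1). The support of the precision matrix is the
  ground-truth edge set.
- **Noise ASVs** (40 per fraction) have independent latent log-means drawn
  from N(−4, 1.5), placing most below the 0.001 mean-abundance filter, as
  rare taxa are in real tables; after filtering, roughly 60–75 ASVs enter
  network inference.
- **Environment**: season-specific means chosen as realistic values for a
  subtropical mariculture bay (e.g. temperature 16/21/28/23 °C across
  winter/spring/summer/autumn; DO anti-correlated with temperature), with
  Gaussian noise; a `season_effect` multiplier scales all seasonal contrasts
  and zero gives exact nulls for calibration tests.
- **Cytometry**: log-normal abundances around group levels (HB 10⁶,
  Syn 10⁵, PPE 10⁴, HNF/PNF 10³ cells mL⁻¹) with a log10-linear coupling to
  standardized temperature.
- **Contamination**: a scaled copy of a pico ASV's profile is inserted into
  the nano table so the realized nano/pico mean relative-abundance ratio
  hits a prescribed target — exactly the artifact the ratio filter removes,
  with copying (not resampling) keeping the target controllable.
- Seasons are categorical blocks; there is no temporal autocorrelation, no
  taxonomic mis-assignment, no chimeras, and no read-level error model.
  Passing tests on these data demonstrate the estimators' correctness and
  calibration, not robustness to artifacts the generator does not emulate.

```{r scenario, eval = FALSE}
scen <- synthetic_scenario(seed = 7)
sim <- generate_counts(scen)
env <- generate_env_table(scen)
sel <- select_network_asvs(sim$bacteria)
net <- stars_select(mclr_transform(sel$counts), seed = 7)
```

## Numerical choices and degenerate inputs

- Shannon uses natural log; Pielou is NA for samples with fewer than two
  ASVs; Chao1 falls back from the classic to `F1(F1−1)/2` when there are
  singletons but no doubletons.
- All-zero samples stay all-zero through relative abundance, Hellinger and
  mCLR, and are flagged; a pair of all-zero samples has Bray–Curtis 0 by
  convention, flagged.
- Relative abundances are always computed against the sample totals
  recorded when a table is created, so ASV filtering never silently
  renormalizes: the 0.001 threshold and the 2/0.5 ratios always refer to
  the whole community, and both filters are idempotent.
- Boundary values are resolved by strict inequalities (ratio exactly 2 or
  0.5 kept; mean abundance exactly 0.001 dropped; prevalence exactly n/3
  dropped).
- Ratio of a shared ASV with zero pico mean but positive nano mean is +∞
  (removed from pico); zero in both fractions means no action.
- In lasso fits, columns constant within a subsample standardize to zero
  columns rather than NaNs; if no penalty meets the instability threshold
  the sparsest penalty is returned with a warning.
- Bootstrap replicates whose resample makes an indicator constant are
  skipped and counted.

## Problem sizes

The shipped default scenario — 4 seasons × 10 samples, 3 fractions, 60 core
plus 120 noise ASVs, 20-point penalty path with 20 subsamples, 10,000
robustness iterations, 1,000 bootstrap resamples — runs the full pipeline
in about a minute and a half on a single core. Recovery and calibration
tests use p = 30 nodes at up to n = 1600 samples, 500-replicate null
simulations, and 200-replicate bootstrap coverage runs; these sizes give
stable Monte-Carlo estimates while keeping the whole suite comfortably
runnable on a laptop.

## Known limitations

- MB+StARS rather than a latent-rank variant (see above); compositional
  closure also means that with very few taxa (p ≲ 15) the mCLR cannot fully
  remove induced negative dependence — network inference is meant for the
  post-filter regime of tens to hundreds of taxa.
- Permutation tests assume exchangeability under the null; no strata or
  repeated-measure structure is modeled.
- The broadcast of network-level robustness/efficiency to samples limits
  the effective degrees of freedom of those blocks to the number of
  seasons.
- Chao1 is a lower-bound estimator and is biased for heavily zero-inflated
  counts; it is reported as conventionally defined.
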