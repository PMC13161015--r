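---
title: "Methods: from flock lists to trait models of nuclearity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from flock lists to trait models of nuclearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`flocknet` estimates how phenotypes relate to a species' structural role in
mixed-species flock networks. This vignette explains each stage's model and
assumptions, the tunable parameters and their defaults, the synthetic-data
generator and what it does and does not emulate, and the numerical choices
made where several reasonable options existed.

## Flock data and filters

The unit of observation is a flock: one row of a locality's binary
flock × species table. Two filters define the analysable data:

* flocks must hold at least 3 species (`min_species = 3`) — smaller
  aggregations are not treated as mixed-species flocks;
* species must occur in at least 3 flocks dataset-wide (`min_flocks = 3`) —
  rarer records are anecdotal.

Removing a rare species can drop a flock below 3 members, and removing that
flock can push another species below 3 occurrences, so `filter_species()`
iterates both rules to a fixed point; the returned matrices satisfy both
constraints simultaneously. The iteration is a design choice: stopping after
one pass can leave flocks that violate the richness rule after column
removal.

**Flocking propensity** is the proportion of flocks a species was detected
in. The default denominator is every flock in the dataset
(`denominator = "global"`, the literal pooled reading); the alternative
`"range"` counts only flocks at localities where the species was recorded,
which is less sensitive to geographic sampling imbalance. Both numerator and
denominator are reported so the choice is auditable. Propensity is
natural-log transformed; no zero-guard is needed because retained species
have at least 3 occurrences.

## Network metrics

Each filtered matrix is projected to a weighted unipartite graph with
`w(i, j)` = number of shared flocks. Connectivity is degree / (S − 1), with
S the species present in that locality's network; strength is the row sum of
weights; closeness uses edge lengths `1/w`, so frequent partners are near
neighbours. On disconnected graphs raw closeness is undefined (infinite
distances), so we use the Wasserman–Faust scaling
`(R/(S−1)) · (R/Σ d)`, with R the number of reachable nodes: members of
small components get low but finite values, isolated nodes 0, and values
remain comparable across localities of different size. A raw
within-component value can be recovered by multiplying by `(S−1)/R`.

Per-species metrics are averaged across occupied localities with a plain
arithmetic mean — unweighted by locality size, treating each locality as one
realization of the species' role. The alternative reading, computing
closeness on a single pooled metanetwork, is available via
`pool_networks()` but is not the default: pooling mixes localities with very
different sampling effort into one graph and breaks the parallel treatment
of the three metrics.

## Null models and z-scores

The null hypothesis is random assembly given flock sizes and species
frequencies: binary matrices with exactly the observed row and column sums.
Sampling uses curveball trades — two random rows exchange a random subset of
the species exclusive to each — whose stationary distribution is uniform on
the fixed-margin set. Each replicate is an independent chain of
`5 × (number of presences)` trades from the observed matrix
(`trades_factor = 5`); the suite checks empirical uniformity against an
exhaustively enumerated margin set. Matrices whose margins admit a single
matrix (no 2×2 checkerboard submatrix) are detected exactly and returned
unchanged with a warning.

Seeds are managed hierarchically: one master seed yields a deterministic
per-locality seed, which yields a per-replicate seed, so any single
replicate can be reproduced in isolation without regenerating the ensemble.

z-scores standardize each observed species–locality–metric value by the
null mean and SD over `n_reps = 500` replicates. A zero null SD (degenerate
margins) yields `NA`, not 0 — a zero-variance null carries no
standardization information — and such cases are counted in a message and
excluded from models. z-scores are computed per locality and then averaged
per species, mirroring the averaging of the observed metrics; standardizing
an averaged metric against an averaged null would instead mix localities
with different null scales.

## Trait predictors

The 12 plumage color-coverage categories are grouped by pigmentary or
structural origin: structural = blue + purple; carotenoid-based = yellow +
orange + red + pink; melanin-based = black + grey + brown + rufous; green
and white pass through. The package's data dictionary places pink with the
carotenoid class (pink plumage is carotenoid-based), which makes the five
classes conserve the total of the 12 inputs exactly. Structural coloration
is excluded from models by default (`exclude = "structural"`) because it is
strongly negatively correlated with melanin-based coloration; the exclusion
list is configurable.

Size correction is phylogenetic: residuals of a PGLS regression with λ
estimated jointly by maximum likelihood, applied to log10 measurements on
log10 body mass. Allometry on the log scale is the standard acoustic and
morphometric convention; a linear option exists
(`log10_transform = FALSE`). On a star phylogeny (or at λ̂ = 0) these
residuals reduce to ordinary least-squares residuals, a reduction the suite
asserts at 1e-8.

Beak shape is PC1 of the four size-corrected beak measurements, computed on
the correlation matrix — the residuals live on different scales, so the
covariance PCA would weight variables arbitrarily. The PC1 sign is fixed so
large, thick beaks score negative (flipped when the mean depth/width
loading is positive), making scores comparable across datasets.

Residual eye size uses log10 axial diameter on log10 mass; models including
it run on the complete-case subset (eye data are typically available for
roughly half the species), with the subset size logged.

Collinearity is screened with GVIF computed from determinant ratios of the
predictor correlation matrix; with continuous 1-df predictors
GVIF^(1/(2Df)) = √VIF, and values at or above 2 are flagged.

## Phylogenetic models

**Pagel's λ** rescales off-diagonal phylogenetic covariances; the ML
estimate profiles the multivariate-normal likelihood over λ ∈ [0, 1] with
the mean and rate maximized analytically at each λ (Cholesky-based, one
O(n³) factorization per λ evaluation). The search is `optimize()` with
tolerance 1e-6, endpoints checked explicitly, and boundary estimates
reported as exactly 0 or 1. The test against λ = 0 is a likelihood-ratio
test with the χ²₁ p-value halved, since λ = 0 lies on the boundary of the
parameter space.

**PGLS** maximizes the same profile likelihood over λ jointly with the
regression; standard errors use σ̂² = RSS_GLS/(n − p) and t-tests have n − p
degrees of freedom. The implementation is checked against the explicit
(XᵀC⁻¹X)⁻¹XᵀC⁻¹y formula at 1e-8 and against `nlme::gls` with `corPagel`.
Rescaling all branch lengths leaves λ̂ and β̂ unchanged (σ̂² absorbs the
scale), so trees need not be on a common depth scale.

**The Bayesian phylogenetic linear mixed model** is
`y = Xβ + u + ε`, `u ~ N(0, σ²_phylo C)`, `ε ~ N(0, σ²_resid I)` — on an
ultrametric unit-height tree this family is the λ model with
λ = σ²_phylo/(σ²_phylo + σ²_resid). Sampling is Gibbs in the eigenbasis of
C: after one eigendecomposition per tree the random-intercept update is
diagonal and each sweep is O(n). Priors are weakly informative —
`β ~ N(0, 10²)` on standardized predictors, half-Cauchy(0, 5) on both SDs
via their inverse-gamma scale-mixture representation, keeping every
conditional conjugate. Defaults are 2 chains × 4,000 iterations with 2,000
burn-in and, by default, no thinning: that yields 5,000 retained draws per
tree and, over a 50-tree sample, a pooled posterior of 250,000 draws —
thinning (`thin = 50`) is available but discards information without
improving pooled summaries. Convergence is summarised by split-R̂ per
parameter (worst case across trees; fits with R̂ > 1.1 warn) and an
autocorrelation-based effective sample size. The variance components mix
more slowly than the coefficients — σ²_phylo is weakly identified when the
residual signal is low — so short exploratory chains often flag σ²_phylo
while the β's are already stable.

Fitting once per tree and concatenating the post-burn-in draws is how
topological uncertainty is propagated; pooled means and central 95%
intervals are reported. Species missing from a given tree are dropped from
that tree's fit with a logged count; no grafting or imputation.

## The synthetic-data generator

`simulate_study()` builds a complete study with known ground truth:

* a pure-birth tree rescaled to unit height, plus a "posterior-like" tree
  sample made by lognormal branch-length jitter (sd 0.1) at fixed topology;
* traits evolved with tunable signal `lambda_signal` (default 1): log10
  body mass (BM sd 0.25 around ~20 g), four beak measurements combining 1/3
  mass allometry, a shared thick-vs-thin shape axis (loading 0.08) and
  per-measurement noise (sd 0.08, making PC1 of the size-corrected
  residuals carry ~55% of variance), eye axial diameter and maximum song
  frequency as mass allometries (the song slope defaults to −0.23 on the
  log10–log10 scale) plus Brownian residual axes, and 12 color-category
  proportions from a logistic-normal with Brownian latents;
* eye measurements retained for a random half of species
  (`eye_subset = 0.5`), emulating incomplete specimen data;
* flock membership: each locality draws a uniform species pool (default 40
  of 559) and a shared intercept (sd 0.5); every flock includes each pool
  species independently with probability
  `plogis(baseline + β·z + locality effect)`, with `baseline = qlogis(0.2)`
  giving realistic flock sizes (~8 species) and small flocks arising
  naturally so the filters have work to do;
* a phylogenetically conserved flocking-tendency latent in the joining
  log-odds (`phylo_intercept_sd = 0.5` at `phylo_intercept_lambda = 0.3`).
  This is the component the models' phylogenetic random intercept absorbs;
  its default is calibrated so the marginal signal of log flocking
  propensity is moderate (λ ≈ 0.25–0.30), the regime reported for real
  flock data, rather than the Brownian extreme.

Default sizes mirror a large compiled field dataset: 559 species, 83
localities, 42 flocks per locality (~3,500 flocks). The default effect
vector (+0.3 on residual song frequency, −0.3 on residual eye size, all
other axes 0) gives the validation suite known signs to recover.

What the generator does **not** emulate: pairwise attraction or avoidance
between species (membership is conditionally independent given traits — an
interaction term would be needed to mimic checkerboard competition),
phylogenetically clumped locality pools, detection error, observer effects,
or realistic biogeography. Passing tests therefore demonstrate that the
estimators recover effects under trait-driven, independently-assembled
flocks — not that real flock assembly satisfies those assumptions.

## Validation problem sizes

The package's checks run at these scales, chosen to exercise study-scale
behaviour while keeping the full suite a few minutes on one core: the null
stage at 83 localities × 500 replicates (41,500 randomized matrices);
margin preservation over 10,000 replicates across 20 matrix shapes; sampler
uniformity with 20,000 draws against an exhaustively enumerated 4×4 margin
set; closeness against an independent shortest-path oracle on 100 random
20-node graphs (1e-10) and PGLS against the direct GLS solve on 50-species
instances (1e-8); λ recovery over 200 replicates × 300 tips at generating
λ ∈ {0, 0.5, 1}; PGLS interval coverage over 200 such replicates;
Bayes-vs-PGLS agreement on the full default scenario at 2 chains × 2,000
iterations over 5 trees; and end-to-end effect recovery over 20 replicates
of a 400-species, 40-locality study (complete eye data, so the two active
effects are tested symmetrically). The z-score calibration scenario sets
every species-level effect to zero — including the conserved tendency — so
that, conditional on margins, the observed matrices are uniform draws from
the null set and pooled z-scores should be standard normal.

## Known limitations

* The Gibbs sampler assumes Gaussian responses; propensity is modeled on
  the log scale rather than with a binomial likelihood, matching standard
  comparative practice but ignoring the known binomial error of the counts.
* σ²_phylo and σ²_resid are weakly separated at low phylogenetic signal;
  coefficient inferences are robust to this, variance-partition summaries
  less so.
* Closeness on disconnected graphs is convention-dependent; the
  Wasserman–Faust scaling is one defensible choice and is documented so
  results can be converted.
* The fixed-fixed null conditions on both margins; effects that operate
  through flock size or species frequency themselves are standardized away
  by construction.
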