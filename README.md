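# flocknet

Tools for asking which phenotypes make a bird species **nuclear** in
mixed-species flocks: the species that join often, connect widely, and sit
centrally in flock co-occurrence networks. `flocknet` takes per-locality
flock-by-species occurrence tables, a species trait table, and one or more
phylogenies, and carries the analysis from raw occurrence records to
phylogenetic comparative models — with a synthetic-data generator so every
stage can be exercised and validated without field data.

## What it computes

**Flocking propensity.** For species *i*, the proportion of flocks it was
detected in, pooled across localities, log-transformed for modeling. Flocks
with fewer than 3 species and species recorded in fewer than 3 flocks are
excluded (the two filters are iterated to a joint fixed point).

**Species-level network metrics.** Each locality's flock × species matrix is
projected to a weighted unipartite graph, *w(i, j)* = number of flocks
containing both *i* and *j*. Per species and locality:

- *connectivity* — normalized degree, deg(i) / (S − 1);
- *strength* — Σ_j w(i, j), the total frequency of interspecific association;
- *closeness* — weighted closeness on edge lengths 1/w (stronger association
  = shorter distance), with Wasserman–Faust component scaling
  (R/(S−1)) · (R/Σd) on disconnected graphs.

Metrics are averaged across the localities where the species occurs.

**Null models.** Each matrix is randomized by the curveball algorithm,
preserving all row sums (flock richness) and column sums (species occurrence
frequency) exactly; metrics recomputed over 500 replicates give per-species
standardized effect sizes, *z* = (observed − null mean) / null SD.

**Trait predictors.** Plumage color proportions grouped into five classes
(structural, carotenoid-based, melanin-based, green, white), beak shape as
PC1 of four phylogenetically size-corrected beak measurements (thick beaks
score negative), residual eye size and residual maximum song frequency from
PGLS allometries on log body mass; everything standardized, collinearity
screened with GVIF^(1/(2·Df)).

**Phylogenetic comparative models.** Pagel's λ by profile maximum
likelihood; PGLS with ML λ, `y = Xβ + ε`, `ε ~ N(0, σ²C(λ))`; and a
Bayesian phylogenetic linear mixed model
`y = Xβ + u + ε`, `u ~ N(0, σ²_phylo C)`, fitted by a Gibbs sampler and
pooled across a sample of trees to propagate phylogenetic uncertainty.

## Worked example

```r
library(flocknet)
library(dplyr)

study  <- simulate_study(sim_config(n_species = 120, n_localities = 10,
                                    flocks_per_locality = 30, pool_size = 30,
                                    n_trees = 5, seed = 42))
flocks <- filter_species(lapply(study$flocks, filter_flocks))
prop   <- flocking_propensity(flocks$matrices)

pagel_lambda_ml(setNames(prop$log_propensity, prop$species_id), study$tree)
#> Pagel's lambda (ML): 0.5782  logLik = -109.619  LRT vs lambda=0: p = 0.00011  (n = 107)

preds <- build_predictors(study$traits, study$tree)
fit <- bayes_phylo_lm(
  inner_join(prop, preds, by = "species_id"),
  log_propensity ~ carotenoid + melanin + res_eye_size + res_max_frequency,
  study$tree_sample, chains = 2, iter = 2000, warmup = 1000, seed = 7)
fit
#> Bayesian phylogenetic LM pooled over 5 tree(s); 10000 draws (2 chains x 1000 kept / tree)
#> # A tibble: 7 × 6
#>   term                mean lower95 upper95  rhat n_eff
#> 1 (Intercept)       -3.04  -3.63    -2.40   1.08  474.
#> 2 carotenoid        -0.261 -0.794    0.272  1.01 1510.
#> 3 melanin           -0.270 -0.798    0.251  1.01 1795.
#> 4 res_eye_size      -0.122 -0.489    0.240  1.00 2825.
#> 5 res_max_frequency  0.386  0.0809   0.708  1.01 2558.
#> 6 sigma2_phylo       0.389  0.0110   1.33   1.08  342.
#> 7 sigma2_resid       0.374  0.142    0.701  1.04  765.
```

The generating model gave song frequency a positive effect (+0.3) and eye
size a negative effect (−0.3) on flock-joining log-odds: the pooled 95%
credible interval for residual song frequency excludes zero with the right
sign, eye size points the right way (the example's eye model runs on the
measured subset, here 51 species), and λ of log-propensity is moderate —
the heritable part of flocking tendency the model's random intercept
absorbs. `tidy()`, `glance()` and `autoplot()` work on both `pgls_fit` and
`phylo_blm` objects, and `run_study()` drives the whole pipeline from one
YAML configuration, writing every stage's table plus a reproducibility
manifest.

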