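#' Configuration of a synthetic flock study
#'
#' Defaults emulate the structure of a large compiled Neotropical dataset:
#' 559 species, 83 localities, ~42 flocks per locality (~3,500 flocks in
#' total), variable per-locality species pools, binary flock membership with
#' per-species joining probability a logistic function of standardized trait
#' axes, traits evolved on a pure-birth tree with tunable phylogenetic
#' signal, and an allometric song-frequency slope of -0.23 on the log-log
#' scale. Small flocks (<3 species) and rare species (<3 flocks) arise
#' naturally at these settings, so the filtering rules are exercised.
#'
#' @param n_species Number of species (tree tips).
#' @param n_localities Number of localities.
#' @param flocks_per_locality Flocks surveyed per locality.
#' @param pool_size Species-pool size per locality (drawn uniformly from the
#'   full species list, without replacement).
#' @param baseline Baseline flock-joining log-odds.
#' @param locality_sd SD of the per-locality intercept (shared by all
#'   species at that locality).
#' @param effects Named vector of effects of the standardized latent trait
#'   axes on joining log-odds. Recognised names: `res_max_frequency`,
#'   `res_eye_size`, `beak_pc1`, `white`, `green`, `carotenoid`, `melanin`,
#'   `structural`.
#' @param phylo_intercept_sd SD of a phylogenetically conserved
#'   flocking-tendency component of the joining log-odds (a Brownian latent
#'   on the tree, independent of the measured traits). This is what gives
#'   flocking propensity a moderate phylogenetic signal beyond the trait
#'   effects, and what the phylogenetic random intercept of the models
#'   absorbs; 0 disables it.
#' @param phylo_intercept_lambda Pagel's lambda of the conserved tendency
#'   latent. The default (with `phylo_intercept_sd = 0.5`) puts the marginal
#'   phylogenetic signal of log flocking propensity in the moderate range
#'   (lambda around 0.3) rather than at the Brownian extreme.
#' @param lambda_signal Pagel's lambda of the simulated trait residuals.
#' @param trait_sd Named list overriding the Brownian-motion SDs of the
#'   trait components: `mass` (log10 body mass), `shape` (latent beak axis),
#'   `beak` (per-measurement noise), `eye`, `freq` (residual axes), `color`
#'   (color latents). Setting one to 0 makes that component constant.
#' @param birth_rate Pure-birth speciation rate of the simulated tree
#'   (height is rescaled to 1, so this only shapes relative node depths).
#' @param allometry_freq Slope of log10 song frequency on log10 mass.
#' @param eye_subset Fraction of species with eye measurements (the rest are
#'   NA, mirroring incomplete specimen data).
#' @param n_trees Size of the tree sample emulating phylogenetic
#'   uncertainty.
#' @param tree_jitter_sd SD of the lognormal branch-length jitter in the
#'   tree sample.
#' @param seed Master seed (mandatory; every stage derives sub-seeds from
#'   it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 559,
                       n_localities = 83,
                       flocks_per_locality = 42,
                       pool_size = 40,
                       baseline = qlogis(0.2),
                       locality_sd = 0.5,
                       effects = c(res_max_frequency = 0.3,
                                   res_eye_size = -0.3),
                       phylo_intercept_sd = 0.5,
                       phylo_intercept_lambda = 0.3,
                       lambda_signal = 1,
                       trait_sd = list(),
                       birth_rate = 1,
                       allometry_freq = -0.23,
                       eye_subset = 0.5,
                       n_trees = 50,
                       tree_jitter_sd = 0.1,
                       seed = 1) {
  stopifnot(n_species >= 3, n_localities >= 1, flocks_per_locality >= 1,
            pool_size >= 2, lambda_signal >= 0, lambda_signal <= 1,
            !is.null(seed))
  cfg <- list(n_species = as.integer(n_species),
              n_localities = as.integer(n_localities),
              flocks_per_locality = as.integer(flocks_per_locality),
              pool_size = as.integer(min(pool_size, n_species)),
              baseline = baseline, locality_sd = locality_sd,
              effects = effects, phylo_intercept_sd = phylo_intercept_sd,
              phylo_intercept_lambda = phylo_intercept_lambda,
              lambda_signal = lambda_signal,
              trait_sd = utils::modifyList(
                list(mass = 0.25, shape = 1, beak = 0.08, eye = 1,
                     freq = 1, color = 1), trait_sd),
              birth_rate = birth_rate, allometry_freq = allometry_freq,
              eye_subset = eye_subset, n_trees = as.integer(n_trees),
              tree_jitter_sd = tree_jitter_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_species Number of tips.
#' @param seed Integer seed.
#' @param birth_rate Speciation rate before rescaling.
#' @return A rooted ultrametric `phylo` scaled to unit height, tips labelled
#'   `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_species, seed = 1, birth_rate = 1) {
  stopifnot(n_species >= 3)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Jittered tree sample emulating phylogenetic uncertainty
#'
#' Multiplies every branch length by independent lognormal noise (then
#' rescales to unit height), keeping the topology: a cheap stand-in for a
#' Bayesian posterior tree sample.
#'
#' @param tree A `phylo`.
#' @param n Number of trees.
#' @param sd SD of the log-normal jitter.
#' @param seed Integer seed.
#' @return A list of `phylo` objects.
#' @export
simulate_tree_sample <- function(tree, n = 50, sd = 0.1, seed = 1) {
  lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, i))
    tr <- tree
    tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length), 0, sd))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr
  })
}

# One trait vector from N(0, sigma2 * C(lambda)), via the Cholesky factor of
# the lambda-transformed covariance (computed once and reused by the caller).
sim_bm_trait <- function(chol_Cl, sigma) {
  if (sigma == 0) return(numeric(nrow(chol_Cl)))
  sigma * drop(crossprod(chol_Cl, rnorm(nrow(chol_Cl))))
}

#' Simulate species traits on a phylogeny
#'
#' Continuous traits evolve as Brownian motion with signal `lambda_signal`:
#' body mass on the log10 scale; four beak measurements as mass allometry
#' (slope 1/3 for linear dimensions) plus a shared thick-vs-thin shape axis
#' and small trait-specific noise; eye axial diameter as mass allometry plus
#' residual (NA outside a random subset of species); maximum song frequency
#' with the configured allometric slope on log10 mass plus residual; 12
#' plumage color-category proportions via a logistic-normal (softmax of
#' BM-correlated latents plus an uncovered-plumage baseline class).
#'
#' @param tree A `phylo` from [simulate_tree()].
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A trait tibble (`species_id`, `body_mass`, `beak_*`, `eye_ad`,
#'   `max_song_freq`, 12 color columns). The latent ground truth (shape
#'   axis, eye and frequency residuals, color-class sums) is stored in the
#'   `"truth"` attribute.
#' @export
simulate_traits <- function(tree, config, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, 2)
  set.seed(seed)
  n <- length(tree$tip.label)
  Cl <- lambda_transform(ape::vcv(tree), config$lambda_signal)
  ch <- chol(Cl)
  ts <- config$trait_sd
  lmass <- 1.3 + sim_bm_trait(ch, ts$mass)            # ~20 g median
  shape <- sim_bm_trait(ch, ts$shape)                 # thick (+) vs thin (-)
  beak <- list(
    beak_depth = -0.35 + lmass / 3 + 0.08 * shape + sim_bm_trait(ch, ts$beak),
    beak_width = -0.40 + lmass / 3 + 0.08 * shape + sim_bm_trait(ch, ts$beak),
    beak_nares = -0.15 + lmass / 3 - 0.08 * shape + sim_bm_trait(ch, ts$beak),
    beak_culmen = 0.05 + lmass / 3 - 0.08 * shape + sim_bm_trait(ch, ts$beak)
  )
  # conserved flocking tendency, at its own (moderate) signal level
  ch_t <- chol(lambda_transform(ape::vcv(tree),
                                config$phylo_intercept_lambda %||%
                                  config$lambda_signal))
  tendency <- sim_bm_trait(ch_t, 1)
  eye_resid <- sim_bm_trait(ch, ts$eye)
  leye <- 0.25 + lmass / 3 + 0.06 * eye_resid
  freq_resid <- sim_bm_trait(ch, ts$freq)
  lfreq <- 0.78 + config$allometry_freq * lmass + 0.10 * freq_resid
  latents <- vapply(seq_len(12), function(k) sim_bm_trait(ch, ts$color),
                    numeric(n)) - 1.2   # baseline class gets latent 0
  expl <- cbind(exp(latents), 1)
  props <- expl[, 1:12, drop = FALSE] / rowSums(expl)
  colnames(props) <- color_categories
  traits <- tibble::tibble(
    species_id = tree$tip.label,
    body_mass = 10^lmass,
    beak_depth = 10^beak$beak_depth,
    beak_width = 10^beak$beak_width,
    beak_nares = 10^beak$beak_nares,
    beak_culmen = 10^beak$beak_culmen,
    eye_ad = 10^leye,
    max_song_freq = 10^lfreq
  )
  has_eye <- runif(n) < config$eye_subset
  traits$eye_ad[!has_eye] <- NA_real_
  traits <- dplyr::bind_cols(traits, tibble::as_tibble(props))
  classes <- group_colors(traits)
  truth <- tibble::tibble(
    species_id = tree$tip.label,
    shape_latent = shape,
    flock_tendency = tendency,
    eye_resid = eye_resid,
    freq_resid = freq_resid,
    white = classes$white, green = classes$green,
    carotenoid = classes$carotenoid, melanin = classes$melanin,
    structural = classes$structural
  )
  attr(traits, "truth") <- truth
  traits
}

#' Simulate per-locality flock occurrence matrices
#'
#' Each locality draws a species pool uniformly without replacement and a
#' shared intercept; every flock then includes each pool species
#' independently with probability
#' `plogis(baseline + effects . z_traits + locality_effect)`, where
#' `z_traits` are the standardized latent trait axes recorded by
#' [simulate_traits()] (the beak axis enters with the analysis sign
#' convention: thick beaks negative). Flocks in which no species occurred
#' are discarded as unobserved; flocks of 1-2 species are kept so the
#' minimum-richness filter has work to do.
#'
#' @param traits Trait tibble from [simulate_traits()].
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults derived from the config seed).
#' @return List of [flock_matrix()] objects; per-species true joining
#'   probabilities (averaged over localities) in the `"truth"` attribute.
#' @export
simulate_flocks <- function(traits, config, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, 3)
  truth <- attr(traits, "truth")
  stopifnot(!is.null(truth))
  zsc <- function(x) if (sd(x) == 0) rep(0, length(x)) else as.numeric(scale(x))
  z <- tibble::tibble(
    res_max_frequency = zsc(truth$freq_resid),
    res_eye_size = zsc(truth$eye_resid),
    beak_pc1 = zsc(-truth$shape_latent),
    white = zsc(truth$white),
    green = zsc(truth$green),
    carotenoid = zsc(truth$carotenoid),
    melanin = zsc(truth$melanin),
    structural = zsc(truth$structural)
  )
  eta_sp <- rep(config$baseline, nrow(traits)) +
    (config$phylo_intercept_sd %||% 0) * zsc(truth$flock_tendency)
  for (nm in names(config$effects)) {
    if (!nm %in% names(z))
      stop("unknown effect name '", nm, "'", call. = FALSE)
    eta_sp <- eta_sp + config$effects[[nm]] * z[[nm]]
  }
  n_sp <- nrow(traits)
  ms <- vector("list", config$n_localities)
  probs <- matrix(NA_real_, n_sp, config$n_localities)
  for (l in seq_len(config$n_localities)) {
    set.seed(derive_seed(seed, l))
    pool <- sort(sample.int(n_sp, config$pool_size))
    loc_eff <- rnorm(1, 0, config$locality_sd)
    p <- plogis(eta_sp[pool] + loc_eff)
    probs[pool, l] <- p
    occ <- matrix(rbinom(config$flocks_per_locality * length(pool), 1,
                         rep(p, each = config$flocks_per_locality)),
                  nrow = config$flocks_per_locality)
    dimnames(occ) <- list(
      sprintf("L%02d_F%03d", l, seq_len(config$flocks_per_locality)),
      traits$species_id[pool])
    occ <- occ[rowSums(occ) > 0, , drop = FALSE]
    if (nrow(occ) == 0) next
    ms[[l]] <- flock_matrix(occ, sprintf("L%02d", l))
  }
  ms <- ms[!vapply(ms, is.null, logical(1))]
  if (!length(ms))
    stop("all simulated flocks are empty; raise the baseline log-odds",
         call. = FALSE)
  names(ms) <- vapply(ms, locality_id, character(1))
  truth_out <- tibble::tibble(
    species_id = traits$species_id,
    joining_logodds = eta_sp,
    mean_join_prob = rowMeans(probs, na.rm = TRUE)
  )
  structure(ms, truth = truth_out)
}

#' Simulate a complete synthetic study
#'
#' Tree, jittered tree sample, traits, and flock matrices, with ground truth
#' attached — the inputs every downstream stage of the pipeline needs.
#'
#' @param config A [sim_config()].
#' @return List with `tree`, `tree_sample`, `traits`, `flocks`, `truth`
#'   (list of trait latents and joining probabilities) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  tree <- simulate_tree(config$n_species, seed = derive_seed(config$seed, 1),
                        birth_rate = config$birth_rate)
  tree_sample <- simulate_tree_sample(tree, n = config$n_trees,
                                      sd = config$tree_jitter_sd,
                                      seed = derive_seed(config$seed, 4))
  traits <- simulate_traits(tree, config)
  flocks <- simulate_flocks(traits, config)
  list(tree = tree, tree_sample = tree_sample, traits = traits,
       flocks = flocks,
       truth = list(traits = attr(traits, "truth"),
                    joining = attr(flocks, "truth")),
       config = config)
}
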