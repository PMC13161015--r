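#' Fixed-row, fixed-column randomization of a flock matrix
#'
#' Draws a binary matrix with exactly the observed row sums (flock sizes) and
#' column sums (species occurrence frequencies), using curveball trades: two
#' random flocks repeatedly exchange a random subset of the species exclusive
#' to each, which provably samples uniformly from the set of matrices sharing
#' the margins. Each call runs an independent chain of
#' `trades_factor * sum(m)` trades from the observed matrix.
#'
#' @param m A binary [flock_matrix()].
#' @param seed Optional integer seed (otherwise the current RNG state is
#'   used).
#' @param trades_factor Number of trades per filled cell (default 5).
#' @param n_trades Override the total number of trades directly.
#' @return A `flock_matrix` with the same dimnames and margins. If the
#'   margins determine the matrix uniquely (no 2x2 checkerboard submatrix),
#'   the input is returned with a warning.
#' @export
randomize_fixed_fixed <- function(m, seed = NULL, trades_factor = 5,
                                  n_trades = NULL) {
  occ <- unclass(m)
  if (is_margin_determined(occ)) {
    warning("margins determine the matrix uniquely; returning input")
    return(m)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_trades)) n_trades <- trades_factor * sum(occ)
  rnd <- curveball_cpp(occ, as.integer(n_trades))
  dimnames(rnd) <- dimnames(occ)
  restore_flock_matrix(rnd, m)
}

# A binary matrix is the only one with its margins iff it has no 2x2
# checkerboard submatrix, i.e. no row pair (i, j) where each row holds a
# species the other lacks.
is_margin_determined <- function(occ) {
  A <- occ %*% (1L - t(occ))   # A[i, j] = #cols where row i has 1, row j has 0
  !any(A > 0 & t(A) > 0)
}

#' Null distribution of species metrics for one locality
#'
#' Generates `n_reps` fixed-fixed randomizations of the flock matrix, projects
#' each to a co-occurrence network, recomputes connectivity, strength and
#' weighted closeness for every species, and summarises each species-metric
#' null distribution by its mean and standard deviation.
#'
#' Replicates are independent curveball chains; the seed of replicate `r` is
#' derived deterministically from `seed` (and, via [compute_null_ensembles()],
#' the locality index), so any single replicate can be reproduced in
#' isolation.
#'
#' @inheritParams randomize_fixed_fixed
#' @param n_reps Number of null replicates (>= 2).
#' @return A `null_ensemble` tibble with `species_id`, `locality_id`,
#'   `metric`, `null_mean`, `null_sd`; attributes `n_reps` and `seed`.
#' @export
null_distribution <- function(m, n_reps = 500, seed = 1, trades_factor = 5) {
  if (n_reps < 2) stop("n_reps must be at least 2", call. = FALSE)
  present <- colSums(m) > 0
  occ <- unclass(m)[, present, drop = FALSE]
  S <- ncol(occ)
  if (S < 2L) stop("fewer than two species present", call. = FALSE)
  n_trades <- as.integer(trades_factor * sum(occ))
  degenerate <- is_margin_determined(occ)
  sums <- sums2 <- matrix(0, 3, S)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    rnd <- if (degenerate) occ else curveball_cpp(occ, n_trades)
    W <- crossprod(rnd)
    diag(W) <- 0L
    vals <- rbind(colSums(W > 0) / (S - 1),
                  colSums(W),
                  closeness_from_weights(W))
    sums <- sums + vals
    sums2 <- sums2 + vals^2
  }
  mu <- sums / n_reps
  vr <- pmax(sums2 / n_reps - mu^2, 0) * n_reps / (n_reps - 1)
  out <- tibble::tibble(
    species_id = rep(colnames(occ), each = 3),
    locality_id = locality_id(m),
    metric = rep(c("connectivity", "strength", "closeness"), S),
    null_mean = as.numeric(mu),
    null_sd = sqrt(as.numeric(vr))
  )
  structure(out, n_reps = n_reps, seed = seed,
            class = c("null_ensemble", class(out)))
}

#' Null ensembles for every locality
#'
#' @param ms List of filtered [flock_matrix()] objects.
#' @param n_reps Replicates per locality.
#' @param seed Master seed; per-locality seeds are derived from it and the
#'   locality position.
#' @inheritParams randomize_fixed_fixed
#' @return A `null_ensemble` tibble covering all localities; the attribute
#'   `n_matrices` records the total number of randomized matrices generated.
#' @export
compute_null_ensembles <- function(ms, n_reps = 500, seed = 1,
                                   trades_factor = 5) {
  out <- purrr::map_dfr(seq_along(ms), function(i) {
    null_distribution(ms[[i]], n_reps = n_reps,
                      seed = derive_seed(seed, i),
                      trades_factor = trades_factor)
  })
  structure(out, n_reps = n_reps, seed = seed,
            n_matrices = n_reps * length(ms),
            class = c("null_ensemble", class(out)))
}

#' Standardized effect sizes (z-scores) of species metrics
#'
#' For each species, locality and metric:
#' `z = (observed - null_mean) / null_sd`. When the null standard deviation
#' is zero the z-score is undefined and set to `NA` (such cases are counted
#' in a message and excluded from downstream models).
#'
#' @param observed Per-locality metrics tibble from [compute_metrics()].
#' @param nulls A `null_ensemble` from [compute_null_ensembles()].
#' @return A tibble with `species_id`, `locality_id`, `metric`, `observed`,
#'   `null_mean`, `null_sd`, `z`.
#' @export
z_scores <- function(observed, nulls) {
  obs_long <- observed |>
    tidyr::pivot_longer(cols = c("connectivity", "strength", "closeness"),
                        names_to = "metric", values_to = "observed")
  merged <- dplyr::left_join(obs_long, nulls,
                             by = c("species_id", "locality_id", "metric"))
  if (anyNA(merged$null_mean)) {
    bad <- unique(merged$species_id[is.na(merged$null_mean)])
    stop("no null distribution for species: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  zero_sd <- merged$null_sd == 0
  if (any(zero_sd))
    message(sum(zero_sd), " species-locality-metric z-scores undefined ",
            "(zero null SD); set to NA")
  merged$z <- ifelse(zero_sd, NA_real_,
                     (merged$observed - merged$null_mean) / merged$null_sd)
  merged
}

#' Average z-scores across localities per species
#'
#' Mirrors the averaging of the observed metrics: the per-species mean of the
#' per-locality z-scores, taken over localities with a defined z.
#'
#' @param z A tibble from [z_scores()].
#' @return A wide tibble: `species_id`, `z_connectivity`, `z_strength`,
#'   `z_closeness`, `n_localities`.
#' @export
average_z_scores <- function(z) {
  z |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::group_by(.data$species_id, .data$metric) |>
    dplyr::summarise(z_mean = mean(.data$z), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(id_cols = "species_id",
                       names_from = "metric", values_from = c("z_mean", "n"),
                       names_glue = "{.value}_{metric}") |>
    dplyr::rename_with(~ sub("^z_mean_", "z_", .x)) |>
    dplyr::rename_with(~ sub("^n_", "n_loc_", .x), dplyr::starts_with("n_"))
}
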