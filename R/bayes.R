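#' Bayesian phylogenetic linear mixed model, pooled over a tree sample
#'
#' Fits `y = X beta + u + e` with a phylogenetic random intercept
#' `u ~ N(0, sigma2_phylo * C)` and residual `e ~ N(0, sigma2_resid * I)`,
#' where `C` is the Brownian-motion covariance of each tree. Sampling is by
#' Gibbs: the model is rotated into the eigenbasis of `C` (one
#' eigendecomposition per tree), which makes the random-intercept update
#' diagonal, so each sweep is O(n). Priors are weakly informative:
#' `beta ~ N(0, 10^2)` and half-Cauchy(0, 5) on both standard deviations
#' (via their inverse-gamma scale-mixture representation, keeping every
#' conditional conjugate).
#'
#' The model is fitted once per tree and the post-warmup draws are
#' concatenated into a single pooled posterior, which is how topological
#' uncertainty across a posterior tree sample is propagated. Reported
#' intervals are central 95% quantiles of the pooled draws. Convergence is
#' summarised by the worst split-Rhat across trees per parameter.
#'
#' @param data Data frame with `species_id` and model variables. Predictors
#'   are expected to be standardized (see [build_predictors()]).
#' @param formula Model formula.
#' @param trees A `phylo`, a list of `phylo`, or a `multiPhylo`.
#' @param chains Number of MCMC chains per tree.
#' @param iter Total iterations per chain.
#' @param warmup Burn-in iterations discarded from each chain.
#' @param thin Keep every `thin`-th post-warmup draw (default 1, giving
#'   `chains * (iter - warmup)` draws per tree).
#' @param seed Integer seed; chain/tree seeds are derived from it.
#' @param prior_beta_sd SD of the normal prior on coefficients.
#' @param prior_scale_sd Scale of the half-Cauchy priors on the two SDs.
#' @return An object of class `phylo_blm` with [tidy()]/[glance()] methods:
#'   pooled draws, coefficient summaries (`mean`, `lower95`, `upper95`,
#'   `rhat`, `n_eff`), per-tree species counts.
#' @export
bayes_phylo_lm <- function(data, formula, trees, chains = 2, iter = 4000,
                           warmup = 2000, thin = 1, seed = 1,
                           prior_beta_sd = 10, prior_scale_sd = 5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1, iter > warmup, chains >= 1)
  stopifnot("species_id" %in% names(data))
  mf_vars <- all.vars(formula)
  keep0 <- complete.cases(data[, mf_vars, drop = FALSE])
  if (any(!keep0)) message("dropping ", sum(!keep0), " incomplete cases")
  d0 <- data[keep0, , drop = FALSE]

  per_tree <- vector("list", length(trees))
  dropped <- integer(length(trees))
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    keep <- d0$species_id %in% tr$tip.label
    dropped[ti] <- sum(!keep)
    d <- d0[keep, , drop = FALSE]
    mf <- model.frame(formula, d)
    y <- stats::model.response(mf)
    X <- model.matrix(formula, mf)
    C <- ape::vcv(tr)[d$species_id, d$species_id]
    eg <- eigen(C, symmetric = TRUE)
    dvals <- pmax(eg$values, 1e-12)
    U <- eg$vectors
    yt <- drop(crossprod(U, y))
    Xt <- crossprod(U, X)
    chain_draws <- vector("list", chains)
    for (ch in seq_len(chains)) {
      set.seed(derive_seed(seed, ti, ch))
      chain_draws[[ch]] <- gibbs_phylo_chain(
        yt, Xt, dvals, iter = iter, warmup = warmup, thin = thin,
        prior_beta_sd = prior_beta_sd, prior_scale_sd = prior_scale_sd)
    }
    per_tree[[ti]] <- chain_draws
  }
  if (sum(dropped) > 0)
    message("species absent from trees dropped per tree: ",
            paste(dropped, collapse = ", "))

  par_names <- colnames(per_tree[[1]][[1]])
  pooled <- do.call(rbind, lapply(per_tree, function(cd) do.call(rbind, cd)))
  rhat_by_tree <- vapply(per_tree, function(cd) {
    vapply(par_names, function(p)
      split_rhat(lapply(cd, function(m) m[, p])), numeric(1))
  }, numeric(length(par_names)))
  rhat <- apply(matrix(rhat_by_tree, nrow = length(par_names)), 1, max)
  ess <- vapply(par_names, function(p) {
    sum(vapply(per_tree, function(cd)
      sum(vapply(cd, function(m) ess_chain(m[, p]), numeric(1))),
      numeric(1)))
  }, numeric(1))
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("Rhat > 1.1 for: ",
            paste(par_names[rhat > 1.1], collapse = ", "),
            "; increase iterations")
  coefs <- tibble::tibble(
    term = par_names,
    mean = colMeans(pooled),
    lower95 = apply(pooled, 2, quantile, 0.025, names = FALSE),
    upper95 = apply(pooled, 2, quantile, 0.975, names = FALSE),
    rhat = rhat,
    n_eff = ess
  )
  structure(list(coefficients = coefs, draws = pooled,
                 n_trees = length(trees), chains = chains, iter = iter,
                 warmup = warmup, thin = thin,
                 n_draws = nrow(pooled), formula = formula,
                 n = nrow(d0), dropped_per_tree = dropped, seed = seed),
            class = "phylo_blm")
}

# One Gibbs chain in the eigenbasis of C. Columns of the returned matrix:
# coefficients, sigma2_phylo, sigma2_resid.
gibbs_phylo_chain <- function(yt, Xt, dvals, iter, warmup, thin,
                              prior_beta_sd, prior_scale_sd) {
  n <- length(yt)
  p <- ncol(Xt)
  XtX <- crossprod(Xt)
  tau2 <- prior_beta_sd^2
  A2 <- prior_scale_sd^2
  beta <- drop(qr.solve(XtX + diag(1e-8, p), crossprod(Xt, yt)))
  u <- numeric(n)
  vy <- var(yt)
  s2p <- s2e <- max(vy / 2, 1e-6)
  a_p <- a_e <- 1
  keep_iter <- seq(warmup + 1, iter)
  keep_iter <- keep_iter[(seq_along(keep_iter) - 1) %% thin == 0]
  out <- matrix(NA_real_, length(keep_iter), p + 2)
  colnames(out) <- c(colnames(Xt), "sigma2_phylo", "sigma2_resid")
  k <- 0L
  for (it in seq_len(iter)) {
    # phylogenetic effects (diagonal in the eigenbasis)
    r <- yt - drop(Xt %*% beta)
    v <- 1 / (1 / (s2p * dvals) + 1 / s2e)
    u <- rnorm(n, v * r / s2e, sqrt(v))
    # coefficients
    A <- XtX / s2e + diag(1 / tau2, p)
    La <- chol(A)
    mb <- backsolve(La, backsolve(La, crossprod(Xt, yt - u) / s2e,
                                  transpose = TRUE))
    beta <- drop(mb + backsolve(La, rnorm(p)))
    # variance components, half-Cauchy via inverse-gamma mixture
    s2p <- 1 / rgamma(1, (n + 1) / 2, rate = sum(u^2 / dvals) / 2 + 1 / a_p)
    a_p <- 1 / rgamma(1, 1, rate = 1 / A2 + 1 / s2p)
    res <- yt - drop(Xt %*% beta) - u
    s2e <- 1 / rgamma(1, (n + 1) / 2, rate = sum(res^2) / 2 + 1 / a_e)
    a_e <- 1 / rgamma(1, 1, rate = 1 / A2 + 1 / s2e)
    if (it > warmup && (it - warmup - 1) %% thin == 0) {
      k <- k + 1L
      out[k, ] <- c(beta, s2p, s2e)
    }
  }
  out
}

# Split-Rhat (Gelman-Rubin with split chains) over a list of chain vectors.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

# Effective sample size of one chain via the initial positive sequence of
# autocorrelations.
ess_chain <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}

#' @export
print.phylo_blm <- function(x, ...) {
  cat("Bayesian phylogenetic LM pooled over ", x$n_trees, " tree(s); ",
      x$n_draws, " draws (", x$chains, " chains x ",
      x$iter - x$warmup, " kept / tree)\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @rdname bayes_phylo_lm
#' @param x A `phylo_blm` object.
#' @param ... Unused.
#' @export
tidy.phylo_blm <- function(x, ...) {
  dplyr::rename(x$coefficients, estimate = "mean",
                conf.low = "lower95", conf.high = "upper95")
}

#' @rdname bayes_phylo_lm
#' @export
glance.phylo_blm <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_draws = x$n_draws, nobs = x$n,
                 max_rhat = max(x$coefficients$rhat, na.rm = TRUE),
                 min_n_eff = min(x$coefficients$n_eff, na.rm = TRUE))
}

#' Fit the trait models for every response
#'
#' Joins a response table to the standardized predictor table and fits one
#' phylogenetic model per response, each with the same predictor set —
#' producing the coefficient layout of the main results tables (mean and 95%
#' interval per predictor per response). Responses are typically
#' `log_propensity` plus the averaged network metrics, or the averaged
#' z-scores.
#'
#' @param responses Tibble with `species_id` and one column per response.
#' @param predictors Tibble from [build_predictors()].
#' @param trees Tree sample (see [bayes_phylo_lm()]).
#' @param response_cols Character vector of response column names (default:
#'   every non-`species_id` column of `responses`).
#' @param engine `"bayes"` ([bayes_phylo_lm()]) or `"pgls"` ([pgls_fit()],
#'   first tree only).
#' @param ... Passed to the engine.
#' @return List with `fits` (named list of model objects) and `table` (one
#'   tidied tibble with a `response` column).
#' @export
fit_all_models <- function(responses, predictors, trees,
                           response_cols = NULL,
                           engine = c("bayes", "pgls"), ...) {
  engine <- match.arg(engine)
  if (is.null(response_cols))
    response_cols <- setdiff(names(responses), c("species_id", "n_localities"))
  pred_cols <- setdiff(names(predictors), "species_id")
  dat <- dplyr::inner_join(responses, predictors, by = "species_id")
  fits <- lapply(response_cols, function(resp) {
    fml <- stats::as.formula(
      paste(resp, "~", paste(pred_cols, collapse = " + ")))
    if (engine == "bayes") {
      bayes_phylo_lm(dat, fml, trees, ...)
    } else {
      tr <- if (inherits(trees, "phylo")) trees else trees[[1]]
      pgls_fit(dat, fml, tr, ...)
    }
  })
  names(fits) <- response_cols
  table <- purrr::map_dfr(response_cols, function(resp)
    dplyr::mutate(tidy(fits[[resp]]), response = resp, .before = 1))
  list(fits = fits, table = table)
}
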