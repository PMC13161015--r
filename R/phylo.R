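#' Read rooted phylogenies from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream models need:
#' branch lengths must be present and non-negative, and tip labels unique.
#' Polytomies are allowed.
#'
#' @param path Path to a Newick file holding one or more trees.
#' @return A single `phylo` object, or a list of them for a multi-tree file.
#' @export
read_newick <- function(path) {
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("failed to parse Newick file '",
                                             path, "': ", conditionMessage(e),
                                             call. = FALSE))
  if (is.null(trees)) stop("failed to parse Newick file '", path, "'",
                           call. = FALSE)
  check <- function(tr) {
    if (is.null(tr$edge.length))
      stop("tree has no branch lengths", call. = FALSE)
    if (any(tr$edge.length < 0))
      stop("tree has negative branch lengths", call. = FALSE)
    if (anyDuplicated(tr$tip.label))
      stop("tree has duplicate tip labels", call. = FALSE)
    tr
  }
  if (inherits(trees, "multiPhylo")) lapply(trees, check) else check(trees)
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance of two tips is their shared
#' root-to-tip path length; the diagonal holds each tip's depth. Pagel's
#' lambda rescales the off-diagonal entries by `lambda` in `[0, 1]` (0 = no
#' phylogenetic signal, 1 = full Brownian expectation).
#'
#' @param tree A `phylo` object.
#' @param lambda Pagel's lambda applied to the off-diagonals.
#' @return A symmetric S x S matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree, lambda = 1) {
  C <- ape::vcv(tree)
  lambda_transform(C, lambda)
}

#' @rdname phylo_vcv
#' @param C A phylogenetic covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Log-likelihood machinery shared by pagel_lambda_ml() and pgls_fit().
# Returns the profile (ML) log-likelihood of a GLS model y = X beta + e,
# e ~ N(0, sigma2 * C(lambda)), maximized analytically over beta and sigma2.
gls_profile <- function(y, X, C, lambda) {
  n <- length(y)
  Cl <- lambda_transform(C, lambda)
  L <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(L)) return(list(logLik = -Inf))
  # whiten: solve t(L) z = x  =>  z = L^-T x, so z' z = x' C^-1 x
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  list(logLik = ll, beta = beta, rss = rss, sigma2_ml = sigma2_ml,
       Xw = Xw, yw = yw, chol = L)
}

# ML search for lambda on [0, 1]; returns the optimum and endpoint checks.
optimize_lambda <- function(y, X, C, tol = 1e-6) {
  f <- function(l) gls_profile(y, X, C, l)$logLik
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  if (all(!is.finite(ll)))
    stop("lambda profile likelihood is degenerate (singular covariance)",
         call. = FALSE)
  best <- which.max(ll)
  lam <- cand[best]
  if (lam < tol) lam <- 0
  if (lam > 1 - tol) lam <- 1
  list(lambda = lam, logLik = max(ll), logLik0 = ll[2], logLik1 = ll[3])
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the multivariate-normal likelihood of a single trait over
#' lambda in `[0, 1]`, with the phylogenetic mean and rate maximized
#' analytically at each lambda. The reported p-value is a likelihood-ratio
#' test against lambda = 0 with the usual boundary correction (the chi-square
#' p halved, since lambda = 0 sits on the edge of the parameter space).
#'
#' @param y Named numeric vector of trait values; names must match tip
#'   labels.
#' @param tree A `phylo` object.
#' @param tol Convergence tolerance of the lambda search.
#' @return An object of class `pagel_lambda`: a list with `lambda`, `logLik`,
#'   `logLik0`, `p_value`, `sigma2`, `mu`, `n`.
#' @export
pagel_lambda_ml <- function(y, tree, tol = 1e-6) {
  if (is.null(names(y))) stop("y must be named by species", call. = FALSE)
  common <- intersect(names(y), tree$tip.label)
  if (length(common) < 4) stop("need at least 4 species", call. = FALSE)
  y <- y[common]
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  C <- ape::vcv(tree)[common, common]
  X <- matrix(1, length(y), 1)
  opt <- optimize_lambda(y, X, C, tol)
  prof <- gls_profile(y, X, C, opt$lambda)
  lr <- 2 * (opt$logLik - opt$logLik0)
  p <- if (lr <= 0) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(lambda = opt$lambda, logLik = opt$logLik,
                 logLik0 = opt$logLik0, p_value = p,
                 sigma2 = prof$sigma2_ml, mu = unname(prof$beta[1]),
                 n = length(y)),
            class = "pagel_lambda")
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat("Pagel's lambda (ML): ", format(x$lambda, digits = 4),
      "  logLik = ", format(x$logLik, digits = 6),
      "  LRT vs lambda=0: p = ", format.pval(x$p_value, digits = 3),
      "  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' Fits `formula` by GLS with error covariance `sigma2 * C(lambda)`, where
#' `C` is the Brownian-motion covariance of `tree` and lambda is either
#' ML-estimated on `[0, 1]` (default) or fixed. Standard errors use
#' `sigma2_hat = RSS_gls / (n - p)`; t-tests have `n - p` degrees of freedom.
#'
#' @param data A data frame with a `species_id` column matching tip labels
#'   and the model variables. Incomplete cases are dropped with a message.
#' @param formula Model formula.
#' @param tree A `phylo` object.
#' @param lambda `"ML"` or a fixed numeric value in `[0, 1]`.
#' @return An object of class `pgls_fit` with [tidy()] and [glance()]
#'   methods.
#' @export
pgls_fit <- function(data, formula, tree, lambda = "ML") {
  stopifnot("species_id" %in% names(data))
  mf_vars <- all.vars(formula)
  keep <- complete.cases(data[, mf_vars, drop = FALSE]) &
    data$species_id %in% tree$tip.label
  if (sum(!keep) > 0)
    message("dropping ", sum(!keep),
            " species (incomplete cases or absent from tree)")
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 4) stop("need at least 4 complete cases", call. = FALSE)
  mf <- model.frame(formula, d)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  C <- ape::vcv(tree)[d$species_id, d$species_id]
  if (identical(lambda, "ML")) {
    opt <- optimize_lambda(y, X, C)
    lam <- opt$lambda
  } else {
    lam <- as.numeric(lambda)
    stopifnot(lam >= 0, lam <= 1)
  }
  prof <- gls_profile(y, X, C, lam)
  p <- ncol(X)
  sigma2 <- prof$rss / (n - p)
  XtCX_inv <- chol2inv(chol(crossprod(prof$Xw)))
  se <- sqrt(sigma2 * diag(XtCX_inv))
  tval <- prof$beta / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = as.numeric(prof$beta),
    std.error = as.numeric(se),
    statistic = as.numeric(tval),
    p.value = as.numeric(pval)
  )
  structure(list(coefficients = coefs, lambda = lam, sigma2 = sigma2,
                 logLik = prof$logLik, n = n, df.residual = n - p,
                 formula = formula, vcov = sigma2 * XtCX_inv,
                 residuals = setNames(as.numeric(y - X %*% prof$beta),
                                      d$species_id),
                 species = d$species_id),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (n = ", x$n, ", lambda = ", format(x$lambda, digits = 4),
      ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @rdname pgls_fit
#' @param x A `pgls_fit` object.
#' @param conf.level Confidence level for the interval columns.
#' @param ... Unused.
#' @export
tidy.pgls_fit <- function(x, conf.level = 0.95, ...) {
  q <- stats::qt(1 - (1 - conf.level) / 2, df = x$df.residual)
  x$coefficients |>
    dplyr::mutate(conf.low = .data$estimate - q * .data$std.error,
                  conf.high = .data$estimate + q * .data$std.error)
}

#' @rdname pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma2 = x$sigma2, logLik = x$logLik,
                 nobs = x$n, df.residual = x$df.residual)
}
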