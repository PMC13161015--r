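make_color_table <- function(n = 6, seed = 1) {
  set.seed(seed)
  raw <- matrix(rexp(n * 12), n, 12)
  props <- raw / rowSums(raw) * runif(n, 0.7, 1)   # total coverage <= 1
  colnames(props) <- flocknet:::color_categories
  dplyr::bind_cols(tibble::tibble(species_id = sprintf("sp%02d", 1:n)),
                   tibble::as_tibble(props))
}

test_that("color classes group the 12 categories and conserve coverage", {
  tt <- make_color_table()
  cls <- group_colors(tt)
  expect_equal(cls$structural, tt$blue + tt$purple)
  expect_equal(cls$carotenoid, tt$yellow + tt$orange + tt$red + tt$pink)
  expect_equal(cls$melanin, tt$black + tt$grey + tt$brown + tt$rufous)
  expect_equal(cls$green, tt$green)
  expect_equal(cls$white, tt$white)
  # conservation: five classes sum to the 12 inputs exactly
  expect_equal(cls$structural + cls$carotenoid + cls$melanin + cls$green +
                 cls$white,
               rowSums(as.matrix(tt[, flocknet:::color_categories])))
  expect_error(group_colors(tt[, -2]), "missing color category")
})

test_that("pure-white and mixed examples map to the expected classes", {
  tt <- make_color_table(2)
  tt[1, flocknet:::color_categories] <- as.list(c(rep(0, 11), 1))  # white only
  tt[2, c("blue", "purple", "yellow", "orange", "red")] <-
    list(0.10, 0.05, 0.2, 0.1, 0.05)
  cls <- group_colors(tt)
  expect_equal(cls$white[1], 1)
  expect_equal(cls$structural[1], 0)
  expect_equal(cls$structural[2], 0.15)
  expect_equal(cls$carotenoid[2], 0.35 + tt$pink[2])
})

test_that("phylogenetic residuals reduce to OLS on a star tree and vanish on exact fits", {
  tr <- star_tree(30)
  set.seed(2)
  d <- tibble::tibble(species_id = tr$tip.label, x = rnorm(30))
  d$y <- 1.5 + 2 * d$x + rnorm(30, sd = 0.3)
  r <- phylo_residuals(d, "y", "x", tr)
  ols <- stats::residuals(lm(y ~ x, d))
  expect_equal(unname(r), unname(ols), tolerance = 1e-8)
  d$y2 <- 2 * d$x
  expect_equal(unname(phylo_residuals(d, "y2", "x", tr)), rep(0, 30),
               tolerance = 1e-10)
  expect_error(phylo_residuals(d[1:2, ], "y", "x", tr), "at least 4")
})

test_that("phylogenetic residuals satisfy GLS orthogonality and match a direct solve", {
  set.seed(7)
  tr <- ape::rphylo(60, 1, 0)
  tr$tip.label <- sprintf("t%02d", 1:60)
  C <- ape::vcv(tr)
  x <- drop(crossprod(chol(C), rnorm(60)))
  y <- 0.5 + 0.8 * x + drop(crossprod(chol(C), rnorm(60))) * 0.5
  d <- tibble::tibble(species_id = tr$tip.label, x = x, y = y)
  fit <- pgls_fit(d, y ~ x, tr, lambda = 1)
  orc <- oracle_gls(y, cbind(1, x), C)
  expect_equal(unname(fit$coefficients$estimate), unname(orc$beta),
               tolerance = 1e-8)
  r <- phylo_residuals(d, "y", "x", tr)   # lambda ML, still GLS-orthogonal
  lam <- pgls_fit(d, y ~ x, tr)$lambda
  Cl <- lambda_transform(C, lam)
  expect_equal(max(abs(t(cbind(1, x)) %*% solve(Cl) %*% r)), 0,
               tolerance = 1e-6)
})

test_that("phylogenetic residuals agree with the phytools reference", {
  skip_if_not_installed("phytools")
  set.seed(11)
  tr <- ape::rphylo(40, 1, 0)
  tr$tip.label <- sprintf("t%02d", 1:40)
  C <- ape::vcv(tr)
  x <- setNames(drop(crossprod(chol(C), rnorm(40))), tr$tip.label)
  y <- setNames(0.3 * x + drop(crossprod(chol(C), rnorm(40))), tr$tip.label)
  d <- tibble::tibble(species_id = tr$tip.label, x = unname(x), y = unname(y))
  ours <- phylo_residuals(d, "y", "x", tr)
  ref <- phytools::phyl.resid(tr, x, y, method = "lambda")
  expect_equal(unname(ours[tr$tip.label]),
               unname(ref$resid[tr$tip.label, 1]), tolerance = 1e-4)
})

test_that("beak PCA matches an eigendecomposition oracle with the thick-negative sign", {
  set.seed(3)
  n <- 50
  size_free <- rnorm(n)
  resids <- cbind(
    beak_depth = 0.9 * size_free + rnorm(n, sd = 0.3),
    beak_width = 0.8 * size_free + rnorm(n, sd = 0.3),
    beak_nares = -0.7 * size_free + rnorm(n, sd = 0.3),
    beak_culmen = -0.6 * size_free + rnorm(n, sd = 0.3))
  rownames(resids) <- sprintf("sp%02d", 1:n)
  pca <- beak_pca(resids)
  expect_equal(sum(pca$variance_proportion), 1)
  ev <- eigen(cor(resids), symmetric = TRUE)$values
  expect_equal(unname(pca$variance_proportion[1]), ev[1] / sum(ev),
               tolerance = 1e-10)
  # thick-beak species (high depth/width residuals) score negative
  expect_lt(cor(pca$scores$PC1, size_free), 0)
  expect_true(mean(pca$loadings[1:2, 1]) <= 0)
})

test_that("degenerate beak inputs are handled as specified", {
  set.seed(4)
  base <- matrix(rnorm(40), 20, 2)
  dup <- cbind(beak_depth = base[, 1], beak_width = base[, 1],
               beak_nares = base[, 2], beak_culmen = rnorm(20))
  pca <- beak_pca(dup)
  expect_gte(unname(pca$variance_proportion[1]), 0.5)
  const <- dup; const[, 3] <- 1
  expect_error(beak_pca(const), "constant")
})

test_that("residual song frequency centers when mass is constant and is OLS on a star tree", {
  tr <- star_tree(25, labels = sprintf("sp%02d", 1:25))
  set.seed(5)
  d <- tibble::tibble(species_id = tr$tip.label,
                      body_mass = 20, max_song_freq = exp(rnorm(25)))
  r <- residual_song_frequency(d, tr)
  expect_equal(unname(r), log10(d$max_song_freq) - mean(log10(d$max_song_freq)))
  d2 <- dplyr::mutate(d, body_mass = exp(rnorm(25, 3)))
  r2 <- residual_song_frequency(d2, tr)
  ols <- stats::residuals(lm(log10(max_song_freq) ~ log10(body_mass), d2))
  expect_equal(unname(r2), unname(ols), tolerance = 1e-6)
})

test_that("GVIF diagnostics match the inverse-correlation oracle and flag collinearity", {
  set.seed(6)
  n <- 200
  # principal-component scores are exactly uncorrelated
  X <- prcomp(matrix(rnorm(n * 3), n, 3))$x
  P <- tibble::tibble(species_id = sprintf("s%03d", 1:n),
                      a = X[, 1], b = X[, 2], c = X[, 3])
  cc <- collinearity_check(P)
  expect_equal(unname(cc$gvif$gvif_adjusted), rep(1, 3), tolerance = 1e-8)
  expect_false(any(cc$gvif$flagged))
  # correlated predictors: GVIF (det ratio) equals diag(solve(R))
  S <- matrix(0.6, 3, 3); diag(S) <- 1
  Y <- matrix(rnorm(n * 3), n, 3) %*% chol(S)
  P2 <- tibble::tibble(species_id = P$species_id,
                       a = Y[, 1], b = Y[, 2], c = Y[, 3])
  cc2 <- collinearity_check(P2)
  expect_equal(unname(cc2$gvif$gvif), unname(diag(solve(cor(Y)))),
               tolerance = 1e-8)
  # duplicated predictor blows up and is flagged
  P3 <- dplyr::mutate(P2, d = .data$a)
  expect_message(cc3 <- collinearity_check(P3), "flagged")
  expect_true(all(cc3$gvif$flagged[c(1, 4)]) || any(!is.finite(cc3$gvif$gvif)))
})

test_that("standardization is invertible and idempotent", {
  d <- tibble::tibble(a = rnorm(40, 5, 3), b = runif(40))
  s1 <- flocknet:::standardize_columns(d, c("a", "b"))
  expect_equal(colMeans(s1[, c("a", "b")]), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(sapply(s1[, c("a", "b")], sd), c(a = 1, b = 1),
               tolerance = 1e-10)
  st <- attr(s1, "standardization")
  back <- sweep(sweep(as.matrix(s1[, c("a", "b")]), 2, st$scale, "*"),
                2, st$center, "+")
  expect_equal(unname(back), unname(as.matrix(d)), tolerance = 1e-12)
  s2 <- flocknet:::standardize_columns(s1, c("a", "b"))
  expect_equal(as.matrix(s2[, c("a", "b")]), as.matrix(s1[, c("a", "b")]),
               tolerance = 1e-10)
})

test_that("the assembled predictor table is standardized and excludes structural color", {
  st <- small_study(seed = 21)
  pred <- build_predictors(st$traits, st$tree)
  expect_false("structural" %in% names(pred))
  expect_true(all(c("white", "green", "carotenoid", "melanin", "beak_pc1",
                    "res_eye_size", "res_max_frequency") %in% names(pred)))
  for (cl in setdiff(names(pred), "species_id")) {
    expect_lt(abs(mean(pred[[cl]], na.rm = TRUE)), 1e-10)
    expect_equal(sd(pred[[cl]], na.rm = TRUE), 1, tolerance = 1e-10)
  }
  pred2 <- build_predictors(st$traits, st$tree, exclude = character(0))
  expect_true("structural" %in% names(pred2))
})
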