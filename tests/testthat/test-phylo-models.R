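test_that("Newick reading validates what the models need", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:3]), c(2, 2, 2))
  writeLines("((A:1,B:1:1,C:2;", f)
  expect_error(read_newick(f), "parse")
  writeLines("((A,B),C);", f)
  expect_error(read_newick(f), "branch lengths")
  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_newick(f), "duplicate tip")
  writeLines(rep("((A:1,B:1):1,C:2);", 50), f)
  trees <- read_newick(f)
  expect_length(trees, 50)
})

test_that("phylogenetic covariance holds shared path lengths, with lambda scaling", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  C <- phylo_vcv(tr)
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  # star tree: diagonal
  Cs <- phylo_vcv(star_tree(4))
  expect_equal(unname(Cs), diag(4))
  # lambda transform endpoints
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  expect_equal(lambda_transform(C, 1), C)
  C5 <- lambda_transform(C, 0.5)
  expect_equal(C5["A", "B"], 0.5)
  expect_equal(diag(C5), diag(C))
})

test_that("lambda ML recovers the generating signal at small scale", {
  lam_hat <- sapply(1:10, function(i) {
    set.seed(i)
    tr <- ape::rphylo(100, 1, 0)
    tr$tip.label <- sprintf("t%03d", 1:100)
    y <- setNames(drop(crossprod(chol(ape::vcv(tr)), rnorm(100))),
                  tr$tip.label)
    pagel_lambda_ml(y, tr)$lambda
  })
  expect_gte(mean(lam_hat), 0.9)
  noise_hat <- sapply(1:10, function(i) {
    set.seed(100 + i)
    tr <- ape::rphylo(100, 1, 0)
    tr$tip.label <- sprintf("t%03d", 1:100)
    y <- setNames(rnorm(100), tr$tip.label)
    pagel_lambda_ml(y, tr)$lambda
  })
  expect_lt(mean(noise_hat), 0.15)
})

test_that("lambda ML is a maximum and agrees with the phytools reference", {
  set.seed(42)
  tr <- ape::rphylo(80, 1, 0)
  tr$tip.label <- sprintf("t%03d", 1:80)
  C <- ape::vcv(tr)
  y <- setNames(0.5 * drop(crossprod(chol(C), rnorm(80))) + rnorm(80, sd = 0.5),
                tr$tip.label)
  fit <- pagel_lambda_ml(y, tr)
  expect_gte(fit$logLik, fit$logLik0 - 1e-8)
  ll1 <- flocknet:::gls_profile(y, matrix(1, 80, 1), C, 1)$logLik
  expect_gte(fit$logLik, ll1 - 1e-8)
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  skip_if_not_installed("phytools")
  ref <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(fit$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(fit$logLik, ref$logL, tolerance = 1e-3)
})

test_that("PGLS reduces to OLS on a star tree and interpolates exact fits", {
  tr <- star_tree(40, labels = sprintf("s%02d", 1:40))
  set.seed(8)
  d <- tibble::tibble(species_id = tr$tip.label,
                      x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + rnorm(40, sd = 0.4)
  fit <- pgls_fit(d, y ~ x1 + x2, tr, lambda = 0)
  ols <- lm(y ~ x1 + x2, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$coefficients$std.error,
               unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
  d$yx <- 2 + 3 * d$x1
  ex <- pgls_fit(d, yx ~ x1, tr)
  expect_equal(ex$coefficients$estimate, c(2, 3), tolerance = 1e-8)
  expect_lt(ex$sigma2, 1e-16)
})

test_that("PGLS matches the direct GLS solve and is invariant to branch rescaling", {
  set.seed(9)
  tr <- ape::rphylo(50, 1, 0)
  tr$tip.label <- sprintf("s%02d", 1:50)
  C <- ape::vcv(tr)
  X <- cbind(1, rnorm(50), rnorm(50))
  y <- drop(X %*% c(0.2, 0.5, -0.3)) + drop(crossprod(chol(C), rnorm(50)))
  d <- tibble::tibble(species_id = tr$tip.label, x1 = X[, 2], x2 = X[, 3],
                      y = y)
  fit <- pgls_fit(d, y ~ x1 + x2, tr, lambda = 1)
  orc <- oracle_gls(y, X, C)
  expect_equal(fit$coefficients$estimate, unname(orc$beta), tolerance = 1e-8)
  expect_equal(unname(fit$vcov),
               unname(orc$cov_unscaled * orc$rss / (50 - 3)), tolerance = 1e-8)
  # branch-length rescaling: lambda and beta unchanged, sigma2 absorbs scale
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7
  fitA <- pgls_fit(d, y ~ x1 + x2, tr)
  fitB <- pgls_fit(d, y ~ x1 + x2, tr2)
  expect_equal(fitA$coefficients$estimate, fitB$coefficients$estimate,
               tolerance = 1e-5)
  expect_equal(fitA$lambda, fitB$lambda, tolerance = 1e-4)
  expect_equal(fitB$sigma2, fitA$sigma2 / 7, tolerance = 1e-4)
  lamfit <- pagel_lambda_ml(setNames(y, d$species_id), tr)
  lamfit2 <- pagel_lambda_ml(setNames(y, d$species_id), tr2)
  expect_equal(lamfit$lambda, lamfit2$lambda, tolerance = 1e-4)
})

test_that("PGLS agrees with the nlme corPagel reference on ML lambda", {
  skip_if_not_installed("nlme")
  set.seed(10)
  tr <- ape::rphylo(60, 1, 0)
  tr$tip.label <- sprintf("s%02d", 1:60)
  C <- ape::vcv(tr)
  x <- rnorm(60)
  y <- 0.4 * x + 0.7 * drop(crossprod(chol(C), rnorm(60))) + rnorm(60, sd = 0.4)
  d <- data.frame(species_id = tr$tip.label, x = x, y = y)
  fit <- pgls_fit(tibble::as_tibble(d), y ~ x, tr)
  rownames(d) <- d$species_id
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(0.5, tr, form = ~species_id),
                   method = "ML")
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-3)
  expect_equal(fit$lambda, unname(coef(ref$modelStruct$corStruct)),
               tolerance = 0.01)
})

test_that("rank-deficient designs fail naming the aliased column", {
  tr <- star_tree(20, labels = sprintf("s%02d", 1:20))
  d <- tibble::tibble(species_id = tr$tip.label, x1 = rnorm(20))
  d$x2 <- d$x1
  d$y <- rnorm(20)
  expect_error(pgls_fit(d, y ~ x1 + x2, tr), "x2")
})

test_that("the Bayesian model matches OLS on a star tree without phylogenetic variance", {
  tr <- star_tree(120, labels = sprintf("s%03d", 1:120))
  set.seed(12)
  d <- tibble::tibble(species_id = tr$tip.label, x = rnorm(120))
  d$y <- 0.8 * d$x + rnorm(120, sd = 0.5)
  b <- suppressWarnings(
    bayes_phylo_lm(d, y ~ x, tr, chains = 2, iter = 1200, warmup = 600,
                   seed = 3))
  ols <- lm(y ~ x, d)
  se <- sqrt(diag(vcov(ols)))
  expect_lt(abs(b$coefficients$mean[1] - coef(ols)[1]), 0.1 * se[1] + 0.02)
  expect_lt(abs(b$coefficients$mean[2] - coef(ols)[2]), 0.1 * se[2] + 0.02)
  expect_true(all(b$coefficients$rhat[1:2] < 1.1))
})

test_that("pooling identical trees equals a single-tree fit up to Monte Carlo error", {
  tr <- star_tree(60, labels = sprintf("s%02d", 1:60))
  set.seed(13)
  d <- tibble::tibble(species_id = tr$tip.label, x = rnorm(60))
  d$y <- 0.5 * d$x + rnorm(60, sd = 0.6)
  one <- suppressWarnings(
    bayes_phylo_lm(d, y ~ x, tr, chains = 2, iter = 800, warmup = 400,
                   seed = 5))
  five <- suppressWarnings(
    bayes_phylo_lm(d, y ~ x, rep(list(tr), 5), chains = 2, iter = 800,
                   warmup = 400, seed = 5))
  expect_equal(five$n_draws, 5 * one$n_draws)
  sd1 <- apply(one$draws, 2, sd)[1:2]
  expect_lt(max(abs(one$coefficients$mean[1:2] - five$coefficients$mean[1:2]) /
                  sd1), 0.25)
})

test_that("Bayesian fits are reproducible and structured for tidy access", {
  tr <- star_tree(30, labels = sprintf("s%02d", 1:30))
  set.seed(14)
  d <- tibble::tibble(species_id = tr$tip.label, x = rnorm(30))
  d$y <- rnorm(30)
  b1 <- suppressWarnings(
    bayes_phylo_lm(d, y ~ x, tr, chains = 2, iter = 300, warmup = 150,
                   seed = 7))
  b2 <- suppressWarnings(
    bayes_phylo_lm(d, y ~ x, tr, chains = 2, iter = 300, warmup = 150,
                   seed = 7))
  expect_identical(b1$draws, b2$draws)
  td <- tidy(b1)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat",
                    "n_eff") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(b1)
  expect_equal(g$n_trees, 1)
  expect_equal(g$n_draws, 2 * 150)
})

test_that("fit_all_models produces one coefficient table row set per response", {
  st <- small_study(seed = 31)
  ms <- filter_species(lapply(st$flocks, filter_flocks))$matrices
  pr <- flocking_propensity(ms)
  avg <- average_metrics(compute_metrics(ms))
  resp <- dplyr::inner_join(pr[, c("species_id", "log_propensity")], avg,
                            by = "species_id")
  pred <- build_predictors(st$traits, st$tree)
  pred$res_eye_size <- NULL
  res <- suppressWarnings(suppressMessages(
    fit_all_models(resp, pred, st$tree_sample[1:2], chains = 2, iter = 300,
                   warmup = 150, seed = 2)))
  expect_length(res$fits, 4)
  expect_setequal(unique(res$table$response),
                  c("log_propensity", "connectivity", "strength", "closeness"))
  res_pgls <- suppressMessages(
    fit_all_models(resp, pred, st$tree, engine = "pgls",
                   response_cols = "log_propensity"))
  expect_length(res_pgls$fits, 1)
  expect_s3_class(res_pgls$fits[[1]], "pgls_fit")
})
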