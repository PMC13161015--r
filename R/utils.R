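# Internal helpers shared across modules.

# Deterministic derivation of sub-seeds from a master seed, so that any single
# locality/replicate is reproducible in isolation. Kept strictly below 2^31.
derive_seed <- function(master, ...) {
  ks <- c(...)
  s <- as.double(master) %% 2147483629
  for (k in ks) s <- (s * 1000003 + as.double(k) * 10007 + 12345) %% 2147483629
  as.integer(s)
}

# Column standardization (mean 0, SD 1) that remembers its centers/scales so
# it can be inverted, and is a no-op on already-standardized columns.
standardize_columns <- function(data, cols) {
  centers <- scales <- setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    x <- data[[cl]]
    centers[cl] <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    scales[cl] <- if (is.na(s) || s == 0) 1 else s
    data[[cl]] <- (x - centers[cl]) / scales[cl]
  }
  attr(data, "standardization") <- list(center = centers, scale = scales)
  data
}

# Draw one multivariate normal vector given the upper Cholesky factor of the
# covariance (as returned by chol()).
rmvnorm_chol <- function(mean, chol_upper) {
  drop(mean + crossprod(chol_upper, rnorm(nrow(chol_upper))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
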