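# Independent oracles and small fixture builders used across the suite.

# Brute-force unipartite projection: count flocks shared by each species pair.
oracle_project <- function(occ) {
  S <- ncol(occ)
  W <- matrix(0L, S, S, dimnames = list(colnames(occ), colnames(occ)))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) next
    W[i, j] <- sum(occ[, i] == 1 & occ[, j] == 1)
  }
  W
}

# Wasserman-Faust weighted closeness recomputed through igraph's Dijkstra.
oracle_closeness <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(ifelse(W > 0, 1 / W, 0),
                                           mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g)
  S <- ncol(W)
  vapply(seq_len(S), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    R <- sum(reach)
    if (R == 0) return(0)
    (R / (S - 1)) * (R / sum(di[reach]))
  }, numeric(1))
}

# Direct GLS solve, no factorization shortcuts: beta = (X'C^-1X)^-1 X'C^-1 y.
oracle_gls <- function(y, X, C) {
  Ci <- solve(C)
  XtCiX <- t(X) %*% Ci %*% X
  beta <- solve(XtCiX, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Ci %*% r)
  list(beta = drop(beta), rss = rss,
       cov_unscaled = solve(XtCiX))
}

# Exhaustive enumeration of binary matrices with the given margins.
# Returns a character vector of keys (concatenated 0/1 cells).
enumerate_margin_matrices <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  stopifnot(nr * nc <= 20)
  n_cells <- nr * nc
  keys <- character(0)
  for (code in 0:(2^n_cells - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(n_cells)])
    m <- matrix(bits, nr, nc)
    if (all(rowSums(m) == row_sums) && all(colSums(m) == col_sums))
      keys <- c(keys, paste(bits, collapse = ""))
  }
  keys
}

matrix_key <- function(m) paste(as.integer(m), collapse = "")

# Star phylogeny with unit terminal branches.
star_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  tr <- ape::stree(n, type = "star")
  tr$tip.label <- labels
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# The three-flock toy: rows {ABC}, {ABD}, {BCD}.
toy_flock_matrix <- function() {
  occ <- rbind(f1 = c(A = 1, B = 1, C = 1, D = 0),
               f2 = c(A = 1, B = 1, C = 0, D = 1),
               f3 = c(A = 0, B = 1, C = 1, D = 1))
  flock_matrix(occ, "toy")
}

random_flock_matrix <- function(nr, nc, p = 0.4, seed = 1, locality = "rand") {
  set.seed(seed)
  repeat {
    occ <- matrix(rbinom(nr * nc, 1, p), nr, nc,
                  dimnames = list(paste0("f", seq_len(nr)),
                                  paste0("s", seq_len(nc))))
    if (all(rowSums(occ) > 0) && sum(colSums(occ) > 0) >= 2) break
  }
  flock_matrix(occ, locality)
}

# A small synthetic study shared by several tests (cheap to build).
small_study <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_species = 80, n_localities = 8, flocks_per_locality = 25,
         pool_size = 25, n_trees = 3, seed = seed),
    list(...))
  simulate_study(do.call(sim_config, args))
}
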