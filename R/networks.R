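#' Project a flock matrix to a species co-occurrence network
#'
#' The bipartite flock-by-species table is projected to a unipartite weighted
#' graph: the edge weight between two species is the number of flocks that
#' contained both. Species with no occurrence at the locality are not part of
#' its network.
#'
#' @param m A filtered [flock_matrix()].
#' @return A `cooccurrence_network`: a symmetric integer weight matrix with a
#'   zero diagonal and a `locality_id` attribute.
#' @examples
#' occ <- matrix(c(1,1,0, 1,1,1, 1,0,1, 0,1,1), nrow = 3,
#'               dimnames = list(paste0("f", 1:3), c("A", "B", "C", "D")))
#' project_unipartite(flock_matrix(occ, "toy"))
#' @export
project_unipartite <- function(m) {
  present <- colSums(m) > 0
  occ <- unclass(m)[, present, drop = FALSE]
  if (ncol(occ) < 2L)
    stop("locality '", locality_id(m),
         "': fewer than two species present, no network", call. = FALSE)
  W <- crossprod(occ)
  storage.mode(W) <- "integer"
  diag(W) <- 0L
  structure(W, locality_id = locality_id(m),
            class = c("cooccurrence_network", class(W)))
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> locality '", attr(x, "locality_id"), "': ",
      ncol(x), " species, ", sum(x > 0) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Species-level network metrics
#'
#' For each species (node) in a locality network:
#' * `connectivity` — normalized degree: the proportion of the other species
#'   in the network it co-occurs with, degree / (S - 1);
#' * `strength` — the sum of its co-occurrence edge weights (total frequency
#'   of interspecific association);
#' * `closeness` — weighted closeness centrality on edge lengths 1/weight, so
#'   stronger associations are shorter distances. On disconnected networks the
#'   Wasserman–Faust component scaling is used:
#'   `(R/(S-1)) * (R / sum of distances to the R reachable nodes)`, which gives
#'   small components low but finite closeness; isolated nodes get 0.
#'
#' @param net A `cooccurrence_network` from [project_unipartite()].
#' @param species Optional character vector restricting the output.
#' @return A tibble with `species_id`, `locality_id`, `connectivity`,
#'   `strength`, `closeness`.
#' @export
species_metrics <- function(net, species = NULL) {
  W <- unclass(net)
  S <- ncol(W)
  if (S < 2L) stop("network has fewer than two species", call. = FALSE)
  deg <- colSums(W > 0)
  conn <- deg / (S - 1)
  stren <- colSums(W)
  close <- closeness_from_weights(W)
  out <- tibble::tibble(
    species_id = colnames(W),
    locality_id = attr(net, "locality_id") %||% NA_character_,
    connectivity = as.numeric(conn),
    strength = as.numeric(stren),
    closeness = as.numeric(close)
  )
  if (!is.null(species)) {
    missing_sp <- setdiff(species, out$species_id)
    if (length(missing_sp))
      stop("species not in network: ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    out <- out[match(species, out$species_id), ]
  }
  out
}

# Wasserman-Faust closeness for every node from a weight matrix.
closeness_from_weights <- function(W) {
  S <- ncol(W)
  len <- ifelse(W > 0, 1 / W, 0)
  d <- shortest_paths_cpp(len)
  reach <- is.finite(d)
  diag(reach) <- FALSE
  R <- rowSums(reach)
  d[!reach] <- 0
  sumd <- rowSums(d)
  ifelse(R == 0, 0, (R / (S - 1)) * (R / pmax(sumd, .Machine$double.xmin)))
}

#' @rdname species_metrics
#' @export
connectivity <- function(net, species = NULL) {
  mt <- species_metrics(net, species)
  setNames(mt$connectivity, mt$species_id)
}

#' @rdname species_metrics
#' @export
strength <- function(net, species = NULL) {
  mt <- species_metrics(net, species)
  setNames(mt$strength, mt$species_id)
}

#' @rdname species_metrics
#' @export
weighted_closeness <- function(net, species = NULL) {
  mt <- species_metrics(net, species)
  setNames(mt$closeness, mt$species_id)
}

#' Metrics for every locality in a dataset
#'
#' @param ms List of filtered [flock_matrix()] objects.
#' @return A tibble of per-locality [species_metrics()] rows.
#' @export
compute_metrics <- function(ms) {
  purrr::map_dfr(ms, function(m) species_metrics(project_unipartite(m)))
}

#' Average species metrics across localities
#'
#' The per-species mean of each metric over the localities where the species
#' occurred (plain arithmetic mean, unweighted by locality size).
#'
#' @param metrics A tibble from [compute_metrics()] (or any tibble with
#'   `species_id`, `locality_id` and metric columns).
#' @param cols Metric columns to average.
#' @return A tibble with one row per species: metric means and `n_localities`.
#' @export
average_metrics <- function(metrics,
                            cols = c("connectivity", "strength", "closeness")) {
  metrics |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cols), ~ mean(.x, na.rm = TRUE)),
      n_localities = dplyr::n(),
      .groups = "drop"
    )
}

#' Pool locality networks into one metanetwork
#'
#' Sums co-occurrence weights over localities on the union of species. This
#' is an optional variant: the default analysis averages per-locality metrics
#' rather than analysing the pooled graph.
#'
#' @param nets List of `cooccurrence_network` objects.
#' @return A `cooccurrence_network` with locality id `"POOLED"`.
#' @export
pool_networks <- function(nets) {
  sp <- sort(unique(unlist(lapply(nets, colnames))))
  W <- matrix(0L, length(sp), length(sp), dimnames = list(sp, sp))
  for (net in nets) {
    i <- match(colnames(net), sp)
    W[i, i] <- W[i, i] + unclass(net)
  }
  structure(W, locality_id = "POOLED",
            class = c("cooccurrence_network", class(W)))
}

#' Edge list of a co-occurrence network
#'
#' @param net A `cooccurrence_network`.
#' @return A tibble with `species_a`, `species_b`, `weight` (upper triangle,
#'   positive weights only).
#' @export
network_edges <- function(net) {
  W <- unclass(net)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  tibble::tibble(
    species_a = rownames(W)[idx[, 1]],
    species_b = colnames(W)[idx[, 2]],
    weight = W[idx]
  )
}
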