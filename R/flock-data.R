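#' Construct a flock occurrence matrix
#'
#' A `flock_matrix` is one locality's binary flock-by-species occurrence
#' table: rows are individual mixed-species flocks, columns are species, and
#' a cell is 1 when the species was recorded in that flock.
#'
#' @param occ A binary (0/1) matrix with flock ids as row names and species
#'   ids as column names.
#' @param locality_id Single string identifying the locality.
#' @return An integer matrix of class `flock_matrix` with a `locality_id`
#'   attribute.
#' @examples
#' occ <- matrix(c(1, 1, 0, 1, 0, 1), nrow = 2,
#'               dimnames = list(c("f1", "f2"), c("a", "b", "c")))
#' flock_matrix(occ, "loc1")
#' @export
flock_matrix <- function(occ, locality_id) {
  if (!is.matrix(occ)) occ <- as.matrix(occ)
  storage.mode(occ) <- "integer"
  if (is.null(rownames(occ))) rownames(occ) <- paste0("flock", seq_len(nrow(occ)))
  if (is.null(colnames(occ))) stop("species ids (column names) are required", call. = FALSE)
  rownames(occ) <- trimws(rownames(occ))
  colnames(occ) <- trimws(colnames(occ))
  m <- structure(occ, locality_id = as.character(locality_id)[1],
                 class = c("flock_matrix", class(occ)))
  validate_flock_matrix(m)
}

validate_flock_matrix <- function(m) {
  loc <- locality_id(m)
  if (nrow(m) == 0L) stop("locality '", loc, "': no flocks", call. = FALSE)
  if (ncol(m) == 0L) stop("locality '", loc, "': no species", call. = FALSE)
  bad <- which(!(m %in% c(0L, 1L)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(m))
    stop("locality '", loc, "': non-binary cell at flock '",
         rownames(m)[idx[1]], "', species '", colnames(m)[idx[2]], "'",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)))
    stop("locality '", loc, "': duplicate flock ids", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("locality '", loc, "': duplicate species ids", call. = FALSE)
  m
}

#' @rdname flock_matrix
#' @param m A `flock_matrix`.
#' @export
locality_id <- function(m) attr(m, "locality_id")

#' @export
print.flock_matrix <- function(x, ...) {
  cat("<flock_matrix> locality '", locality_id(x), "': ",
      nrow(x), " flocks x ", ncol(x), " species, ",
      sum(x), " occurrences\n", sep = "")
  invisible(x)
}

# Rebuild class/attributes after subsetting with [ , , drop = FALSE]
restore_flock_matrix <- function(occ, template) {
  structure(occ, locality_id = locality_id(template),
            class = c("flock_matrix", class(occ)[class(occ) != "flock_matrix"]))
}

#' Read per-locality flock occurrence tables from CSV
#'
#' Each CSV holds one locality: first column flock ids, remaining columns one
#' per species, cells 0/1. The locality id is the file name without
#' extension. Ids are whitespace-trimmed; non-binary cells, duplicate ids and
#' empty files are rejected.
#'
#' @param path Directory containing one CSV per locality.
#' @return A named list of [flock_matrix()] objects.
#' @export
read_flock_tables <- function(path) {
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no CSV files found in '", path, "'", call. = FALSE)
  out <- lapply(files, function(f) {
    loc <- sub("\\.csv$", "", basename(f))
    df <- tryCatch(
      readr::read_csv(f, col_types = readr::cols(), progress = FALSE,
                      show_col_types = FALSE, name_repair = "minimal"),
      error = function(e) stop("failed to parse '", basename(f), "': ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(df) == 0L) stop("'", basename(f), "': no flocks", call. = FALSE)
    if (ncol(df) < 2L) stop("'", basename(f), "': no species columns", call. = FALSE)
    occ <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(occ))
      stop("'", basename(f), "': non-numeric occurrence cells", call. = FALSE)
    rownames(occ) <- as.character(df[[1]])
    flock_matrix(occ, loc)
  })
  names(out) <- vapply(out, locality_id, character(1))
  out
}

#' Write flock matrices as per-locality CSV files
#'
#' @param ms List of [flock_matrix()] objects.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_flock_tables <- function(ms, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (m in ms) {
    df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "flock_id")
    readr::write_csv(df, file.path(path, paste0(locality_id(m), ".csv")))
  }
  invisible(path)
}

#' Drop flocks below a minimum species richness
#'
#' Mixed-species flocks are conventionally required to hold at least three
#' species; flocks (rows) whose species count is below `min_species` are
#' removed. Columns are untouched.
#'
#' @param m A [flock_matrix()].
#' @param min_species Minimum number of species per retained flock.
#' @return A filtered `flock_matrix`.
#' @export
filter_flocks <- function(m, min_species = 3) {
  keep <- rowSums(m) >= min_species
  if (!any(keep))
    stop("locality '", locality_id(m), "': no flocks survive filter",
         call. = FALSE)
  restore_flock_matrix(m[keep, , drop = FALSE], m)
}

#' Drop species recorded in too few flocks, dataset-wide
#'
#' Species whose total occurrence count across all localities is below
#' `min_flocks` are removed from every matrix. Because removing a species can
#' push a flock below the `min_species` rule (and removing a flock can push a
#' species below `min_flocks`), both filters are re-applied to a fixed point,
#' so the returned matrices satisfy both constraints simultaneously.
#'
#' @param ms List of [flock_matrix()] objects, already flock-filtered.
#' @param min_flocks Minimum total number of flocks a species must occur in.
#' @param min_species Minimum species per flock, re-checked after species
#'   removal.
#' @return List with `matrices` (localities that retain at least one flock)
#'   and `species` (character vector of retained species ids).
#' @export
filter_species <- function(ms, min_flocks = 3, min_species = 3) {
  repeat {
    counts <- species_occurrence_counts(ms)
    drop_sp <- names(counts)[counts < min_flocks]
    changed <- length(drop_sp) > 0
    if (changed) {
      ms <- lapply(ms, function(m) {
        keep <- !(colnames(m) %in% drop_sp)
        restore_flock_matrix(m[, keep, drop = FALSE], m)
      })
    }
    pruned <- lapply(ms, function(m) {
      keep <- rowSums(m) >= min_species
      restore_flock_matrix(m[keep, , drop = FALSE], m)
    })
    if (any(vapply(ms, nrow, 1L) != vapply(pruned, nrow, 1L))) changed <- TRUE
    ms <- pruned
    empty <- vapply(ms, function(m) nrow(m) == 0L || sum(m) == 0L, logical(1))
    if (any(empty)) {
      changed <- TRUE
      ms <- ms[!empty]
    }
    if (!length(ms)) {
      warning("no flocks survive joint filtering; empty species set")
      return(list(matrices = list(), species = character(0)))
    }
    if (!changed) break
  }
  species <- sort(unique(unlist(lapply(ms, colnames))))
  # species columns that became all-zero in a locality stay (they carry no
  # co-occurrence there); species with zero total occurrences cannot remain
  # by construction of the fixed point
  if (!length(species)) warning("empty species set after filtering")
  list(matrices = ms, species = species)
}

species_occurrence_counts <- function(ms) {
  tallies <- lapply(ms, colSums)
  all_sp <- unique(unlist(lapply(tallies, names)))
  out <- setNames(numeric(length(all_sp)), all_sp)
  for (tl in tallies) out[names(tl)] <- out[names(tl)] + tl
  out
}

#' Flocking propensity per species
#'
#' Flocking propensity is the proportion of flocks in which a species was
#' detected, pooled across localities. With `denominator = "global"` the
#' denominator is every flock in the dataset; with `"range"` it is only the
#' flocks at localities where the species was recorded at least once.
#' Propensity is natural-log transformed (`log_propensity`) for modeling;
#' retained species occur in at least one flock so the log is always finite.
#'
#' @param ms List of filtered [flock_matrix()] objects.
#' @param denominator `"global"` (all flocks) or `"range"` (flocks at
#'   occupied localities).
#' @return A tibble with `species_id`, `n_flocks_present`, `n_flocks_total`,
#'   `propensity`, `log_propensity`.
#' @export
flocking_propensity <- function(ms, denominator = c("global", "range")) {
  denominator <- match.arg(denominator)
  counts <- species_occurrence_counts(ms)
  counts <- counts[counts > 0]
  n_total_global <- sum(vapply(ms, nrow, 1L))
  if (denominator == "global") {
    totals <- setNames(rep(n_total_global, length(counts)), names(counts))
  } else {
    per_loc <- vapply(ms, nrow, 1L)
    totals <- vapply(names(counts), function(sp) {
      occ <- vapply(ms, function(m) sp %in% colnames(m) && sum(m[, sp]) > 0,
                    logical(1))
      sum(per_loc[occ])
    }, numeric(1))
  }
  tibble::tibble(
    species_id = names(counts),
    n_flocks_present = as.integer(counts),
    n_flocks_total = as.integer(totals),
    propensity = as.numeric(counts / totals),
    log_propensity = log(as.numeric(counts / totals))
  ) |>
    dplyr::arrange(.data$species_id)
}
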