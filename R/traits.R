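# Names of the 12 human-visible plumage color categories and their grouping
# into five broader classes by pigmentary/structural origin.
color_categories <- c("blue", "purple", "yellow", "orange", "red", "pink",
                      "black", "grey", "brown", "rufous", "green", "white")

color_class_map <- list(
  structural = c("blue", "purple"),
  carotenoid = c("yellow", "orange", "red", "pink"),
  melanin = c("black", "grey", "brown", "rufous"),
  green = "green",
  white = "white"
)

#' Group the 12 plumage color categories into five classes
#'
#' Structural (blue + purple), carotenoid-based (yellow + orange + red),
#' melanin-based (black + grey + brown + rufous); green and white pass
#' through unchanged. Proportions are body-coverage fractions, so the five
#' classes conserve the total coverage of the 12 inputs exactly.
#'
#' @param traits A data frame with the 12 color category columns (body
#'   coverage proportions) and `species_id`.
#' @return A tibble with `species_id` and the five class proportions.
#' @export
group_colors <- function(traits) {
  needed <- unlist(color_class_map, use.names = FALSE)
  missing_cols <- setdiff(needed, names(traits))
  if (length(missing_cols))
    stop("missing color category columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(species_id = traits$species_id)
  for (cls in names(color_class_map)) {
    cols <- color_class_map[[cls]]
    out[[cls]] <- rowSums(as.matrix(traits[, cols, drop = FALSE]))
  }
  out
}

#' Phylogenetic size-correction residuals
#'
#' Residuals of the phylogenetic GLS regression of `y` on `x`, with Pagel's
#' lambda estimated jointly by maximum likelihood (the same size-correction
#' as the classic `phyl.resid` approach). On a star phylogeny (or when
#' `lambda_hat = 0`) these reduce to ordinary least-squares residuals.
#'
#' @param data Data frame with `species_id` and the two trait columns.
#' @param y,x Column names (strings) of the response and the size variable.
#' @param tree A `phylo` object.
#' @return A named numeric vector of residuals (NA for incomplete cases),
#'   aligned with `data$species_id`.
#' @export
phylo_residuals <- function(data, y, x, tree) {
  stopifnot("species_id" %in% names(data))
  fml <- stats::as.formula(paste(y, "~", x))
  fit <- pgls_fit(data, fml, tree, lambda = "ML")
  out <- setNames(rep(NA_real_, nrow(data)), data$species_id)
  out[fit$species] <- fit$residuals
  out
}

#' Summarize beak morphology by PCA of size-corrected measurements
#'
#' PCA on the correlation matrix of the four phylogenetic size-residuals of
#' beak depth, width, length-to-nares and length-to-culmen. PC1 is used as a
#' composite beak-shape axis; its sign is fixed so that large, thick beaks
#' score negative (the PC is flipped when the mean loading of depth and width
#' is positive).
#'
#' @param resids Data frame (or matrix) whose columns are the four
#'   size-corrected beak variables; rows named (or a `species_id` column).
#' @return List with `scores` (tibble: `species_id`, `PC1`...),
#'   `loadings`, and `variance_proportion`.
#' @export
beak_pca <- function(resids) {
  if (is.data.frame(resids) && "species_id" %in% names(resids)) {
    sp <- resids$species_id
    mat <- as.matrix(resids[, setdiff(names(resids), "species_id")])
    rownames(mat) <- sp
  } else {
    mat <- as.matrix(resids)
    if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  }
  cc <- complete.cases(mat)
  mat <- mat[cc, , drop = FALSE]
  sds <- apply(mat, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- prcomp(mat, center = TRUE, scale. = TRUE)
  # sign convention: thick beaks (high depth/width residuals) score negative
  dw <- grep("depth|width", colnames(mat), ignore.case = TRUE)
  if (length(dw) && mean(pc$rotation[dw, 1]) > 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  varprop <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = tibble::as_tibble(pc$x, rownames = "species_id"),
    loadings = pc$rotation,
    variance_proportion = setNames(varprop, colnames(pc$x))
  )
}

#' Size-corrected maximum song frequency
#'
#' Residuals of a PGLS allometric regression of log10 maximum song frequency
#' on log10 body mass (larger birds sing lower; the expected slope is
#' negative). Set `log10_transform = FALSE` to residualize the raw scales.
#'
#' @param data Data frame with `species_id`, `max_song_freq` (kHz) and
#'   `body_mass` (g).
#' @param tree A `phylo` object.
#' @param log10_transform Log10 both variables before residualizing
#'   (default).
#' @return Named numeric vector of residuals aligned with
#'   `data$species_id`.
#' @export
residual_song_frequency <- function(data, tree, log10_transform = TRUE) {
  d <- data
  if (log10_transform) {
    d$.freq <- log10(d$max_song_freq)
    d$.mass <- log10(d$body_mass)
  } else {
    d$.freq <- d$max_song_freq
    d$.mass <- d$body_mass
  }
  if (sd(d$.mass, na.rm = TRUE) == 0) {
    out <- d$.freq - mean(d$.freq, na.rm = TRUE)
    return(setNames(out, d$species_id))
  }
  phylo_residuals(d, ".freq", ".mass", tree)
}

#' Assemble the standardized predictor table
#'
#' Builds the model predictors from a raw trait table: five plumage color
#' classes, beak-shape PC1 from phylogenetically size-corrected beak
#' measurements, residual eye size (log10 axial diameter on log10 mass,
#' PGLS), and residual maximum song frequency. All predictors are then
#' standardized to mean 0, SD 1 over complete cases. Predictors listed in
#' `exclude` (by default structural coloration, which is strongly negatively
#' correlated with melanin-based coloration) are dropped from the returned
#' table.
#'
#' @param traits Trait table: `species_id`, `body_mass`, `beak_depth`,
#'   `beak_width`, `beak_nares`, `beak_culmen`, `max_song_freq`, optional
#'   `eye_ad`, and the 12 color categories.
#' @param tree A `phylo` object covering the species.
#' @param exclude Character vector of predictors to drop after assembly.
#' @return A tibble with `species_id` and standardized predictor columns;
#'   standardization centers/scales stored in the `"standardization"`
#'   attribute, beak PCA summary in `"beak_pca"`.
#' @export
build_predictors <- function(traits, tree, exclude = "structural") {
  cols <- group_colors(traits)
  d <- traits
  d$.lmass <- log10(d$body_mass)
  beak_res <- sapply(c("beak_depth", "beak_width", "beak_nares", "beak_culmen"),
                     function(v) {
                       d2 <- d
                       d2$.y <- log10(d2[[v]])
                       phylo_residuals(d2, ".y", ".lmass", tree)
                     })
  pca <- beak_pca(beak_res)
  pc1 <- setNames(pca$scores$PC1, pca$scores$species_id)
  out <- cols
  out$beak_pc1 <- as.numeric(pc1[out$species_id])
  if ("eye_ad" %in% names(traits) && any(!is.na(traits$eye_ad))) {
    d2 <- d
    d2$.y <- log10(d2$eye_ad)
    out$res_eye_size <- as.numeric(phylo_residuals(d2, ".y", ".lmass", tree)[out$species_id])
  }
  out$res_max_frequency <-
    as.numeric(residual_song_frequency(traits, tree)[out$species_id])
  pred_cols <- setdiff(names(out), "species_id")
  out <- standardize_columns(out, pred_cols)
  std <- attr(out, "standardization")
  out <- out[, c("species_id", setdiff(pred_cols, exclude))]
  attr(out, "standardization") <- std
  attr(out, "beak_pca") <- pca[c("loadings", "variance_proportion")]
  out
}

#' Collinearity diagnostics for a predictor table
#'
#' Pairwise Pearson and Spearman correlations plus generalized variance
#' inflation factors computed from determinant ratios of the predictor
#' correlation matrix: `GVIF_j = det(R_j) * det(R_-j) / det(R)`. For a
#' single-column (1 df) predictor this is the ordinary VIF, and
#' `GVIF^(1/(2*Df)) = sqrt(VIF)`; values at or above `flag_threshold` are
#' flagged.
#'
#' @param predictors Tibble from [build_predictors()] (or any numeric
#'   predictor table with `species_id`).
#' @param flag_threshold Flag predictors whose `GVIF^(1/(2Df))` meets this
#'   value.
#' @return List with `pearson`, `spearman` (correlation matrices) and `gvif`
#'   (tibble: `term`, `gvif`, `df`, `gvif_adjusted`, `flagged`).
#' @export
collinearity_check <- function(predictors, flag_threshold = 2) {
  mat <- as.matrix(predictors[, setdiff(names(predictors), "species_id")])
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (ncol(mat) < 2) stop("need at least 2 predictors", call. = FALSE)
  R <- cor(mat)
  Rs <- cor(mat, method = "spearman")
  detR <- det(R)
  gvif <- vapply(seq_len(ncol(R)), function(j) {
    if (detR <= .Machine$double.eps) return(Inf)
    det(R[j, j, drop = FALSE]) * det(R[-j, -j, drop = FALSE]) / detR
  }, numeric(1))
  adj <- gvif^(1 / 2)  # Df = 1 per continuous predictor
  tbl <- tibble::tibble(term = colnames(R), gvif = gvif, df = 1L,
                        gvif_adjusted = adj,
                        flagged = adj >= flag_threshold)
  if (any(tbl$flagged))
    message("collinearity flagged for: ",
            paste(tbl$term[tbl$flagged], collapse = ", "))
  list(pearson = R, spearman = Rs, gvif = tbl)
}
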