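coef_interval_plot <- function(tbl, title) {
  tbl <- dplyr::filter(tbl, .data$term != "(Intercept)")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "standardized effect", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @rdname bayes_phylo_lm
#' @param object A fitted model.
#' @export
autoplot.phylo_blm <- function(object, ...) {
  coef_interval_plot(tidy(object),
                     "Posterior means and 95% credible intervals")
}

#' @rdname pgls_fit
#' @param object A fitted model.
#' @export
autoplot.pgls_fit <- function(object, ...) {
  coef_interval_plot(tidy(object), "PGLS estimates and 95% CIs")
}

#' Plot a species co-occurrence network
#'
#' Species on a circle, edges weighted by co-occurrence count.
#'
#' @param net A `cooccurrence_network`.
#' @param label Draw species labels.
#' @return A ggplot object.
#' @export
plot_network <- function(net, label = TRUE) {
  sp <- colnames(net)
  S <- length(sp)
  th <- 2 * pi * (seq_len(S) - 1) / S
  pos <- tibble::tibble(species_id = sp, x = cos(th), y = sin(th))
  ed <- network_edges(net) |>
    dplyr::left_join(pos, by = c(species_a = "species_id")) |>
    dplyr::left_join(pos, by = c(species_b = "species_id"),
                     suffix = c("", "end"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      alpha = 0.4) +
    ggplot2::geom_point(data = pos, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Co-occurrence network, locality '",
                                 attr(net, "locality_id"), "'"))
  if (label)
    p <- p + ggplot2::geom_text(
      data = pos,
      ggplot2::aes(x = 1.08 * .data$x, y = 1.08 * .data$y,
                   label = .data$species_id),
      size = 2.7)
  p
}

#' Histogram of standardized effect sizes by metric
#'
#' @param z A tibble from [z_scores()].
#' @return A ggplot object.
#' @export
plot_z_scores <- function(z) {
  ggplot2::ggplot(dplyr::filter(z, !is.na(.data$z)),
                  ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "z-score (observed vs fixed-fixed null)",
                  y = "species-locality count") +
    ggplot2::theme_minimal()
}
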