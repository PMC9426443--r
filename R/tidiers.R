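## broom-style tidiers and ggplot2 methods for the package's result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted-curve table
#'
#' One row per gene and candidate family with the fit statistics; parameters
#' stay in a list column (use [query_curve()] to evaluate curves).
#'
#' @param x a `diel_fits` table.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.diel_fits <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Per-gene fit summary
#'
#' @param x a `diel_fits` table.
#' @param ... unused.
#' @return tibble with one row per gene: `gene_id`, `best_family`,
#'   `best_aicc`, `best_weight`, `n_obs`.
#' @export
glance.diel_fits <- function(x, ...) {
  best <- dplyr::filter(x, .data$best)
  tibble::tibble(gene_id = best$gene_id, best_family = best$family,
                 best_aicc = best$aicc, best_weight = best$weight,
                 n_obs = best$n_obs)
}

#' Tidy a diel simulation into long component-mass format
#'
#' @param x a `diel_simulation`.
#' @param ... unused.
#' @return tibble `t`, `component`, `mass`.
#' @export
tidy.diel_simulation <- function(x, ...) {
  traj <- x$trajectory
  long <- tidyr::pivot_longer(traj,
                              dplyr::starts_with("mass_"),
                              names_to = "component",
                              names_prefix = "mass_",
                              values_to = "mass")
  long[, c("t", "component", "mass")]
}

#' One-row summary of a diel simulation
#'
#' @param x a `diel_simulation`.
#' @param ... unused.
#' @return tibble: `status`, `hours`, `dt`, `final_normalized`,
#'   `dumped_total`, `u_max`.
#' @export
glance.diel_simulation <- function(x, ...) {
  fin <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(status = x$status, hours = x$hours, dt = x$dt,
                 final_normalized = fin$normalized,
                 dumped_total = fin$dumped_cum, u_max = x$u_max)
}

#' Plot a diel simulation: component masses and total biomass
#'
#' Stacked component masses over time, with the light phase shaded and the
#' normalized total overlaid.
#'
#' @param object a `diel_simulation`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.diel_simulation <- function(object, ...) {
  long <- tidy(object)
  nights <- tibble::tibble(
    xmin = seq(12, max(long$t), by = 24),
    xmax = pmin(seq(24, max(long$t) + 12, by = 24), max(long$t)))
  nights <- nights[nights$xmin < max(long$t), ]
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(data = nights,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       fill = "grey85", alpha = 0.5) +
    ggplot2::geom_area(ggplot2::aes(x = .data$t, y = .data$mass,
                                    fill = .data$component)) +
    ggplot2::geom_line(data = object$trajectory,
                       ggplot2::aes(x = .data$t, y = .data$total),
                       linewidth = 0.8) +
    ggplot2::labs(x = "time since light onset (h)", y = "biomass (g)",
                  fill = "component") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fitted expression curves against the measured points
#'
#' @param fits a `diel_fits` table.
#' @param expression the expression table the fits came from.
#' @param genes genes to show.
#' @param dt curve sampling interval (h).
#' @return a ggplot object, faceted by gene.
#' @export
plot_expression_fit <- function(fits, expression, genes, dt = 0.1) {
  expression <- normalize_expression_columns(expression)
  pts <- dplyr::filter(expression, .data$gene_id %in% genes)
  curves <- query_curve(fits, genes, seq(0, 24, by = dt))
  lab <- stats::setNames(
    paste0(glance.diel_fits(fits[fits$gene_id %in% genes, ])$gene_id, " (",
           glance.diel_fits(fits[fits$gene_id %in% genes, ])$best_family, ")"),
    glance.diel_fits(fits[fits$gene_id %in% genes, ])$gene_id)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$time,
                                                 y = .data$fpkm)) +
    ggplot2::geom_line(data = curves, ggplot2::aes(x = .data$time,
                                                   y = .data$value),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~gene_id, scales = "free_y",
                        labeller = ggplot2::labeller(gene_id = lab)) +
    ggplot2::labs(x = "time since light onset (h)", y = "FPKM") +
    ggplot2::theme_minimal()
}

#' Plot a knockout scan as ranked biomass ratios
#'
#' Each vertical line is one gene knockout, ordered by final biomass
#' relative to the wild type; dashed guides mark the under- and
#' overperformance thresholds.
#'
#' @param object a `knockout_scan` table.
#' @param underperform_threshold,overperform_threshold classification
#'   thresholds to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.knockout_scan <- function(object, underperform_threshold = 0.75,
                                   overperform_threshold = 1.10, ...) {
  res <- dplyr::filter(object, .data$gene_id != "WT",
                       !is.na(.data$relative_to_wt))
  res <- dplyr::arrange(res, .data$relative_to_wt)
  res$rank <- seq_len(nrow(res))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$rank,
                                    y = .data$relative_to_wt)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$rank, y = 0,
                                       yend = .data$relative_to_wt),
                          linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(underperform_threshold, 1,
                                       overperform_threshold),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = c("firebrick", "grey40", "seagreen")) +
    ggplot2::labs(x = "knockout rank", y = "biomass relative to wild type") +
    ggplot2::theme_minimal()
}
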