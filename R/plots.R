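#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot single-cell trajectories and the ON fraction
#'
#' Thin lines are single-cell reporter trajectories (a subsample), the thick
#' line the fraction of cells above `threshold`, and the dashed line the
#' threshold itself.
#'
#' @param object a `gal_ensemble`.
#' @param threshold ON/OFF threshold; default derives it from the ensemble.
#' @param max_cells trajectories to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gal_ensemble <- function(object, threshold = NULL, max_cells = 100,
                                  ...) {
  if (is.null(threshold)) threshold <- ensemble_threshold(object)
  df <- tidy(object)
  keep <- unique(df$cell)[seq_len(min(max_cells, nrow(object$signal)))]
  frac <- tibble::tibble(
    time_min = object$time,
    fraction_on = colMeans(object$signal > threshold))
  sig_max <- max(df$signal)
  ggplot2::ggplot(df[df$cell %in% keep, ],
                  ggplot2::aes(x = .data$time_min, y = .data$signal)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$cell), alpha = 0.15,
                       colour = "#6a3d9a") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_line(data = frac,
                       ggplot2::aes(y = .data$fraction_on * sig_max),
                       colour = "darkgreen", linewidth = 1.2) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / sig_max, name = "fraction ON")) +
    ggplot2::labs(x = "time after induction (min)",
                  y = "reporter signal (a.u.)",
                  title = sprintf("[gal] = %g%%", object$gal)) +
    ggplot2::theme_minimal()
}

#' Plot a chi-squared fit surface
#'
#' @param object a `gal_fit`.
#' @param ... unused.
#' @return A ggplot object (log-log tile map of the chi-squared surface with
#'   the minimum marked).
#' @export
autoplot.gal_fit <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$rho, y = .data$kgal,
                               fill = log10(.data$chi2 + 1))) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$rho_hat, y = object$kgal_hat,
                      colour = "red", shape = 4, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "log10 chi2") +
    ggplot2::labs(x = "rho_Gal3", y = "Kgal (% w/v)") +
    ggplot2::theme_minimal()
}

#' Plot a phenotypic landscape
#'
#' @param object a `gal_landscape` from [landscape()].
#' @param alleles optional tibble with `strain`, `rho`, `kgal` (and
#'   optionally `rho_lo`, `rho_hi`, `kgal_lo`, `kgal_hi` error bars) to
#'   overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gal_landscape <- function(object, alleles = NULL, ...) {
  pal <- c(gradual = "#b15928", binary = "#fb9a99",
           intermediate = "grey95", no_response = "grey70")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$rho, y = .data$kgal,
                                    fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = pal, name = NULL) +
    ggplot2::labs(x = "rho_Gal3", y = "Kgal (% w/v)",
                  title = sprintf("[gal] = %g%%", attr(object, "gal"))) +
    ggplot2::theme_minimal()
  if ("bistable" %in% names(object)) {
    p <- p + ggplot2::geom_point(
      data = object[which(object$bistable), ],
      shape = 0, size = 2, colour = "goldenrod")
  }
  if (!is.null(alleles)) {
    p <- p + ggplot2::geom_point(
      data = alleles, ggplot2::aes(x = .data$rho, y = .data$kgal),
      inherit.aes = FALSE, size = 2) +
      ggplot2::geom_text(
        data = alleles,
        ggplot2::aes(x = .data$rho, y = .data$kgal, label = .data$strain),
        inherit.aes = FALSE, vjust = -1, size = 3)
  }
  p
}

#' Plot inducibility time courses
#'
#' @param data an inducibility tibble (`time`, `fraction_on`, `sem`, `gal`
#'   and optionally `strain`).
#' @return A ggplot object with one line per concentration, faceted by
#'   strain when present.
#' @export
plot_inducibility <- function(data) {
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$time, y = .data$fraction_on,
                                    colour = factor(.data$gal))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$fraction_on - .data$sem, 0),
      ymax = pmin(.data$fraction_on + .data$sem, 1)), size = 0.2) +
    ggplot2::scale_colour_viridis_d(name = "[gal] (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time after induction (min)", y = "fraction ON") +
    ggplot2::theme_minimal()
  if ("strain" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~strain)
  }
  p
}
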