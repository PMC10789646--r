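# ggplot2 figures for each result type.

#' Volcano plot of enrichment results
#'
#' @param records Records tibble from [classify_enrichment()].
#' @param p_threshold,fc_threshold Guide lines (defaults 0.05 and 2).
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, p_threshold = 0.05, fc_threshold = 2) {
  d <- volcano_table(records)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_p,
                                  colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 fold enrichment (+UV / -UV)",
                  y = "-log10 p-value", colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot an ITC isotherm (and optionally its fit)
#'
#' Normalized heat per mole of injectant against the molar ratio; the
#' discarded initial injection is shown hollow.
#'
#' @param isotherm An `itc_isotherm` tibble.
#' @param fit Optional `one_site_fit` whose curve is overlaid.
#' @return A ggplot object.
#' @export
plot_isotherm <- function(isotherm, fit = NULL) {
  p <- ggplot2::ggplot(isotherm,
                       ggplot2::aes(x = .data$molar_ratio, y = .data$molar_heat)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$discard), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "molar ratio (titrant / macromolecule)",
                  y = "kcal per mol of injectant") +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = fit$fitted[!fit$fitted$discard, , drop = FALSE],
      ggplot2::aes(y = .data$fitted), colour = "red"
    )
  }
  p
}

#' @method autoplot itc_isotherm
#' @export
autoplot.itc_isotherm <- function(object, ...) plot_isotherm(object, ...)

#' @method autoplot one_site_fit
#' @export
autoplot.one_site_fit <- function(object, ...) {
  iso <- dplyr::rename(object$fitted, molar_heat = "observed")
  plot_isotherm(iso, fit = object)
}

#' Mean TSS signal profile
#'
#' Line graph of the column-mean signal of a [tss_matrix()].
#'
#' @param x A `tss_matrix` object.
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(x) {
  ggplot2::ggplot(x$profile, ggplot2::aes(x = .data$position,
                                          y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean signal") +
    ggplot2::theme_bw()
}

#' Tornado heatmap of a TSS matrix
#'
#' @param object A `tss_matrix` object.
#' @param ... Unused.
#' @return A ggplot object (rows sorted high to low as in the matrix).
#' @method autoplot tss_matrix
#' @export
autoplot.tss_matrix <- function(object, ...) {
  m <- object$matrix
  d <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    position = rep(object$positions, each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "distance from TSS (bp)", y = "TSS (sorted by signal)",
                  fill = "signal") +
    ggplot2::theme_bw()
}
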