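#' Plot the joint CD31/EMCN intensity density
#'
#' The gate-space density plot: voxel counts over joint (CD31, EMCN)
#' intensity, log-scaled colour, with optional gate lines.
#'
#' @param hist a [joint_intensity_histogram()] result.
#' @param gates optional [gate_config()] drawn as dashed lines.
#' @return a ggplot object.
#' @export
plot_joint_density <- function(hist, gates = NULL) {
  df <- tidy.joint_histogram(hist)
  df <- df[df$count > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cd31, y = .data$emcn,
                                        fill = log10(.data$count))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 voxels") +
    ggplot2::labs(x = "CD31 intensity (a.u.)", y = "EMCN intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(gates)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(gates$vessel_presence, gates$cd31_lo_hi),
                          linetype = "dashed", colour = "grey30") +
      ggplot2::geom_hline(yintercept = c(gates$emcn_neg_lo, gates$emcn_lo_hi),
                          linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot a spot distance histogram
#'
#' DTC and random-spot distance distributions to a structure, binned with an
#' overflow bin, as side-by-side fractions.
#'
#' @param hist_tbl a [distance_histogram()] result.
#' @return a ggplot object.
#' @export
plot_distance_histogram <- function(hist_tbl) {
  hist_tbl$bin <- factor(
    ifelse(is.finite(hist_tbl$bin_hi),
           sprintf("[%g, %g)", hist_tbl$bin_lo, hist_tbl$bin_hi),
           sprintf(">= %g", hist_tbl$bin_lo)),
    levels = unique(ifelse(is.finite(hist_tbl$bin_hi),
                           sprintf("[%g, %g)", hist_tbl$bin_lo, hist_tbl$bin_hi),
                           sprintf(">= %g", hist_tbl$bin_lo)))
  )
  ggplot2::ggplot(hist_tbl, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                         fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "distance (µm)", y = "fraction of spots",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of proximity fractions with s.e.m. error bars
#'
#' @param object a [proximity_fraction()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.proximity_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = 100 * .data$fraction,
                                   fill = .data$kind)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$fraction - .data$sem),
                   ymax = 100 * (.data$fraction + .data$sem)),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("%% of spots within %g µm of %s",
                  df$threshold_um[1], df$structure[1])
    ) +
    ggplot2::theme_minimal()
}
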