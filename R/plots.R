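#' Plot a neuron tree projection
#'
#' Draws the parent-to-child segments of a reconstruction projected onto a
#' coordinate plane, line width scaled by local radius.
#'
#' @param object a [neuron_tree()].
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot neuron_tree
#' @export
autoplot.neuron_tree <- function(object, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  pos <- match(object$parent, object$id)
  ok <- !is.na(pos)
  seg <- tibble::tibble(
    x = object[[ax[1]]][ok], y = object[[ax[2]]][ok],
    xend = object[[ax[1]]][pos[ok]], yend = object[[ax[2]]][pos[ok]],
    radius = object$radius[ok])
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend,
                                       linewidth = .data$radius),
                          lineend = "round") +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = ax[1], y = ax[2], linewidth = "radius (vox)") +
    ggplot2::theme_minimal()
}

#' Plot a parameter or noise sweep
#'
#' Shows length and bifurcation proportions against the swept variable
#' (sampling distance or noise SD).
#'
#' @param object a tibble returned by [sweep_sampling_distance()] or
#'   [noise_robustness()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rayburst_sweep
#' @export
autoplot.rayburst_sweep <- function(object, ...) {
  xvar <- if ("sampling_distance" %in% names(object)) "sampling_distance"
          else "noise_sd"
  long <- tidyr::pivot_longer(
    object[, c(xvar, "length_proportion", "bifurcation_proportion")],
    cols = c("length_proportion", "bifurcation_proportion"),
    names_to = "measure", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]],
                                     y = .data$proportion,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = gsub("_", " ", xvar), y = "proportion of truth") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
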