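#' Plot a per-residue interaction summary
#'
#' Bar chart of mean favorable-contact counts per core residue with
#' bootstrap error bars, basic-patch residues highlighted — the standard
#' way tail-core contact propensity is displayed.
#'
#' @param object An [interaction_summary()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot interaction_summary
#' @export
autoplot.interaction_summary <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$core_residue),
                                  y = .data$mean_count,
                                  fill = .data$basic)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_count - .data$sd_count, 0),
      ymax = .data$mean_count + .data$sd_count
    ), width = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey60"),
                               name = "basic patch") +
    ggplot2::labs(x = "core residue",
                  y = "mean favorable tail contacts per model") +
    ggplot2::theme_minimal()
}

#' Plot a binding fit
#'
#' Data points with the fitted curve; titration-style fits are drawn on a
#' log concentration axis.
#'
#' @param object A `binding_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  xvar <- if (startsWith(object$model, "exponential")) "t" else "x"
  d <- object$data
  xs <- d[[xvar]]
  logx <- xvar == "x" && all(xs >= 0) && sum(xs > 0) >= 2
  grid <- if (logx) {
    pos <- xs[xs > 0]
    10^seq(log10(min(pos)), log10(max(pos)), length.out = 200)
  } else {
    seq(min(xs), max(xs), length.out = 200)
  }
  nd <- tibble::tibble(!!xvar := grid)
  nd$y_fit <- as.numeric(predict(object, newdata = nd))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = nd,
                       ggplot2::aes(x = .data[[xvar]], y = .data$y_fit),
                       color = "#b2182b") +
    ggplot2::labs(x = if (xvar == "t") "time (s)" else "concentration",
                  y = "signal",
                  title = object$model) +
    ggplot2::theme_minimal()
  if (logx) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot effective concentration against accessible-sphere radius
#'
#' Shows how the worm-like-chain effective concentration falls with the
#' tail's accessible radius, with reference radii marked.
#'
#' @param r_range Radius range in Angstrom (default 45-150).
#' @param mark Radii to highlight (default 105 and 70 A, the full-length
#'   and linker-shortened tails).
#' @param ... Passed to [chain_geometry()] (core dimensions).
#' @return A ggplot object.
#' @export
plot_local_concentration <- function(r_range = c(45, 150),
                                     mark = c(105, 70), ...) {
  r <- seq(r_range[1], r_range[2], length.out = 200)
  d <- purrr::map_dfr(r, ~ local_concentration(chain_geometry(.x, ...)))
  marks <- purrr::map_dfr(mark, ~ local_concentration(chain_geometry(.x, ...)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_tail, y = .data$conc_uM)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, color = "#b2182b", size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "accessible sphere radius (Å)",
                  y = "effective tip concentration (µM)") +
    ggplot2::theme_minimal()
}
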