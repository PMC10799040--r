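# ggplot2 quick-look methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a radial distribution function
#' @param object An `rdf_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rdf_result <- function(object, ...) {
  groups <- attr(object, "groups")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "g(r)",
                  title = if (!is.null(groups)) {
                    paste("RDF:", paste(groups, collapse = " – "))
                  } else "RDF") +
    ggplot2::theme_minimal()
}

#' Plot a correlation result (MSD, VACF, VRD, beta)
#' @param object A `correlation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_result <- function(object, ...) {
  kind <- attr(object, "kind") %||% "correlation"
  ylab <- switch(kind, msd = "MSD (Å²)", vacf = "C(τ)",
                 vrd = "VRD(τ)", beta = "β(τ)", "value")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag τ (ps)", y = ylab, title = toupper(kind)) +
    ggplot2::theme_minimal()
  if (kind == "msd") p <- p + ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10()
  if (kind %in% c("vacf", "vrd")) {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                                 colour = "grey60")
  }
  if (kind == "beta") {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                                 colour = "grey60") +
      ggplot2::scale_x_log10()
  }
  p
}

#' Plot a 2-D combined distribution function
#' @param object A `cdf2d`.
#' @param ... Unused.
#' @return A ggplot (raster heat map).
#' @export
autoplot.cdf2d <- function(object, ...) {
  df <- tidy.cdf2d(object)
  names(df) <- c("x", "y", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = object$x_lab, y = object$y_lab, fill = "events") +
    ggplot2::theme_minimal()
}

#' Plot the running Green-Kubo integral
#' @param object A `viscosity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.viscosity_result <- function(object, ...) {
  ggplot2::ggplot(object$acf,
                  ggplot2::aes(x = .data$lag, y = .data$running_eta)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$eta, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "upper limit (ps)", y = "running η (internal)",
                  title = "Green–Kubo running integral") +
    ggplot2::theme_minimal()
}

#' Plot a stability report
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot (ranked bar chart with the miscibility threshold).
#' @export
autoplot.stability_report <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 3.30
  df <- tibble::as_tibble(object)
  df$system <- factor(df$system, levels = rev(df$system))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$S, y = .data$system,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "relative stability factor S", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
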