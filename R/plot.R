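#' Plot an orientation field
#'
#' Raster plot with angles hue-coded cyclically over the axial period;
#' invalid pixels are black.
#'
#' @param object an `orientation_field`.
#' @param angle `"theta"` or `"phi"`.
#' @param slice slice to show for 3D fields (default middle).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot orientation_field
#' @export
autoplot.orientation_field <- function(object, angle = c("theta", "phi"),
                                       slice = NULL, ...) {
  angle <- match.arg(angle)
  a <- if (angle == "theta") object$theta else object$phi
  if (is.null(a)) stop(sprintf("field has no %s angle", angle))
  if (length(dim(a)) == 3L) {
    if (is.null(slice)) slice <- ceiling(dim(a)[3] / 2)
    a <- a[, , slice]
  }
  df <- expand.grid(y = seq_len(nrow(a)), x = seq_len(ncol(a)))
  df$angle <- as.vector(a)
  df$fill <- ifelse(is.finite(df$angle),
                    grDevices::hsv((df$angle %% 180) / 180, 1, 1), "black")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s orientation map (deg, axial hue)", angle)) +
    ggplot2::theme_void()
}

#' Plot a depth-variance profile
#'
#' @param profile a tibble from [depth_profile()].
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile) {
  ggplot2::ggplot(profile[profile$n_valid > 0, ],
                  ggplot2::aes(x = .data$depth, y = .data$variance_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "depth", y = "mean directional variance") +
    ggplot2::theme_minimal()
}

#' Plot thickness-stratified variance distributions
#'
#' @param strata a tibble from [stratify_by_thickness()].
#' @return A ggplot object.
#' @export
plot_strata <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$variance,
                                       colour = .data$stratum)) +
    ggplot2::geom_density() +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "directional variance", y = "density",
                  colour = "thickness") +
    ggplot2::theme_minimal()
}

#' Plot per-window comparison errors
#'
#' Mean angular error of each fixed window with the adaptive-window error
#' as a horizontal reference line.
#'
#' @param report a `comparison_report` from [run_comparison()].
#' @param metric `"balanced"` or `"pooled"` error average.
#' @param kind angle kind to show.
#' @return A ggplot object.
#' @export
plot_comparison <- function(report, metric = c("balanced", "pooled"),
                            kind = "theta") {
  metric <- match.arg(metric)
  td <- tidy.comparison_report(report)
  td <- td[td$kind == kind, ]
  col <- paste0(metric, "_error")
  fx <- td[td$method != "wo", ]
  wo <- td[[col]][td$method == "wo"]
  ggplot2::ggplot(fx, ggplot2::aes(x = .data$window, y = .data[[col]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = wo, linetype = 2) +
    ggplot2::annotate("text", x = min(fx$window), y = wo,
                      label = "adaptive window", hjust = 0, vjust = -0.5,
                      size = 3) +
    ggplot2::labs(x = "fixed window size (px)",
                  y = sprintf("mean %s error (deg, %s)", kind, metric)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
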