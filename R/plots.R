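#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_line
#'   scale_fill_viridis_c coord_equal labs theme_minimal facet_wrap
NULL

#' Plot a gridded concentration map
#'
#' @param object A `cll_prediction` (from [predict_grid()] or
#'   [mosaic_zone_maps()]).
#' @param what Which surface to draw: the median-scale prediction `y_hat`
#'   or its delta-method SD `sd_y`.
#' @param ... Unused.
#' @return A ggplot object (tile map, equal coordinates).
#' @method autoplot cll_prediction
#' @export
autoplot.cll_prediction <- function(object, what = c("y_hat", "sd_y"), ...) {
  what <- match.arg(what)
  lab <- if (what == "y_hat") "Cd (µg/g)" else "SD (µg/g)"
  ggplot(object, aes(x = .data$x / 1000, y = .data$y / 1000,
                     fill = .data[[what]])) +
    geom_tile() +
    scale_fill_viridis_c(name = lab) +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)") +
    theme_minimal()
}

#' Plot a kriging map
#'
#' @param object An `ok_prediction` from [ok_predict()].
#' @param what `y_hat` (back-transformed prediction) or `sd_y`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ok_prediction
#' @export
autoplot.ok_prediction <- function(object, what = c("y_hat", "sd_y"), ...) {
  what <- match.arg(what)
  lab <- if (what == "y_hat") "Cd (µg/g)" else "SD (µg/g)"
  ggplot(object, aes(x = .data$x / 1000, y = .data$y / 1000,
                     fill = .data[[what]])) +
    geom_tile() +
    scale_fill_viridis_c(name = lab) +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)") +
    theme_minimal()
}

#' Plot an empirical variogram with its fitted model
#'
#' @param object A `variogram_model` from [fit_variogram()].
#' @param ... Unused.
#' @return A ggplot object: binned empirical semivariances (point size by
#'   pair count) with the fitted curve.
#' @method autoplot variogram_model
#' @export
autoplot.variogram_model <- function(object, ...) {
  emp <- object$empirical_bins
  curve <- tibble::tibble(
    lag = seq(0, max(emp$lag), length.out = 200)
  )
  curve$gamma <- semivariance(curve$lag, object)
  ggplot(emp, aes(x = .data$lag / 1000, y = .data$gamma)) +
    geom_point(aes(size = .data$n_pairs), alpha = 0.7) +
    geom_line(data = curve, aes(x = .data$lag / 1000, y = .data$gamma),
              linewidth = 0.7, colour = "firebrick") +
    labs(x = "lag (km)", y = "semivariance", size = "pairs",
         title = paste0(object$family, " variogram of log concentrations")) +
    theme_minimal()
}

#' @export
ggplot2::autoplot
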