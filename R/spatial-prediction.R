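#' Predict a fitted CLL model over a grid
#'
#' Evaluates the linear predictor \eqn{\hat\eta(s)} at every grid cell with
#' the categorical variables fixed at a reference profile (by default Hc
#' mosses under deciduous tree cover), computes the standard error of the
#' fitted mean from the coefficient covariance, and back-transforms to the
#' concentration scale: \eqn{\hat y(s) = Cd_{max}\exp(-\exp(\hat\eta(s)))} —
#' the median of the response given \eqn{\hat\eta}, since the transform is
#' monotone. The concentration-scale standard deviation uses the delta
#' method, \eqn{sd_y = |d\hat y/d\eta| \cdot se_\eta} with
#' \eqn{d\hat y/d\eta = -Cd_{max}\exp(\eta - \exp(\eta))}.
#'
#' Cells with a missing value in any model covariate are excluded (their
#' count is recorded in the `n_missing` attribute). Cells where any
#' quantitative covariate falls outside the training range are flagged
#' `extrapolated` rather than masked.
#'
#' @param fit A [fit_cll()] object.
#' @param grid Grid tibble from [generate_grid()] (or any table with the
#'   model covariates plus `x`, `y` and, if the model uses it, `zone`).
#' @param profile Named character vector of fixed categorical levels; must
#'   cover every categorical in the model except `zone`, which is taken from
#'   the grid when present there.
#' @param include_residual_var Add the residual variance to the linear
#'   predictor variance before the delta method, giving a prediction-scale
#'   SD for a new observation instead of the SD of the fitted median surface.
#' @return A tibble of class `cll_prediction`: `x`, `y`, `zone`, `eta_hat`,
#'   `se_eta`, `y_hat`, `sd_y`, `extrapolated`.
#' @export
predict_grid <- function(fit, grid,
                         profile = c(moss_species = "Hc",
                                     tree_cover = "deciduous"),
                         include_residual_var = FALSE) {
  stopifnot(inherits(fit, "cll_fit"))
  cat_vars <- intersect(fit$variables, .categorical_vars)
  quant_vars <- setdiff(fit$variables, .categorical_vars)
  missing_cols <- setdiff(quant_vars, names(grid))
  if (length(missing_cols) > 0) {
    abort(paste0("grid lacks model covariates: ",
                 paste(missing_cols, collapse = ", ")))
  }
  newdata <- grid
  for (v in cat_vars) {
    if (v == "zone" && "zone" %in% names(grid)) {
      newdata$zone <- grid$zone
    } else {
      if (!v %in% names(profile)) {
        abort(paste0("`profile` must supply a level for '", v, "'."))
      }
      lv <- fit$design_info$levels[[v]]
      if (!profile[[v]] %in% lv) {
        abort(sprintf("profile level '%s' for '%s' was not in the training data.",
                      profile[[v]], v))
      }
      newdata[[v]] <- profile[[v]]
    }
  }
  for (v in cat_vars) {
    newdata[[v]] <- factor(newdata[[v]], levels = fit$design_info$levels[[v]])
  }

  used <- c(quant_vars, cat_vars)
  ok <- complete.cases(newdata[, used, drop = FALSE])
  n_missing <- sum(!ok)
  newdata <- newdata[ok, , drop = FALSE]

  pr <- predict(fit$model, newdata = newdata, se.fit = TRUE)
  eta <- unname(pr$fit)
  se_eta <- unname(pr$se.fit)
  if (include_residual_var) {
    se_eta <- sqrt(se_eta^2 + fit$sigma2_unbiased)
  }
  y_hat <- inverse_cll(eta, fit$cd_max)
  dyd <- abs(-fit$cd_max * exp(eta - exp(eta)))
  sd_y <- dyd * se_eta

  extrapolated <- rep(FALSE, nrow(newdata))
  if (!is.null(fit$training_ranges)) {
    for (i in seq_len(nrow(fit$training_ranges))) {
      v <- fit$training_ranges$variable[i]
      extrapolated <- extrapolated |
        newdata[[v]] < fit$training_ranges$min[i] |
        newdata[[v]] > fit$training_ranges$max[i]
    }
  }
  out <- tibble::tibble(
    x = newdata$x, y = newdata$y,
    zone = if ("zone" %in% names(newdata)) as.character(newdata$zone)
           else NA_character_,
    eta_hat = eta, se_eta = se_eta, y_hat = y_hat, sd_y = sd_y,
    extrapolated = extrapolated
  )
  attr(out, "profile") <- profile
  attr(out, "n_missing") <- n_missing
  attr(out, "cd_max") <- fit$cd_max
  class(out) <- c("cll_prediction", class(out))
  out
}

#' Mosaic per-zone prediction maps
#'
#' Combines per-zone prediction tables into one national map: each grid cell
#' carries the prediction of its own zone's model. Errors if any cell
#' (identified by its `x`, `y` centre) is claimed by two zones, or — when
#' the full `grid` is supplied — claimed by none.
#'
#' @param per_zone_predictions List of `cll_prediction` tibbles, one per
#'   zone.
#' @param grid Optional full grid used to verify that the zones partition it.
#' @return A single `cll_prediction` tibble with a `zone_borders` attribute
#'   (the zone label of every cell, for drawing borders).
#' @export
mosaic_zone_maps <- function(per_zone_predictions, grid = NULL) {
  combined <- dplyr::bind_rows(per_zone_predictions)
  key <- paste(combined$x, combined$y)
  if (anyDuplicated(key) > 0) {
    abort("some grid cells are claimed by two or more zones.")
  }
  if (!is.null(grid)) {
    gkey <- paste(grid$x, grid$y)
    missing <- setdiff(gkey, key)
    if (length(missing) > 0) {
      abort(sprintf("%d grid cells are claimed by no zone.", length(missing)))
    }
  }
  cd_max <- attr(per_zone_predictions[[1]], "cd_max")
  attr(combined, "cd_max") <- cd_max
  attr(combined, "n_missing") <-
    sum(purrr::map_dbl(per_zone_predictions,
                       ~ attr(.x, "n_missing") %||% 0))
  class(combined) <- unique(c("cll_prediction", class(combined)))
  combined
}
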