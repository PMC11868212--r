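#' Complementary log-log transform of a bounded concentration
#'
#' Maps a concentration bounded in \eqn{(0, Cd_{max})} to the real line:
#' \eqn{z = \ln(\ln(Cd_{max}/y))}. The transform is strictly decreasing in
#' `y`; its inverse is [inverse_cll()].
#'
#' @param y Concentrations in micrograms per gram, strictly inside
#'   `(0, cd_max)`.
#' @param cd_max Upper concentration bound (default 1.5 micrograms per gram,
#'   the maximal value expected for Cd in mosses).
#' @return Transformed values, same length as `y`.
#' @export
#' @examples
#' cll_transform(1.5 / exp(1))        # 0
#' inverse_cll(cll_transform(0.3), 1.5)
cll_transform <- function(y, cd_max = 1.5) {
  bad <- which(!is.finite(y) | y <= 0 | y >= cd_max)
  if (length(bad) > 0) {
    abort(sprintf(
      "response values must lie strictly in (0, %g); offending rows: %s",
      cd_max, paste(head(bad, 5), collapse = ", ")))
  }
  log(log(cd_max / y))
}

#' Inverse complementary log-log transform
#'
#' @param eta Values on the transformed (real) scale.
#' @param cd_max Upper concentration bound.
#' @return Concentrations \eqn{y = Cd_{max}\exp(-\exp(\eta))}, always strictly
#'   inside `(0, cd_max)` for finite `eta`.
#' @export
inverse_cll <- function(eta, cd_max = 1.5) {
  cd_max * exp(-exp(eta))
}

# Reference levels match map semantics: predictions are expressed for Hc
# mosses under deciduous cover, zone effects relative to Alpine.
.reference_levels <- c(moss_species = "Hc", tree_cover = "deciduous",
                       zone = "Alpine")
.categorical_vars <- names(.reference_levels)

# Put the reference level first so lm's treatment contrasts use it; unused
# levels are dropped so single-observation species absent from a subset do
# not produce aliased all-zero columns.
prepare_model_data <- function(sites, variables, cd_max,
                               response = "cd") {
  dat <- sites[, c(intersect(c(response), names(sites)), variables),
               drop = FALSE]
  if (response %in% names(sites)) {
    dat$.z <- cll_transform(sites[[response]], cd_max)
  }
  for (v in intersect(variables, .categorical_vars)) {
    f <- factor(dat[[v]])
    ref <- .reference_levels[[v]]
    if (ref %in% levels(f)) f <- stats::relevel(f, ref = ref)
    dat[[v]] <- droplevels(f)
  }
  dat
}

#' Fit the complementary log-log linear model
#'
#' Transforms the response with [cll_transform()] and fits the linear model
#' \eqn{z_i = \alpha + \sum_j \beta_j X_i^j + \epsilon_i} by ordinary least
#' squares. Categorical variables (`moss_species`, `tree_cover`, `zone`) are
#' dummy-coded against the reference levels Hc, deciduous and Alpine. The AIC
#' uses the Gaussian log-likelihood with the maximum-likelihood residual
#' variance and counts the variance as a parameter
#' (\eqn{AIC = -2\ell + 2(k+1)}), the convention of [stats::AIC()];
#' coefficient standard errors use the unbiased residual variance.
#'
#' @param sites Site table containing the response column and all model
#'   variables.
#' @param variables Character vector of model terms (quantitative covariate
#'   names and/or `"moss_species"`, `"tree_cover"`, `"zone"`). May be empty
#'   for an intercept-only model.
#' @param cd_max Upper concentration bound used in the transform.
#' @param response Name of the response column (micrograms per gram).
#' @return An object of class `cll_fit` with the fitted [stats::lm] in
#'   `$model` plus `alpha`, `betas`, `sigma2_hat` (ML), `coef_cov`, `n_obs`,
#'   `k_params`, `loglik`, `aic`, `p_values` and training covariate ranges.
#'   Rank-deficient designs raise an error naming the aliased columns.
#' @export
fit_cll <- function(sites, variables = character(), cd_max = 1.5,
                    response = "cd") {
  missing_vars <- setdiff(variables, names(sites))
  if (length(missing_vars) > 0) {
    abort(paste0("variables not present in `sites`: ",
                 paste(missing_vars, collapse = ", ")))
  }
  dat <- prepare_model_data(sites, variables, cd_max, response)
  fml <- if (length(variables) == 0) .z ~ 1 else {
    as.formula(paste(".z ~", paste(variables, collapse = " + ")))
  }
  model <- lm(fml, data = dat)
  cf <- coef(model)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased) > 0) {
    abort(paste0("rank-deficient design; aliased columns: ",
                 paste(aliased, collapse = ", ")))
  }
  M <- length(model$residuals)
  k <- length(cf)
  if (M <= k) abort("more mean parameters than observations.")
  rss <- sum(model$residuals^2)
  sigma2_ml <- rss / M
  loglik <- -M / 2 * (log(2 * pi * sigma2_ml) + 1)
  # degenerate noiseless designs fit exactly; that is fine here
  sm <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(
    model = model,
    cd_max = cd_max,
    response = response,
    variables = variables,
    alpha = unname(cf["(Intercept)"]),
    betas = cf[setdiff(names(cf), "(Intercept)")],
    sigma2_hat = sigma2_ml,
    sigma2_unbiased = rss / (M - k),
    coef_cov = sm$cov.unscaled * sm$sigma^2,
    n_obs = M,
    k_params = k,
    loglik = loglik,
    aic = -2 * loglik + 2 * (k + 1),
    p_values = sm$coefficients[, "Pr(>|t|)"],
    coef_table = sm$coefficients,
    r_squared = sm$r.squared,
    design_info = list(reference_levels = .reference_levels,
                       levels = model$xlevels),
    training_ranges = training_ranges(dat, variables)
  ), class = "cll_fit")
}

training_ranges <- function(dat, variables) {
  quant <- setdiff(variables, .categorical_vars)
  if (length(quant) == 0) return(NULL)
  purrr::map_dfr(quant, function(v) {
    tibble::tibble(variable = v, min = min(dat[[v]]), max = max(dat[[v]]))
  })
}

#' @export
print.cll_fit <- function(x, ...) {
  cat("<cll_fit>  z = ln(ln(", x$cd_max, "/ y ))\n")
  cat("  n =", x$n_obs, "  mean parameters =", x$k_params,
      "  AIC =", round(x$aic, 2), "\n")
  cat("  sigma_hat (ML) =", round(sqrt(x$sigma2_hat), 4), "\n")
  cat("  terms:", if (length(x$variables)) paste(x$variables, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Tidy a CLL fit into a coefficient table
#'
#' @param x A `cll_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` and `signif` stars at the 0.05 / 0.01 / 0.001 levels.
#' @method tidy cll_fit
#' @export
tidy.cll_fit <- function(x, ...) {
  sm <- x$coef_table
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"],
    signif = signif_stars(sm[, "Pr(>|t|)"])
  )
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' One-row model summary of a CLL fit
#'
#' @param x A `cll_fit`.
#' @param ... Unused.
#' @return A tibble with `n_obs`, `k_params`, `sigma2_hat`, `r.squared`,
#'   `loglik`, `aic`.
#' @method glance cll_fit
#' @export
glance.cll_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    k_params = x$k_params,
    sigma2_hat = x$sigma2_hat,
    r.squared = x$r_squared,
    loglik = x$loglik,
    aic = x$aic
  )
}

#' @export
residuals.cll_fit <- function(object, ...) {
  unname(object$model$residuals)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
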