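#' Leave-one-out cross-validation on the concentration scale
#'
#' For each site, refits the predictor on the remaining `M - 1` sites with
#' the model specification held fixed — the selected variable set for the
#' CLL regression, the fitted variogram for ordinary kriging (variable
#' selection and variography are *not* re-run inside folds) — and predicts
#' the held-out site on the concentration scale (inverse CLL transform, or
#' exponentiated kriging of log values). The score is
#' \deqn{RMSE = \sqrt{\sum_{i=1}^M (y_i - \hat y_i)^2 / M}.}
#'
#' Regression folds where the refit cannot honour the held-out site's
#' categorical level (a level present only at that site) predict it from the
#' reference-level profile and are flagged; the count of flagged folds is
#' reported.
#'
#' @param sites Site table with the response column.
#' @param method `"cll_regression"` or `"ordinary_kriging"`.
#' @param model_spec For the regression, a list with `variables` (and
#'   optionally `cd_max`); for kriging, a list with `vgm` (a
#'   `variogram_model`; fitted once on the full data when omitted) and
#'   optionally `refit_variogram = TRUE` to refit it per fold.
#' @param scope Label for the analysis scope (e.g. `"France"` or a zone
#'   name).
#' @param response Response column name.
#' @param cd_max Upper bound used by the CLL transform.
#' @return A `loocv_result`: list with `scope`, `method`, `per_site`
#'   (tibble of `id`, `y`, `y_hat`, `flagged`), `rmse`, `M`, `n_flagged`.
#' @export
loocv <- function(sites, method = c("cll_regression", "ordinary_kriging"),
                  model_spec = list(), scope = "France", response = "cd",
                  cd_max = 1.5) {
  method <- match.arg(method)
  m <- nrow(sites)
  if (m < 3) abort("at least 3 sites are required.")
  ids <- if ("id" %in% names(sites)) sites$id else as.character(seq_len(m))
  y <- sites[[response]]
  y_hat <- numeric(m)
  flagged <- logical(m)

  if (method == "cll_regression") {
    variables <- model_spec$variables %||% character()
    cd_max <- model_spec$cd_max %||% cd_max
    for (i in seq_len(m)) {
      train <- sites[-i, , drop = FALSE]
      fit <- tryCatch(fit_cll(train, variables, cd_max, response),
                      error = function(e) NULL)
      if (is.null(fit)) {
        # the reduced fold cannot support the full specification (e.g. as
        # many parameters as remaining sites): intercept-only fallback
        fit <- fit_cll(train, character(), cd_max, response)
        flagged[i] <- TRUE
        y_hat[i] <- inverse_cll(fit$alpha, cd_max)
        next
      }
      new <- sites[i, , drop = FALSE]
      for (v in intersect(variables, .categorical_vars)) {
        lv <- fit$design_info$levels[[v]]
        if (!new[[v]] %in% lv) {
          new[[v]] <- fit$design_info$reference_levels[[v]]
          if (!new[[v]] %in% lv) new[[v]] <- lv[1]
          flagged[i] <- TRUE
        }
        new[[v]] <- factor(new[[v]], levels = lv)
      }
      eta <- unname(predict(fit$model, newdata = new))
      y_hat[i] <- inverse_cll(eta, cd_max)
    }
  } else {
    vgm <- model_spec$vgm %||% fit_variogram(sites, response)
    refit <- isTRUE(model_spec$refit_variogram)
    for (i in seq_len(m)) {
      train <- sites[-i, , drop = FALSE]
      v <- if (refit) fit_variogram(train, response) else vgm
      pred <- ok_predict(train, v, sites[i, c("x", "y")], response)
      y_hat[i] <- pred$y_hat
    }
  }
  new_loocv_result(scope, method,
                   tibble::tibble(id = ids, y = y, y_hat = y_hat,
                                  flagged = flagged))
}

new_loocv_result <- function(scope, method, per_site) {
  structure(list(
    scope = scope, method = method, per_site = per_site,
    rmse = rmse(per_site$y, per_site$y_hat),
    M = nrow(per_site), n_flagged = sum(per_site$flagged)
  ), class = "loocv_result")
}

#' Split a LOOCV result by zone
#'
#' Re-scores the held-out predictions of one result within each zone,
#' without refitting: this is how a nation-wide ("encompassing") model is
#' evaluated zone by zone.
#'
#' @param result A `loocv_result` whose folds cover several zones.
#' @param sites The site table the result was computed on (provides `zone`).
#' @return A list of `loocv_result`, one per zone.
#' @export
loocv_by_zone <- function(result, sites) {
  stopifnot(inherits(result, "loocv_result"))
  idx <- match(result$per_site$id, sites$id)
  zones <- sites$zone[idx]
  lapply(split(seq_len(nrow(result$per_site)), zones), function(rows) {
    new_loocv_result(unique(zones[rows]), result$method,
                     result$per_site[rows, , drop = FALSE])
  })
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result> ", x$scope, "/", x$method, "\n")
  cat("  M =", x$M, "  RMSE =", signif(x$rmse, 5), "ug/g")
  if (x$n_flagged > 0) cat("  (", x$n_flagged, "flagged folds )")
  cat("\n")
  invisible(x)
}

#' @method tidy loocv_result
#' @export
tidy.loocv_result <- function(x, ...) x$per_site

#' @method glance loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(scope = x$scope, method = x$method, rmse = x$rmse,
                 M = x$M, n_flagged = x$n_flagged)
}

#' Compare LOOCV scores across scopes and methods
#'
#' Assembles per-scope RMSEs into one comparison table, one row per scope
#' and one column per method, and appends a pooled row per method computed
#' from the concatenated held-out predictions of that method's per-zone
#' results (algebraically, \eqn{\sqrt{\sum_k M_k\,rmse_k^2 / \sum_k M_k}}).
#' Methods sharing a scope must have been evaluated on the same site set.
#'
#' @param results List of `loocv_result` objects.
#' @param pooled_label Scope label for the pooled rows (default
#'   `"pooled"`); set `NULL` to skip pooling.
#' @return A tibble with columns `scope`, `method`, `rmse`, `M`.
#' @export
compare_scopes <- function(results, pooled_label = "pooled") {
  stopifnot(length(results) > 0)
  tab <- purrr::map_dfr(results, glance)
  for (sc in unique(tab$scope)) {
    subs <- results[purrr::map_chr(results, "scope") == sc]
    if (length(subs) > 1) {
      sets <- purrr::map(subs, ~ sort(.x$per_site$id))
      if (!all(purrr::map_lgl(sets[-1], identical, sets[[1]]))) {
        abort(sprintf("methods disagree on the site set for scope '%s'.", sc))
      }
    }
  }
  if (!is.null(pooled_label)) {
    for (mth in unique(tab$method)) {
      subs <- results[purrr::map_chr(results, "method") == mth]
      if (length(subs) > 1) {
        per <- dplyr::bind_rows(purrr::map(subs, "per_site"))
        tab <- dplyr::add_row(tab, scope = pooled_label, method = mth,
                              rmse = rmse(per$y, per$y_hat), M = nrow(per),
                              n_flagged = sum(per$flagged))
      }
    }
  }
  dplyr::select(tab, "scope", "method", "rmse", "M")
}
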