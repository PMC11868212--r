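#' Backward-forward AIC model selection
#'
#' Best-first stepwise selection on the complementary log-log linear model:
#' at every iteration the AIC of dropping each current variable and of adding
#' each eligible excluded variable (from `start_variables`) is evaluated, and
#' the single move with the largest AIC decrease is applied; selection stops
#' when no move decreases the AIC. Categorical variables move as whole blocks
#' (all dummy columns together). Candidate fits that are rank-deficient are
#' skipped and logged, not fatal. Because every accepted move strictly
#' decreases the AIC the procedure cannot cycle.
#'
#' @param sites Site table with the response column.
#' @param start_variables The screened full-model variable set; selection
#'   starts from the full model and only these variables are ever eligible.
#' @param cd_max Upper concentration bound.
#' @param response Name of the response column.
#' @return A list of class `cll_selection` with the refitted final model
#'   (`$fit`), the move trace (`$trace`: tibble of `action`, `variable`,
#'   `aic_before`, `aic_after`), `$final_variables`, `$final_aic` and
#'   `$skipped` (rank-deficient candidates).
#' @export
stepwise_aic <- function(sites, start_variables, cd_max = 1.5,
                         response = "cd") {
  fit_or_null <- function(vars) {
    tryCatch(fit_cll(sites, vars, cd_max, response),
             error = function(e) NULL)
  }
  current <- start_variables
  fit <- fit_or_null(current)
  skipped <- character()
  # A rank-deficient full model cannot seed the search: drop offenders until
  # it fits (each removal logged), mirroring what an analyst would do by hand.
  while (is.null(fit) && length(current) > 0) {
    cand <- purrr::map(seq_along(current), function(i) {
      fit_or_null(current[-i])
    })
    ok <- which(!purrr::map_lgl(cand, is.null))
    if (length(ok) == 0) abort("no full model of any size could be fitted.")
    aics <- purrr::map_dbl(cand[ok], "aic")
    best <- ok[which.min(aics)]
    skipped <- c(skipped, paste0("full-model drop: ", current[best]))
    current <- current[-best]
    fit <- cand[[best]]
  }
  if (is.null(fit)) abort("could not fit the starting model.")

  trace <- tibble::tibble(action = character(), variable = character(),
                          aic_before = numeric(), aic_after = numeric())
  repeat {
    moves <- tibble::tibble(action = character(), variable = character(),
                            aic = numeric())
    for (v in current) {
      f <- fit_or_null(setdiff(current, v))
      if (is.null(f)) {
        skipped <- c(skipped, paste0("drop ", v))
      } else {
        moves <- dplyr::add_row(moves, action = "drop", variable = v,
                                aic = f$aic)
      }
    }
    for (v in setdiff(start_variables, current)) {
      f <- fit_or_null(c(current, v))
      if (is.null(f)) {
        skipped <- c(skipped, paste0("add ", v))
      } else {
        moves <- dplyr::add_row(moves, action = "add", variable = v,
                                aic = f$aic)
      }
    }
    if (nrow(moves) == 0) break
    best <- moves[which.min(moves$aic), ]
    if (best$aic >= fit$aic - 1e-10) break
    trace <- dplyr::add_row(trace, action = best$action,
                            variable = best$variable,
                            aic_before = fit$aic, aic_after = best$aic)
    current <- if (best$action == "drop") {
      setdiff(current, best$variable)
    } else {
      c(current, best$variable)
    }
    fit <- fit_or_null(current)
    stopifnot(!is.null(fit))
  }
  structure(list(
    fit = fit,
    trace = trace,
    final_variables = current,
    final_aic = fit$aic,
    skipped = unique(skipped)
  ), class = "cll_selection")
}

#' @export
print.cll_selection <- function(x, ...) {
  cat("<cll_selection>  backward-forward AIC\n")
  cat("  moves accepted:", nrow(x$trace),
      "  final AIC:", round(x$final_aic, 2), "\n")
  cat("  final variables:",
      if (length(x$final_variables)) paste(x$final_variables, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' @method tidy cll_selection
#' @export
tidy.cll_selection <- function(x, ...) x$trace

#' @method glance cll_selection
#' @export
glance.cll_selection <- function(x, ...) {
  tibble::tibble(n_moves = nrow(x$trace),
                 n_final = length(x$final_variables),
                 final_aic = x$final_aic)
}
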