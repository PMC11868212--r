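#' Zero-proportion covariate filter
#'
#' Removes quantitative covariates that are almost always exactly zero on the
#' rows of the analysis scope (one biogeographical zone, or all rows for a
#' nation-wide model): a variable is removed iff its proportion of exact
#' zeros is strictly greater than `threshold`. Qualitative variables are
#' never considered. With `by_zone = TRUE` the proportion is evaluated within
#' each zone and a variable is removed if it exceeds the threshold in any
#' zone.
#'
#' @param sites Site table (the rows define the scope).
#' @param threshold Zero-proportion threshold in `(0, 1]` (default 0.95).
#' @param variables Candidate quantitative variables (default: every
#'   non-reserved numeric column).
#' @param by_zone Evaluate the proportion within each zone rather than pooled.
#' @return A `screening_report`; see [screen_covariates()].
#' @export
zero_filter <- function(sites, threshold = 0.95,
                        variables = covariate_columns(sites),
                        by_zone = FALSE) {
  if (nrow(sites) == 0) abort("`sites` is empty.")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  prop_zero <- function(v) mean(v == 0)
  props <- vapply(variables, function(nm) {
    if (by_zone) {
      max(vapply(split(sites[[nm]], sites$zone), prop_zero, numeric(1)))
    } else {
      prop_zero(sites[[nm]])
    }
  }, numeric(1))
  removed_idx <- props > threshold
  new_screening_report(
    removed = tibble::tibble(
      variable = variables[removed_idx],
      reason = rep("zero_filter", sum(removed_idx)),
      detail = unname(props[removed_idx])
    ),
    retained = variables[!removed_idx],
    threshold_zero = threshold,
    threshold_rho = NA_real_
  )
}

#' Spearman collinearity filter
#'
#' Two-step removal of collinear quantitative covariates by Spearman rank
#' correlation (average ranks for ties):
#'
#' 1. Within each buffered family (e.g. `Forest_1/5/10/15`): if any pair has
#'    `|rho| > threshold`, all members of the connected component of
#'    over-threshold pairs are removed except the one with the smallest
#'    buffer radius.
#' 2. Across the remaining variables: while any pair has `|rho| > threshold`
#'    (highest offending `|rho|` first), the member of the pair with the
#'    larger mean absolute Spearman correlation to all other remaining
#'    variables is removed; correlations are re-evaluated after each removal.
#'
#' Constant (zero-variance) variables are removed up front with reason
#' `collinear_pair` and detail `NA` (undefined correlation).
#'
#' @param sites Site table (rows define the scope).
#' @param threshold Absolute Spearman correlation threshold (default 0.75).
#' @param variables Candidate variables, typically the retained set of
#'   [zero_filter()].
#' @return A `screening_report`.
#' @export
spearman_filter <- function(sites, threshold = 0.75,
                            variables = covariate_columns(sites)) {
  if (nrow(sites) == 0) abort("`sites` is empty.")
  removed <- tibble::tibble(variable = character(), reason = character(),
                            detail = numeric())
  # constant variables: correlation undefined
  consts <- variables[vapply(variables, function(v) {
    var(sites[[v]]) == 0
  }, logical(1))]
  if (length(consts) > 0) {
    removed <- dplyr::add_row(removed, variable = consts,
                              reason = "collinear_pair", detail = NA_real_)
    inform(paste0("constant variables removed (undefined correlation): ",
                  paste(consts, collapse = ", ")))
    variables <- setdiff(variables, consts)
  }
  rho <- function(a, b) cor(sites[[a]], sites[[b]], method = "spearman")

  # Step 1: within-family connected components of over-threshold pairs.
  info <- parse_covariate_name(variables)
  for (fam in unique(info$family)) {
    members <- info[info$family == fam & !is.na(info$radius), ]
    members <- members[order(members$radius), ]
    if (nrow(members) < 2) next
    nm <- members$variable
    cmat <- abs(cor(as.matrix(sites[nm]), method = "spearman"))
    adj <- cmat > threshold
    diag(adj) <- FALSE
    comp <- connected_components(adj)
    for (cc in comp) {
      if (length(cc) < 2) next
      keep <- cc[1]  # members ordered by radius: smallest buffer kept
      for (drop in cc[-1]) {
        removed <- dplyr::add_row(removed, variable = nm[drop],
                                  reason = "collinear_family",
                                  detail = max(cmat[drop, setdiff(cc, drop)]))
      }
      variables <- setdiff(variables, nm[cc[-1]])
    }
  }

  # Step 2: iterate over remaining over-threshold pairs, worst first.
  repeat {
    if (length(variables) < 2) break
    cmat <- abs(cor(as.matrix(sites[variables]), method = "spearman"))
    diag(cmat) <- 0
    worst <- max(cmat)
    if (worst <= threshold) break
    idx <- which(cmat == worst, arr.ind = TRUE)[1, ]
    pair <- variables[idx]
    mean_abs <- vapply(pair, function(v) {
      others <- setdiff(variables, v)
      mean(abs(cmat[v, others]))
    }, numeric(1))
    # remove the more redundant member; deterministic name tie-break
    drop <- if (mean_abs[1] > mean_abs[2]) pair[1]
            else if (mean_abs[2] > mean_abs[1]) pair[2]
            else sort(pair)[2]
    removed <- dplyr::add_row(removed, variable = drop,
                              reason = "collinear_pair", detail = worst)
    variables <- setdiff(variables, drop)
  }

  new_screening_report(removed = removed, retained = variables,
                       threshold_zero = NA_real_, threshold_rho = threshold)
}

connected_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    stack <- i
    comp <- integer()
    while (length(stack) > 0) {
      v <- stack[[1]]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Run both pre-selection filters
#'
#' Applies [zero_filter()] then [spearman_filter()] on the rows of `sites`
#' and merges the two reports.
#'
#' @inheritParams zero_filter
#' @param threshold_zero,threshold_rho Filter thresholds.
#' @return A `screening_report`: list with `removed` (tibble of `variable`,
#'   `reason` in `zero_filter` / `collinear_family` / `collinear_pair`,
#'   `detail` = offending proportion or correlation), `retained` (ordered
#'   character vector) and the thresholds used.
#' @export
screen_covariates <- function(sites, threshold_zero = 0.95,
                              threshold_rho = 0.75,
                              variables = covariate_columns(sites),
                              by_zone = FALSE) {
  zf <- zero_filter(sites, threshold_zero, variables, by_zone)
  sf <- spearman_filter(sites, threshold_rho, zf$retained)
  new_screening_report(
    removed = dplyr::bind_rows(zf$removed, sf$removed),
    retained = sf$retained,
    threshold_zero = threshold_zero,
    threshold_rho = threshold_rho
  )
}

new_screening_report <- function(removed, retained, threshold_zero,
                                 threshold_rho) {
  structure(list(removed = removed, retained = retained,
                 threshold_zero = threshold_zero,
                 threshold_rho = threshold_rho),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat("  removed:", nrow(x$removed), "  retained:", length(x$retained), "\n")
  if (nrow(x$removed) > 0) {
    tab <- table(x$removed$reason)
    cat("  reasons:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy screening_report
#' @export
tidy.screening_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$removed, status = "removed"),
    tibble::tibble(variable = x$retained, reason = NA_character_,
                   detail = NA_real_, status = "retained")
  )
}
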