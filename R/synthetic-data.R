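#' Generate synthetic sampling sites
#'
#' Draws a site table with the statistical structure of a national moss
#' biomonitoring survey: sites allocated to biogeographical zones and placed
#' uniformly within each zone's rectangle; moss species and tree-cover classes
#' drawn from the configured frequencies; quantitative covariates sampled from
#' shared latent spatial fields so buffered families are strongly
#' rank-correlated and zero-inflated classes have spatially coherent zeros.
#' The response is added separately by [simulate_response()].
#'
#' @param config A [study_config()].
#' @return A tibble with columns `id`, `x`, `y`, `zone`, `moss_species`,
#'   `tree_cover` and one column per quantitative covariate. If the number of
#'   sites is less than twice the number of covariates the attribute
#'   `overfit_risk` is set to `TRUE` (and a warning is raised), flagging
#'   designs where per-zone fits may be unstable.
#' @export
#' @examples
#' sites <- generate_sites(study_config(n_sites = 40, seed = 7))
#' dplyr::count(sites, zone)
generate_sites <- function(config) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_sites
  layout <- config$zone_layout

  zone <- with_substream(config$seed, "zones", {
    sample(layout$zone, n, replace = TRUE, prob = layout$prob)
  })
  pos <- with_substream(config$seed, "positions", {
    i <- match(zone, layout$zone)
    list(x = runif(n, layout$xmin[i], layout$xmax[i]),
         y = runif(n, layout$ymin[i], layout$ymax[i]))
  })
  moss <- with_substream(config$seed, "species", {
    sample(names(config$species_probs), n, replace = TRUE,
           prob = config$species_probs)
  })
  tree <- with_substream(config$seed, "tree", {
    sample(names(config$tree_probs), n, replace = TRUE,
           prob = config$tree_probs)
  })

  fields <- make_latent_fields(config)
  covs <- eval_covariates(fields, config, pos$x, pos$y)
  covs <- apply_zero_inflation(covs, config, zone)

  sites <- dplyr::bind_cols(
    tibble::tibble(id = paste0("S", sprintf("%04d", seq_len(n))),
                   x = pos$x, y = pos$y, zone = zone,
                   moss_species = moss, tree_cover = tree),
    covs
  )
  overfit <- n < 2 * ncol(covs)
  attr(sites, "overfit_risk") <- overfit
  if (overfit) {
    warn(sprintf(paste0("n_sites (%d) is below twice the number of ",
                        "quantitative covariates (%d): overfitting risk."),
                 n, ncol(covs)))
  }
  sites
}

#' Simulate the bounded concentration response
#'
#' Adds the response column `cd` from the data-generating complementary
#' log-log model: the linear predictor
#' \eqn{\eta_i = \alpha + \sum_j \beta_j X_i^j} (plus species, tree-cover and
#' zone effects) receives Gaussian noise \eqn{\epsilon_i \sim N(0,\sigma^2)}
#' on the transformed scale and is mapped back through
#' \eqn{Y_i = Cd_{max}\exp(-\exp(\eta_i + \epsilon_i))}, so every simulated
#' concentration lies strictly inside \eqn{(0, Cd_{max})}.
#'
#' @param sites A site table from [generate_sites()].
#' @param config The [study_config()] used to generate `sites`.
#' @return `sites` with an added `cd` column (micrograms per gram) and
#'   attribute `eta` holding the noiseless linear predictor.
#' @export
simulate_response <- function(sites, config) {
  stopifnot(inherits(config, "study_config"))
  missing_cov <- setdiff(names(config$true_betas), names(sites))
  if (length(missing_cov) > 0) {
    abort(paste0("covariates named in `true_betas` are absent from `sites`: ",
                 paste(missing_cov, collapse = ", ")))
  }
  eta <- rep(config$true_alpha, nrow(sites))
  for (nm in names(config$true_betas)) {
    eta <- eta + config$true_betas[[nm]] * sites[[nm]]
  }
  eta <- eta +
    unname(config$species_effects[sites$moss_species]) +
    unname(config$tree_effects[sites$tree_cover]) +
    unname(config$zone_effects[sites$zone])
  eps <- with_substream(config$seed, "response", {
    rnorm(nrow(sites), sd = config$sigma)
  })
  out <- dplyr::mutate(sites, cd = inverse_cll(eta + eps, config$cd_max))
  attr(out, "eta") <- eta
  attr(out, "overfit_risk") <- attr(sites, "overfit_risk")
  out
}

#' Generate a prediction grid with covariates
#'
#' Lays a regular grid of square cells over the configured zone rectangles and
#' evaluates every quantitative covariate at each cell centre, from the same
#' latent fields used by [generate_sites()] — a grid cell coincident with a
#' site location carries the site's covariate values. Cells whose centre falls
#' outside all zones are dropped. Zone membership uses half-open rectangles
#' (`xmin <= x < xmax`) so each cell belongs to exactly one zone.
#'
#' @param config A [study_config()].
#' @param cell_size_m Cell edge length in metres (e.g. `2000` for a
#'   2 x 2 km production grid; coarser for demonstrations).
#' @return A tibble with `x`, `y` (cell centres), `zone` and covariate
#'   columns; the attribute `n_cells` records the cell count.
#' @export
generate_grid <- function(config, cell_size_m) {
  stopifnot(inherits(config, "study_config"))
  if (!is.numeric(cell_size_m) || cell_size_m <= 0)
    abort("`cell_size_m` must be positive.")
  layout <- config$zone_layout
  x0 <- min(layout$xmin); x1 <- max(layout$xmax)
  y0 <- min(layout$ymin); y1 <- max(layout$ymax)
  if (x1 <= x0 || y1 <= y0) abort("zone layout has empty extent.")

  cx <- seq(x0 + cell_size_m / 2, x1, by = cell_size_m)
  cy <- seq(y0 + cell_size_m / 2, y1, by = cell_size_m)
  grid <- tidyr::expand_grid(x = cx, y = cy)
  grid$zone <- assign_zone(grid$x, grid$y, layout)
  grid <- dplyr::filter(grid, !is.na(.data$zone))
  if (nrow(grid) == 0) abort("no grid cell falls inside the zone layout.")

  fields <- make_latent_fields(config)
  covs <- eval_covariates(fields, config, grid$x, grid$y)
  covs <- apply_zero_inflation(covs, config, grid$zone)
  out <- dplyr::bind_cols(grid, covs)
  attr(out, "n_cells") <- nrow(out)
  attr(out, "cell_size_m") <- cell_size_m
  out
}

# Half-open rectangle membership; NA when outside every zone.
assign_zone <- function(x, y, layout) {
  zone <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(layout))) {
    inside <- x >= layout$xmin[i] & x < layout$xmax[i] &
      y >= layout$ymin[i] & y < layout$ymax[i]
    zone[inside & is.na(zone)] <- layout$zone[i]
  }
  zone
}
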