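#' Configuration for a synthetic moss-biomonitoring study
#'
#' Defines the study design emulated by [generate_sites()], [simulate_response()]
#' and [generate_grid()]: number of sites, biogeographical zone layout, moss
#' species and tree-cover frequencies, the quantitative covariate fields, and
#' the data-generating complementary log-log (CLL) model
#' \deqn{\ln(\ln(Cd_{max}/Y_i)) = \alpha + \sum_j \beta_j X_i^j + \epsilon_i,
#'       \quad \epsilon_i \sim N(0, \sigma^2).}
#'
#' Defaults emulate a national forest-moss survey: 445 sites across four
#' biogeographical zones (Atlantic, Continental, Mediterranean, Alpine) with
#' site frequencies 220/147/49/29, five moss species with frequencies
#' 227/186/27/4/1 (Hc, Pp, Tt, Ps, Hs), four tree-cover classes, buffered
#' land-use covariate families at 1/5/10/15 km radii built from shared latent
#' spatial fields (so that within-family rank correlations are high, as for
#' real buffered percentages), plus unbuffered altitude, modelled air
#' concentration and soil concentration covariates.
#'
#' @param n_sites Number of sampling sites.
#' @param zone_layout Tibble with columns `zone`, `xmin`, `xmax`, `ymin`,
#'   `ymax` (metres, axis-aligned non-overlapping rectangles) and `prob`
#'   (site allocation probabilities).
#' @param species_probs Named probability vector over moss species.
#' @param tree_probs Named probability vector over tree-cover classes.
#' @param covariate_spec Tibble describing quantitative covariates; see
#'   [default_covariate_spec()].
#' @param true_alpha Intercept of the data-generating CLL model (transformed
#'   scale).
#' @param true_betas Named vector of slopes for quantitative covariates
#'   (transformed scale, per native covariate unit).
#' @param species_effects,tree_effects,zone_effects Named vectors of additive
#'   effects on the transformed scale; reference levels (Hc, deciduous,
#'   Alpine) must be 0.
#' @param sigma Standard deviation of the site-level noise on the transformed
#'   scale.
#' @param cd_max Upper bound of the concentration response, in micrograms per
#'   gram.
#' @param seed Master seed; all stages draw from substreams derived from it.
#'
#' @return An object of class `study_config`.
#' @export
#' @examples
#' cfg <- study_config(n_sites = 50, seed = 1)
#' cfg$species_probs
study_config <- function(n_sites = 445,
                         zone_layout = default_zone_layout(),
                         species_probs = c(Hc = 227, Pp = 186, Tt = 27,
                                           Ps = 4, Hs = 1) / 445,
                         tree_probs = c(deciduous = 0.45, coniferous = 0.30,
                                        mixed_deciduous = 0.15,
                                        mixed_coniferous = 0.10),
                         covariate_spec = default_covariate_spec(),
                         true_alpha = 0.9,
                         true_betas = default_true_betas(),
                         species_effects = c(Hc = 0, Pp = -0.20, Tt = -0.30,
                                             Ps = -0.20, Hs = 0),
                         tree_effects = c(deciduous = 0, coniferous = 0.25,
                                          mixed_deciduous = 0.10,
                                          mixed_coniferous = 0.20),
                         zone_effects = c(Alpine = 0, Atlantic = 0.15,
                                          Continental = 0.10,
                                          Mediterranean = -0.10),
                         sigma = 0.3,
                         cd_max = 1.5,
                         seed = 1L) {
  if (!is.numeric(n_sites) || n_sites < 1) abort("`n_sites` must be positive.")
  if (abs(sum(species_probs) - 1) > 1e-12)
    abort("`species_probs` must sum to 1 (within 1e-12).")
  if (abs(sum(tree_probs) - 1) > 1e-12)
    abort("`tree_probs` must sum to 1 (within 1e-12).")
  if (abs(sum(zone_layout$prob) - 1) > 1e-12)
    abort("zone allocation probabilities must sum to 1 (within 1e-12).")
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (cd_max <= 0) abort("`cd_max` must be positive.")
  check_zones_disjoint(zone_layout)

  cfg <- list(
    n_sites = as.integer(n_sites),
    zone_layout = zone_layout,
    species_probs = species_probs,
    tree_probs = tree_probs,
    covariate_spec = covariate_spec,
    true_alpha = true_alpha,
    true_betas = true_betas,
    species_effects = species_effects,
    tree_effects = tree_effects,
    zone_effects = zone_effects,
    sigma = sigma,
    cd_max = cd_max,
    seed = as.integer(seed)
  )
  structure(cfg, class = "study_config")
}

check_zones_disjoint <- function(layout) {
  n <- nrow(layout)
  if (n < 1) abort("zone layout is empty.")
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      overlap_x <- layout$xmin[i] < layout$xmax[j] && layout$xmin[j] < layout$xmax[i]
      overlap_y <- layout$ymin[i] < layout$ymax[j] && layout$ymin[j] < layout$ymax[i]
      if (overlap_x && overlap_y)
        abort(sprintf("zones '%s' and '%s' overlap.",
                      layout$zone[i], layout$zone[j]))
    }
  }
  invisible(layout)
}

#' Default biogeographical zone layout
#'
#' Four axis-aligned rectangles on a 900 x 900 km planar domain standing in
#' for the Atlantic, Continental, Mediterranean and Alpine zones, with site
#' allocation probabilities proportional to 220/147/49/29.
#'
#' @return A tibble with columns `zone`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `prob`.
#' @export
default_zone_layout <- function() {
  tibble::tibble(
    zone = c("Atlantic", "Continental", "Mediterranean", "Alpine"),
    xmin = c(0, 400e3, 400e3, 400e3),
    xmax = c(400e3, 900e3, 900e3, 900e3),
    ymin = c(0, 300e3, 0, 200e3),
    ymax = c(900e3, 900e3, 200e3, 300e3),
    prob = c(220, 147, 49, 29) / 445
  )
}

#' Default quantitative covariate specification
#'
#' Six buffered land-use families (percentages at 1/5/10/15 km radii, built
#' as monotone transforms of one latent Gaussian field per family plus
#' radius-specific jitter so within-family Spearman correlations exceed
#' `rho_target`) and three unbuffered covariates (altitude in metres, modelled
#' air concentration and soil concentration on positive scales). `zero_prop`
#' is the per-zone proportion of exact zeros (spatially coherent: the lowest
#' latent values are zeroed), emulating land-use classes absent from most
#' buffers, such as sea or industrial area.
#'
#' @return A tibble with one row per covariate family or single covariate:
#'   `name`, `type` (`percent`, `altitude`, `positive`), `radii` (list
#'   column, km; `NA` for unbuffered), `corr_length` (metres),
#'   `rho_target`, `zero_prop`, `meanlog`, `sdlog`.
#' @export
default_covariate_spec <- function() {
  fam <- function(name, corr_length, zero_prop) {
    tibble::tibble(name = name, type = "percent",
                   radii = list(c(1, 5, 10, 15)),
                   corr_length = corr_length, rho_target = 0.8,
                   zero_prop = zero_prop, meanlog = NA_real_,
                   sdlog = NA_real_)
  }
  dplyr::bind_rows(
    fam("Forest", 60e3, 0),
    fam("Urban", 40e3, 0.25),
    fam("Agricultural", 60e3, 0.10),
    fam("Pasture", 60e3, 0.10),
    fam("Vegetation", 50e3, 0.20),
    fam("Sea", 80e3, 0.70),
    tibble::tibble(name = "Altitude", type = "altitude", radii = list(NA_real_),
                   corr_length = 80e3, rho_target = NA_real_, zero_prop = 0,
                   meanlog = NA_real_, sdlog = NA_real_),
    tibble::tibble(name = "EMEP_air", type = "positive", radii = list(NA_real_),
                   corr_length = 100e3, rho_target = NA_real_, zero_prop = 0,
                   meanlog = log(0.5), sdlog = 0.4),
    tibble::tibble(name = "RMQS_tot", type = "positive", radii = list(NA_real_),
                   corr_length = 60e3, rho_target = NA_real_, zero_prop = 0,
                   meanlog = log(0.3), sdlog = 0.5)
  )
}

#' Default data-generating slopes
#'
#' Non-zero slopes for a handful of covariates, on the transformed
#' (complementary log-log) scale per native covariate unit. Signs follow the
#' usual biomonitoring expectations: higher modelled air and soil
#' concentrations and more urban land use increase moss Cd (decrease the
#' transformed response), higher altitude decreases it.
#'
#' @return A named numeric vector.
#' @export
default_true_betas <- function() {
  c(EMEP_air = -0.55, RMQS_tot = -0.35, Urban_5 = -0.004,
    Forest_1 = -0.002, Pasture_5 = 0.003, Altitude = 4e-4)
}

#' @export
print.study_config <- function(x, ...) {
  n_cov <- sum(vapply(seq_len(nrow(x$covariate_spec)), function(i) {
    r <- x$covariate_spec$radii[[i]]
    if (all(is.na(r))) 1L else length(r)
  }, integer(1)))
  cat("<study_config>\n")
  cat("  sites:", x$n_sites, " zones:", nrow(x$zone_layout),
      " quantitative covariates:", n_cov, "\n")
  cat("  cd_max:", x$cd_max, "ug/g   sigma:", x$sigma,
      "  seed:", x$seed, "\n")
  invisible(x)
}

# Expand the covariate spec into one row per generated column.
expand_covariates <- function(spec) {
  purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    r <- spec$radii[[i]]
    if (all(is.na(r))) {
      tibble::tibble(column = spec$name[i], family = spec$name[i],
                     radius = NA_real_, idx = i)
    } else {
      tibble::tibble(column = paste0(spec$name[i], "_", r),
                     family = spec$name[i], radius = r, idx = i)
    }
  })
}
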