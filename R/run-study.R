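#' Run the full mapping study end to end
#'
#' Executes the whole analysis on synthetic data from one configuration:
#' simulate sites and response; then, for the nation-wide scope — covariate
#' screening (zero-proportion and Spearman filters), backward-forward AIC
#' selection of the CLL model, Moran's I on the transformed response and on
#' the residuals, gridded prediction with delta-method SDs — plus an
#' ordinary-kriging baseline map; the same modelling within each
#' biogeographical zone with the per-zone maps mosaicked; and leave-one-out
#' cross-validation comparing the encompassing model (scored zone by zone),
#' the zone-specific models, and kriging, on the concentration scale.
#'
#' @param config A [study_config()].
#' @param cell_size_m Prediction-grid cell size in metres (default 20 km, a
#'   demonstration scale; use 2000 for a production 2 x 2 km grid).
#' @param n_perm Permutations for the Moran tests.
#' @param min_zone_sites Zones with fewer sites are skipped (with a message)
#'   for zone-specific modelling.
#' @param run_loocv Compute the LOOCV comparison (the slowest stage).
#' @param quiet Suppress stage progress messages.
#' @return A list of class `moss_study`: `sites`, `grid`, `france`
#'   (screening, selection, fit, moran before/after, prediction), `kriging`
#'   (variogram, prediction, loocv), `zones` (per-zone stages),
#'   `zone_mosaic`, `moran_table`, `loocv` and `comparison`.
#' @export
run_study <- function(config, cell_size_m = 20e3, n_perm = 999,
                      min_zone_sites = 15, run_loocv = TRUE, quiet = TRUE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) inform(paste0(...))
  stage <- function(name, scope, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed for scope '%s': %s",
                    name, scope, conditionMessage(e)))
    })
  }

  say("simulating sites and grid")
  sites <- stage("simulate", "France",
                 simulate_response(generate_sites(config), config))
  grid <- stage("grid", "France", generate_grid(config, cell_size_m))
  z <- cll_transform(sites$cd, config$cd_max)
  coords <- cbind(sites$x, sites$y)

  analyse_scope <- function(dat, scope, with_zone) {
    say("screening covariates: ", scope)
    screening <- stage("screen", scope, screen_covariates(dat))
    cats <- c("moss_species", "tree_cover", if (with_zone) "zone")
    say("model selection: ", scope)
    selection <- stage("fit", scope,
                       stepwise_aic(dat, c(cats, screening$retained),
                                    config$cd_max))
    fit <- selection$fit
    zz <- cll_transform(dat$cd, config$cd_max)
    cc <- cbind(dat$x, dat$y)
    say("Moran diagnostics: ", scope)
    moran_before <- stage("moran", scope,
                          moran_i(zz, cc, n_perm = n_perm,
                                  seed = substream_seed(config$seed,
                                                        paste0("mb:", scope))))
    moran_after <- stage("moran", scope,
                         moran_i(residuals(fit), cc, n_perm = n_perm,
                                 seed = substream_seed(config$seed,
                                                       paste0("ma:", scope))))
    list(screening = screening, selection = selection, fit = fit,
         moran_before = moran_before, moran_after = moran_after)
  }

  france <- analyse_scope(sites, "France", with_zone = TRUE)
  say("predicting France grid")
  france$prediction <- stage("predict", "France",
                             predict_grid(france$fit, grid))

  say("ordinary kriging baseline")
  vgm <- stage("krige", "France", fit_variogram(sites))
  kriging <- list(variogram = vgm,
                  prediction = stage("krige", "France",
                                     ok_predict(sites, vgm, grid)))

  zones <- list()
  zone_preds <- list()
  for (zn in config$zone_layout$zone) {
    dat <- dplyr::filter(sites, .data$zone == zn)
    if (nrow(dat) < min_zone_sites) {
      say("skipping zone ", zn, " (", nrow(dat), " sites)")
      next
    }
    res <- analyse_scope(dat, zn, with_zone = FALSE)
    zgrid <- dplyr::filter(grid, .data$zone == zn)
    res$prediction <- stage("predict", zn, predict_grid(res$fit, zgrid))
    zones[[zn]] <- res
    zone_preds[[zn]] <- res$prediction
  }
  zone_mosaic <- if (length(zone_preds) > 0) {
    mosaic_zone_maps(zone_preds)
  } else NULL

  moran_table <- purrr::map_dfr(c(list(France = france), zones),
    function(res) {
      dplyr::bind_rows(
        dplyr::mutate(tidy(res$moran_before), stage = "response"),
        dplyr::mutate(tidy(res$moran_after), stage = "residuals"))
    }, .id = "scope")
  moran_table <- dplyr::select(moran_table, "scope", "stage", "i_stat",
                               "expected_i", "p_value")

  loocv_results <- NULL
  comparison <- NULL
  if (run_loocv) {
    say("LOOCV: encompassing model")
    enc <- stage("loocv", "France",
                 loocv(sites, "cll_regression",
                       list(variables = france$selection$final_variables),
                       scope = "France", cd_max = config$cd_max))
    enc_zones <- loocv_by_zone(enc, sites)
    say("LOOCV: zone-specific models")
    zone_lo <- purrr::imap(zones, function(res, zn) {
      stage("loocv", zn,
            loocv(dplyr::filter(sites, .data$zone == zn), "cll_regression",
                  list(variables = res$selection$final_variables),
                  scope = zn, cd_max = config$cd_max))
    })
    say("LOOCV: kriging")
    krig_lo <- stage("loocv", "France",
                     loocv(sites, "ordinary_kriging", list(vgm = vgm),
                           scope = "France", cd_max = config$cd_max))
    loocv_results <- list(encompassing = enc, encompassing_by_zone = enc_zones,
                          zone_specific = zone_lo, kriging = krig_lo)
    rows <- function(x, model) {
      dplyr::mutate(glance(x), model = model, .before = "method")
    }
    comparison <- dplyr::bind_rows(
      rows(enc, "encompassing"),
      purrr::map_dfr(enc_zones, rows, model = "encompassing"),
      purrr::map_dfr(zone_lo, rows, model = "zone_specific"),
      if (length(zone_lo) > 1) {
        per <- dplyr::bind_rows(purrr::map(zone_lo, "per_site"))
        tibble::tibble(model = "zone_specific", scope = "France (pooled)",
                       method = "cll_regression",
                       rmse = rmse(per$y, per$y_hat), M = nrow(per),
                       n_flagged = sum(per$flagged))
      },
      rows(krig_lo, "kriging")
    )
    comparison <- dplyr::select(comparison, "scope", "model", "rmse", "M")
  }

  structure(list(
    config = config, sites = sites, grid = grid,
    france = france, kriging = kriging, zones = zones,
    zone_mosaic = zone_mosaic, moran_table = moran_table,
    loocv = loocv_results, comparison = comparison
  ), class = "moss_study")
}

#' @export
print.moss_study <- function(x, ...) {
  cat("<moss_study>\n")
  cat("  sites:", nrow(x$sites), "  grid cells:", nrow(x$grid), "\n")
  cat("  France model:",
      length(x$france$selection$final_variables), "variables, AIC",
      round(x$france$selection$final_aic, 2), "\n")
  cat("  zone models:", paste(names(x$zones), collapse = ", "), "\n")
  if (!is.null(x$comparison)) {
    cat("  LOOCV comparison:\n")
    print(as.data.frame(x$comparison), row.names = FALSE)
  }
  invisible(x)
}
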