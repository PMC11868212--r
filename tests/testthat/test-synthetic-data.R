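test_that("species and tree-cover draws match the configured frequencies", {
  cfg <- study_config(n_sites = 445, seed = 101)
  sites <- quiet_sites(cfg)
  expect_equal(nrow(sites), 445)
  counts <- table(factor(sites$moss_species, names(cfg$species_probs)))
  expected <- 445 * cfg$species_probs
  sds <- sqrt(445 * cfg$species_probs * (1 - cfg$species_probs))
  expect_true(all(abs(counts - expected) <= 3 * sds))
  expect_true(all(sites$moss_species %in% names(cfg$species_probs)))
  expect_true(all(sites$tree_cover %in% names(cfg$tree_probs)))
})

test_that("sites fall inside their zone rectangles", {
  cfg <- tiny_config(n = 120, seed = 5)
  sites <- quiet_sites(cfg)
  layout <- cfg$zone_layout
  for (i in seq_len(nrow(layout))) {
    s <- dplyr::filter(sites, zone == layout$zone[i])
    expect_true(all(s$x >= layout$xmin[i] & s$x <= layout$xmax[i]))
    expect_true(all(s$y >= layout$ymin[i] & s$y <= layout$ymax[i]))
  }
})

test_that("zero-inflation settings control exact zeros", {
  spec <- default_covariate_spec()
  spec$zero_prop <- rep(0, nrow(spec))
  cfg <- study_config(n_sites = 10, covariate_spec = spec, seed = 3)
  sites <- quiet_sites(cfg)
  covs <- as.matrix(sites[, covariate_columns(sites)])
  expect_true(all(covs != 0))

  cfg2 <- study_config(n_sites = 300, seed = 3)
  sites2 <- generate_sites(cfg2)
  # Sea family configured with 70% zeros per zone
  for (zn in unique(sites2$zone)) {
    v <- sites2$Sea_1[sites2$zone == zn]
    if (length(v) >= 20) {
      expect_equal(mean(v == 0), 0.7, tolerance = 0.1)
    }
  }
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- tiny_config(n = 50, seed = 77)
  a <- simulate_response(quiet_sites(cfg), cfg)
  b <- simulate_response(quiet_sites(cfg), cfg)
  expect_identical(a, b)
  g1 <- generate_grid(cfg, 60e3)
  g2 <- generate_grid(cfg, 60e3)
  expect_identical(g1, g2)
})

test_that("buffer families exceed the configured Spearman target", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- study_config(n_sites = 200, seed = 1000 + r)
    sites <- quiet_sites(cfg)
    fam <- as.matrix(sites[, paste0("Forest_", c(1, 5, 10, 15))])
    rho <- cor(fam, method = "spearman")
    if (min(rho[upper.tri(rho)]) > 0.8) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("grid covariates come from the same fields as site covariates", {
  spec <- default_covariate_spec()
  spec$zero_prop <- rep(0, nrow(spec))
  cfg <- study_config(n_sites = 20, covariate_spec = spec, seed = 9)
  # coarse-grid centres recur exactly in a 3x finer grid
  coarse <- generate_grid(cfg, 90e3)
  fine <- generate_grid(cfg, 30e3)
  key_c <- paste(coarse$x, coarse$y)
  key_f <- paste(fine$x, fine$y)
  shared <- intersect(key_c, key_f)
  expect_gt(length(shared), 10)
  cc <- covariate_columns(coarse)
  a <- as.matrix(coarse[match(shared, key_c), cc])
  b <- as.matrix(fine[match(shared, key_f), cc])
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("grid cell count follows the extent arithmetic", {
  layout <- tibble::tibble(zone = "Z", xmin = 0, xmax = 100e3,
                           ymin = 0, ymax = 80e3, prob = 1)
  cfg <- study_config(n_sites = 20, zone_layout = layout,
                      zone_effects = c(Z = 0), seed = 1)
  g <- generate_grid(cfg, 2e3)
  expect_equal(nrow(g), 50 * 40)
  expect_equal(attr(g, "n_cells"), 2000)
  expect_error(generate_grid(cfg, -5), "positive")
})

test_that("an under-sampled design raises the overfitting flag", {
  cfg <- study_config(n_sites = 20, seed = 2)
  expect_warning(sites <- generate_sites(cfg), "overfitting")
  expect_true(attr(sites, "overfit_risk"))
  cfg2 <- study_config(n_sites = 445, seed = 2)
  expect_false(attr(generate_sites(cfg2), "overfit_risk"))
})

test_that("responses follow the stated noise model and stay in bounds", {
  # identity case: sigma = 0, alpha = 0, no effects -> Y = cd_max / e
  spec <- default_covariate_spec()[7:9, ]
  cfg0 <- study_config(
    n_sites = 25, covariate_spec = spec, true_alpha = 0,
    true_betas = c(EMEP_air = 0), sigma = 0,
    species_effects = c(Hc = 0, Pp = 0, Tt = 0, Ps = 0, Hs = 0),
    tree_effects = c(deciduous = 0, coniferous = 0, mixed_deciduous = 0,
                     mixed_coniferous = 0),
    zone_effects = c(Alpine = 0, Atlantic = 0, Continental = 0,
                     Mediterranean = 0),
    seed = 4)
  s0 <- simulate_response(generate_sites(cfg0), cfg0)
  expect_equal(s0$cd, rep(1.5 / exp(1), 25), tolerance = 1e-12)

  # noiseless round trip: transform recovers the linear predictor exactly
  cfg1 <- study_config(n_sites = 40, covariate_spec = spec, sigma = 0,
                       true_betas = c(EMEP_air = -0.5, RMQS_tot = -0.3),
                       seed = 4)
  s1 <- simulate_response(generate_sites(cfg1), cfg1)
  expect_equal(cll_transform(s1$cd, 1.5), attr(s1, "eta"), tolerance = 1e-12)

  # Monte-Carlo check of the noise SD on the transformed scale
  cfg2 <- study_config(n_sites = 10000, covariate_spec = spec, sigma = 0.3,
                       true_betas = c(EMEP_air = -0.5), seed = 21)
  s2 <- simulate_response(generate_sites(cfg2), cfg2)
  resid_sd <- sd(cll_transform(s2$cd, 1.5) - attr(s2, "eta"))
  expect_equal(resid_sd, 0.3, tolerance = 0.02)

  # boundedness on 1e5 draws
  cfg3 <- study_config(n_sites = 1e5, covariate_spec = spec, sigma = 0.6,
                       true_betas = c(EMEP_air = -0.8), seed = 31)
  s3 <- simulate_response(generate_sites(cfg3), cfg3)
  expect_true(all(s3$cd > 0 & s3$cd < 1.5))
})

test_that("missing covariates named in true_betas are rejected", {
  cfg <- tiny_config(n = 10, seed = 1,
                     true_betas = c(NotThere = 1))
  sites <- quiet_sites(cfg)
  expect_error(simulate_response(sites, cfg), "NotThere")
})

test_that("invalid configurations are rejected", {
  expect_error(study_config(species_probs = c(Hc = 0.5, Pp = 0.4)), "sum to 1")
  expect_error(study_config(sigma = -1), "non-negative")
  expect_error(study_config(cd_max = 0), "positive")
  bad_layout <- tibble::tibble(
    zone = c("A", "B"), xmin = c(0, 50), xmax = c(100, 150),
    ymin = c(0, 0), ymax = c(100, 100), prob = c(0.5, 0.5))
  expect_error(study_config(zone_layout = bad_layout), "overlap")
})
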