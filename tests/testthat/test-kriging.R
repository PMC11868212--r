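# simulate a Gaussian random field with exponential covariance at coords
sim_exp_field <- function(coords, nugget, psill, range_m, seed) {
  withr::with_seed(seed, {
    d <- as.matrix(dist(coords))
    sigma <- psill * exp(-d / range_m) + diag(nugget, nrow(coords))
    l <- chol(sigma + diag(1e-10, nrow(coords)))
    drop(t(l) %*% rnorm(nrow(coords)))
  })
}

test_that("the fitted semivariance function is well-behaved", {
  vgm <- structure(list(family = "exponential", nugget = 0.1,
                        partial_sill = 0.5, range = 30e3),
                   class = "variogram_model")
  expect_equal(semivariance(0, vgm), 0.1)  # gamma(0) = nugget
  h <- seq(0, 2e5, length.out = 100)
  for (fam in c("exponential", "spherical", "gaussian")) {
    g <- semivariance(h, fam, 0.1, 0.5, 30e3)
    expect_true(all(diff(g) >= -1e-12))
    expect_equal(g[1], 0.1)
  }
  expect_error(semivariance(1, "matern", 0, 1, 1), "unknown")
})

test_that("pure-nugget data yield a near-flat empirical variogram", {
  withr::with_seed(61, {
    n <- 200
    obs <- tibble::tibble(x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                          cd = exp(rnorm(n, log(0.3), 0.3)))
  })
  vgm <- fit_variogram(obs)
  emp <- vgm$empirical_bins
  expect_lt((max(emp$gamma) - min(emp$gamma)) / mean(emp$gamma), 0.2)
})

test_that("kriging is exact at data sites when the nugget is zero", {
  withr::with_seed(62, {
    n <- 30
    obs <- tibble::tibble(x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                          cd = runif(n, 0.1, 1.2))
  })
  vgm <- structure(list(family = "exponential", nugget = 0,
                        partial_sill = 0.4, range = 25e3),
                   class = "variogram_model")
  pred <- ok_predict(obs, vgm, obs[, c("x", "y")])
  expect_equal(pred$y_hat, obs$cd, tolerance = 1e-8)
  expect_true(all(pred$sd_log < 1e-4))
})

test_that("constant observations krige to that constant everywhere", {
  withr::with_seed(63, {
    obs <- tibble::tibble(x = runif(20, 0, 1e5), y = runif(20, 0, 1e5),
                          cd = 0.42)
    grid <- tibble::tibble(x = runif(15, 0, 1e5), y = runif(15, 0, 1e5))
  })
  vgm <- structure(list(family = "exponential", nugget = 0.05,
                        partial_sill = 0.3, range = 20e3),
                   class = "variogram_model")
  pred <- ok_predict(obs, vgm, grid)
  expect_equal(pred$y_hat, rep(0.42, 15), tolerance = 1e-10)
})

test_that("4-point weights match a directly solved 5x5 system", {
  oc <- rbind(c(0, 0), c(10e3, 0), c(0, 10e3), c(12e3, 9e3))
  vgm <- structure(list(family = "exponential", nugget = 0.1,
                        partial_sill = 0.5, range = 30e3),
                   class = "variogram_model")
  target <- c(4e3, 5e3)
  sol <- ok_weights(oc, vgm, target)
  gam <- semivariance(as.matrix(dist(oc)), vgm)
  diag(gam) <- 0
  a <- rbind(cbind(gam, 1), c(1, 1, 1, 1, 0))
  g0 <- semivariance(sqrt(colSums((t(oc) - target)^2)), vgm)
  hand <- solve(a, c(g0, 1))
  expect_equal(sol$weights, hand[1:4], tolerance = 1e-10)
  expect_equal(sol$mu, unname(hand[5]), tolerance = 1e-10)
  expect_equal(sol$variance, unname(sum(hand[1:4] * g0) + hand[5]),
               tolerance = 1e-10)
})

test_that("kriging weights sum to one and variances are non-negative", {
  withr::with_seed(64, {
    n <- 40
    oc <- cbind(runif(n, 0, 1e5), runif(n, 0, 1e5))
    targets <- cbind(runif(10, 0, 1e5), runif(10, 0, 1e5))
  })
  vgm <- structure(list(family = "spherical", nugget = 0.05,
                        partial_sill = 0.4, range = 40e3),
                   class = "variogram_model")
  for (i in 1:10) {
    sol <- ok_weights(oc, vgm, targets[i, ])
    expect_equal(sum(sol$weights), 1, tolerance = 1e-10)
    expect_gte(sol$variance, 0)
  }
})

test_that("variogram fitting recovers known parameters roughly", {
  withr::with_seed(65, {
    n <- 300
    coords <- cbind(runif(n, 0, 120e3), runif(n, 0, 120e3))
  })
  z <- sim_exp_field(coords, nugget = 0.1, psill = 0.5, range_m = 30e3,
                     seed = 66)
  obs <- tibble::tibble(x = coords[, 1], y = coords[, 2],
                        cd = exp(z + log(0.3)))
  vgm <- fit_variogram(obs)
  expect_equal(vgm$family, "exponential")
  expect_equal(vgm$nugget + vgm$partial_sill, 0.6, tolerance = 0.4)
  expect_gt(vgm$range, 5e3)
  expect_s3_class(tidy(vgm), "tbl_df")
})

test_that("degenerate variogram inputs raise errors", {
  few <- tibble::tibble(x = runif(5), y = runif(5), cd = runif(5, 0.1, 1))
  expect_error(fit_variogram(few), "at least 10")
  same <- tibble::tibble(x = rep(0, 12), y = rep(0, 12),
                         cd = runif(12, 0.1, 1))
  expect_error(fit_variogram(same), "identical")
  vgm <- structure(list(family = "exponential", nugget = 0.1,
                        partial_sill = 0.5, range = 30e3),
                   class = "variogram_model")
  obs <- tibble::tibble(x = runif(12, 0, 1e4), y = runif(12, 0, 1e4),
                        cd = runif(12, 0.1, 1))
  expect_error(ok_predict(obs, vgm, obs[0, c("x", "y")]), "empty")
})
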