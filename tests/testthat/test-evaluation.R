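test_that("rmse follows the root-mean-square formula", {
  y <- c(1, 2, 3, 4)
  yh <- y - c(0.1, -0.1, 0.2, -0.2)
  expect_equal(rmse(y, yh), sqrt(0.1 / 4))
  expect_equal(rmse(y, y), 0)
})

test_that("LOOCV matches a brute-force per-fold refit oracle at M = 5", {
  withr::with_seed(71, {
    s <- tibble::tibble(id = paste0("s", 1:5),
                        x = runif(5, 0, 1e4), y = runif(5, 0, 1e4),
                        A = rnorm(5),
                        cd = runif(5, 0.1, 1.2))
  })
  res <- loocv(s, "cll_regression", list(variables = "A"))
  oracle <- vapply(1:5, function(i) {
    train <- s[-i, ]
    z <- cll_transform(train$cd, 1.5)
    b <- coef(lm(z ~ A, data = train))
    inverse_cll(b[1] + b[2] * s$A[i], 1.5)
  }, numeric(1))
  expect_equal(res$per_site$y_hat, oracle, tolerance = 1e-10)
  expect_equal(res$rmse, sqrt(mean((s$cd - oracle)^2)), tolerance = 1e-12)
})

test_that("noiseless covariate-driven data give zero regression LOOCV error", {
  withr::with_seed(72, {
    n <- 40
    s <- tibble::tibble(id = as.character(1:n),
                        x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                        A = rnorm(n), B = rnorm(n))
    s$cd <- inverse_cll(0.3 + 0.6 * s$A - 0.4 * s$B, 1.5)
  })
  res <- loocv(s, "cll_regression", list(variables = c("A", "B")))
  expect_lt(res$rmse, 1e-8)
  vgm <- fit_variogram(s)
  krig <- loocv(s, "ordinary_kriging", list(vgm = vgm))
  expect_gt(krig$rmse, 1e-3)
})

test_that("transformed-scale folds obey the linear-smoother identity", {
  withr::with_seed(73, {
    n <- 30
    s <- tibble::tibble(id = as.character(1:n),
                        x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                        A = rnorm(n), B = rnorm(n))
    s$cd <- inverse_cll(0.2 + 0.5 * s$A - 0.3 * s$B + rnorm(n, sd = 0.2), 1.5)
  })
  res <- loocv(s, "cll_regression", list(variables = c("A", "B")))
  # closed form: z_i - e_i / (1 - h_ii) is the held-out transformed prediction
  z <- cll_transform(s$cd, 1.5)
  X <- cbind(1, s$A, s$B)
  h <- diag(X %*% solve(crossprod(X)) %*% t(X))
  e <- residuals(lm(z ~ A + B, data = s))
  z_loo <- z - e / (1 - h)
  expect_equal(cll_transform(res$per_site$y_hat, 1.5), unname(z_loo),
               tolerance = 1e-8)
  # but the concentration-scale RMSE is not the inverse transform of the
  # transformed-scale RMSE: refits on the original scale are essential
  rmse_z <- sqrt(mean((z - z_loo)^2))
  expect_gt(abs(res$rmse - abs(inverse_cll(rmse_z, 1.5))), 1e-3)
})

test_that("LOOCV runs are deterministic and folds are independent", {
  withr::with_seed(74, {
    n <- 20
    s <- tibble::tibble(id = as.character(1:n),
                        x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                        A = rnorm(n),
                        cd = runif(n, 0.1, 1.2))
  })
  a <- loocv(s, "cll_regression", list(variables = "A"))
  b <- loocv(s, "cll_regression", list(variables = "A"))
  expect_identical(a$per_site, b$per_site)
})

test_that("folds with a unique categorical level fall back to the reference", {
  cfg <- tiny_config(n = 120, seed = 75)
  s <- simulate_response(quiet_sites(cfg), cfg)
  # force exactly one site to carry a species seen nowhere else
  s$moss_species <- rep(c("Hc", "Pp"), length.out = nrow(s))
  s$moss_species[1] <- "Hs"
  res <- loocv(s, "cll_regression",
               list(variables = c("moss_species", "EMEP_air")))
  expect_equal(res$n_flagged, 1)
  expect_true(res$per_site$flagged[1])
  expect_true(all(is.finite(res$per_site$y_hat)))
})

test_that("pooled RMSE satisfies the weighted-square identity", {
  withr::with_seed(76, {
    mk <- function(zone, n) {
      s <- tibble::tibble(id = paste0(zone, 1:n),
                          x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                          A = rnorm(n))
      s$cd <- inverse_cll(0.4 + 0.3 * s$A + rnorm(n, sd = 0.3), 1.5)
      loocv(s, "cll_regression", list(variables = "A"), scope = zone)
    }
    r1 <- mk("Z1", 15)
    r2 <- mk("Z2", 25)
  })
  tab <- compare_scopes(list(r1, r2), pooled_label = "all")
  pooled <- tab$rmse[tab$scope == "all"]
  expected <- sqrt((15 * r1$rmse^2 + 25 * r2$rmse^2) / 40)
  expect_equal(pooled, expected, tolerance = 1e-12)
  # single scope, single method: the table is just that result
  tab1 <- compare_scopes(list(r1))
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$rmse, r1$rmse)
})

test_that("mismatched site sets across methods are rejected", {
  withr::with_seed(77, {
    n <- 15
    s <- tibble::tibble(id = as.character(1:n),
                        x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                        A = rnorm(n),
                        cd = runif(n, 0.1, 1.2))
  })
  r1 <- loocv(s, "cll_regression", list(variables = "A"), scope = "S")
  r2 <- loocv(s[-1, ], "ordinary_kriging",
              list(vgm = structure(list(family = "exponential", nugget = 0.05,
                                        partial_sill = 0.3, range = 2e4),
                                   class = "variogram_model")),
              scope = "S")
  expect_error(compare_scopes(list(r1, r2)), "disagree")
})

test_that("splitting one LOOCV result by zone preserves every fold", {
  cfg <- tiny_config(n = 100, seed = 78)
  s <- simulate_response(quiet_sites(cfg), cfg)
  res <- loocv(s, "cll_regression", list(variables = "EMEP_air"))
  by_zone <- loocv_by_zone(res, s)
  expect_equal(sum(purrr::map_int(by_zone, "M")), res$M)
  pooled <- sqrt(sum(purrr::map_dbl(by_zone, ~ .x$M * .x$rmse^2)) / res$M)
  expect_equal(pooled, res$rmse, tolerance = 1e-12)
})
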