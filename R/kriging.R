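#' Fit a variogram model to log-transformed observations
#'
#' Computes the classical (Matheron) empirical semivariogram of
#' `log(response)` — \eqn{\hat\gamma(h) = \frac{1}{2|N(h)|}\sum_{N(h)}
#' (z_i - z_j)^2} over distance bins — and fits a parametric model (nugget,
#' partial sill, range) by weighted least squares with pair counts as
#' weights.
#'
#' @param obs Site table with coordinates `x`, `y` and the response column.
#' @param response Response column name; values must be positive (they are
#'   log-transformed).
#' @param family Variogram family: `"exponential"` (default), `"spherical"`
#'   or `"gaussian"`.
#' @param n_bins Number of distance bins.
#' @param cutoff Maximum pair distance used (default one third of the
#'   maximum pairwise distance, a common variography default).
#' @return A `variogram_model`: list with `family`, `nugget`,
#'   `partial_sill`, `range`, `objective` (the WLS value) and
#'   `empirical_bins` (tibble of `lag`, `gamma`, `n_pairs`).
#' @export
fit_variogram <- function(obs, response = "cd", family = "exponential",
                          n_bins = 15, cutoff = NULL) {
  if (nrow(obs) < 10) abort("at least 10 sites are required.")
  z <- log(obs[[response]])
  coords <- cbind(obs$x, obs$y)
  d <- dist(coords)
  dv <- as.vector(d)
  if (max(dv) == min(dv)) abort("all pairwise distances are identical.")
  if (is.null(cutoff)) cutoff <- max(dv) / 3
  g <- 0.5 * as.vector(dist(z))^2  # elementwise half squared differences
  keep <- dv <= cutoff & dv > 0
  dv <- dv[keep]; g <- g[keep]
  breaks <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(dv, breaks, include.lowest = TRUE)
  emp <- tibble::tibble(
    lag = tapply(dv, bin, mean),
    gamma = tapply(g, bin, mean),
    n_pairs = as.numeric(table(bin))
  )
  emp <- emp[emp$n_pairs > 0 & !is.na(emp$gamma), ]

  sill0 <- max(emp$gamma)
  start <- c(nugget = max(min(emp$gamma), 1e-6),
             psill = max(sill0 - min(emp$gamma), 1e-6),
             range = cutoff / 3)
  obj <- function(par) {
    gm <- semivariance(emp$lag, family, par[1], par[2], par[3])
    sum(emp$n_pairs * (emp$gamma - gm)^2)
  }
  fit <- optim(start, obj, method = "L-BFGS-B",
               lower = c(0, 0, cutoff / 1e4),
               upper = c(2 * sill0, 4 * sill0, 4 * cutoff))
  structure(list(
    family = family,
    nugget = unname(fit$par[1]),
    partial_sill = unname(fit$par[2]),
    range = unname(fit$par[3]),
    objective = fit$value,
    empirical_bins = emp
  ), class = "variogram_model")
}

#' Semivariance of a fitted variogram model
#'
#' @param h Lag distances (metres).
#' @param family,nugget,partial_sill,range Model family and parameters; a
#'   `variogram_model` can be passed as `family`.
#' @return Semivariances \eqn{\gamma(h)}; \eqn{\gamma(0)} equals the nugget.
#' @export
semivariance <- function(h, family, nugget = NULL, partial_sill = NULL,
                         range = NULL) {
  if (inherits(family, "variogram_model")) {
    vgm <- family
    family <- vgm$family; nugget <- vgm$nugget
    partial_sill <- vgm$partial_sill; range <- vgm$range
  }
  s <- switch(family,
    exponential = 1 - exp(-h / range),
    gaussian = 1 - exp(-(h / range)^2),
    spherical = ifelse(h < range,
                       1.5 * h / range - 0.5 * (h / range)^3, 1),
    abort(sprintf("unknown variogram family '%s'", family))
  )
  nugget + partial_sill * s
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("<variogram_model> ", x$family, "\n")
  cat(sprintf("  nugget = %.4g  partial sill = %.4g  range = %.4g m\n",
              x$nugget, x$partial_sill, x$range))
  cat("  WLS objective:", signif(x$objective, 4),
      " bins:", nrow(x$empirical_bins), "\n")
  invisible(x)
}

#' @method tidy variogram_model
#' @export
tidy.variogram_model <- function(x, ...) {
  tibble::tibble(family = x$family, nugget = x$nugget,
                 partial_sill = x$partial_sill, range = x$range,
                 objective = x$objective)
}

# Solve the ordinary-kriging system for one or more targets.
# A = [[Gamma, 1], [1', 0]], rhs gamma0 per target; weights sum to 1 via the
# Lagrange multiplier row. Returns weights (n x m), multiplier and variance.
ok_solve <- function(obs_coords, vgm, target_coords) {
  n <- nrow(obs_coords)
  gam <- semivariance(as.matrix(dist(obs_coords)), vgm)
  diag(gam) <- 0
  a <- rbind(cbind(gam, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(target_coords[, 1], obs_coords[, 1], "-")^2 +
             outer(target_coords[, 2], obs_coords[, 2], "-")^2)
  g0 <- semivariance(d0, vgm)
  g0[d0 == 0] <- 0  # a target coincident with a site has zero semivariance
  rhs <- rbind(t(g0), 1)
  sol <- tryCatch(solve(a, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    # jitter-and-retry once (duplicate sites / zero nugget can be singular)
    jit <- 1e-8 * max(1, max(gam))
    sol <- tryCatch(solve(a + diag(jit, n + 1), rhs),
                    error = function(e) abort("singular kriging matrix."))
  }
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  kvar <- colSums(lambda * t(g0)) + mu
  list(weights = lambda, mu = mu, variance = pmax(kvar, 0))
}

#' Ordinary-kriging weights at a single target
#'
#' Exposes the solved kriging system (weights, Lagrange multiplier, kriging
#' variance) for inspection and testing.
#'
#' @param obs_coords Matrix of observation coordinates (two columns).
#' @param vgm A `variogram_model`.
#' @param target Numeric length-2 target location.
#' @return List with `weights` (summing to 1), `mu`, `variance`.
#' @export
ok_weights <- function(obs_coords, vgm, target) {
  sol <- ok_solve(as.matrix(obs_coords), vgm,
                  matrix(target, ncol = 2))
  list(weights = drop(sol$weights), mu = unname(sol$mu),
       variance = unname(sol$variance))
}

#' Ordinary kriging of log concentrations over a grid
#'
#' Solves the ordinary-kriging system per grid cell on the log scale (all
#' observations in one global neighbourhood up to 500 sites, otherwise the
#' nearest 64 per cell), then back-transforms point predictions by
#' exponentiation. The kriging standard deviation is reported on the log
#' scale and propagated to the concentration scale by the delta method
#' (`y_hat * sd_log`). No lognormal bias correction is applied: the
#' back-transformed surface is the median-type map, which slightly
#' underestimates the mean.
#'
#' @param obs Site table with `x`, `y` and the response column.
#' @param vgm A `variogram_model` (fitted with [fit_variogram()]).
#' @param grid Table of target cells with `x`, `y`.
#' @param response Response column name.
#' @param max_global Largest observation count solved as one global system.
#' @return A tibble of class `ok_prediction`: `x`, `y`, `pred_log`,
#'   `sd_log`, `y_hat`, `sd_y`.
#' @export
ok_predict <- function(obs, vgm, grid, response = "cd", max_global = 500) {
  if (nrow(grid) == 0) abort("`grid` is empty.")
  z <- log(obs[[response]])
  oc <- cbind(obs$x, obs$y)
  tc <- cbind(grid$x, grid$y)
  n <- nrow(oc)
  if (n <= max_global) {
    sol <- ok_solve(oc, vgm, tc)
    pred <- drop(crossprod(sol$weights, z))
    kvar <- sol$variance
  } else {
    pred <- numeric(nrow(tc)); kvar <- numeric(nrow(tc))
    for (i in seq_len(nrow(tc))) {
      d <- sqrt((oc[, 1] - tc[i, 1])^2 + (oc[, 2] - tc[i, 2])^2)
      nb <- order(d)[seq_len(64)]
      s <- ok_solve(oc[nb, , drop = FALSE], vgm, tc[i, , drop = FALSE])
      pred[i] <- sum(s$weights * z[nb])
      kvar[i] <- s$variance
    }
  }
  sd_log <- sqrt(kvar)
  y_hat <- exp(pred)
  out <- tibble::tibble(
    x = grid$x, y = grid$y,
    pred_log = pred, sd_log = sd_log,
    y_hat = y_hat, sd_y = y_hat * sd_log
  )
  class(out) <- c("ok_prediction", class(out))
  out
}
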