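# Latent spatial fields for the synthetic-data generator.
#
# Each covariate family is driven by one smooth latent Gaussian field plus a
# radius-specific jitter field. Fields are random-Fourier-feature surrogates
# of a Gaussian-covariance process: f(x) = sqrt(2/K) * sum_k cos(w_k'x + phi_k)
# with w_k ~ N(0, I / ell^2). Given the seed, f is a deterministic function of
# location, so sites and grid cells sample literally the same surface and a
# grid cell coincident with a site reproduces the site's covariate exactly.

rff_field <- function(seed, stream, corr_length, n_features = 256L) {
  with_substream(seed, stream, {
    k <- n_features
    list(
      w = matrix(rnorm(2L * k, sd = 1 / corr_length), ncol = 2L),
      phi = runif(k, 0, 2 * pi),
      k = k
    )
  })
}

eval_field <- function(field, x, y) {
  proj <- cbind(x, y) %*% t(field$w)
  sqrt(2 / field$k) * rowSums(cos(sweep(proj, 2L, field$phi, "+")))
}

# Build all field definitions for a config. Jitter amplitude lambda is chosen
# so that corr(L + lambda*J_a, L + lambda*J_b) = 1/(1+lambda^2) comfortably
# exceeds the configured Spearman target.
make_latent_fields <- function(config) {
  spec <- config$covariate_spec
  cols <- expand_covariates(spec)
  fields <- list()
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    fields[[nm]] <- list(
      base = rff_field(config$seed, paste0("field:", nm), spec$corr_length[i])
    )
    r <- spec$radii[[i]]
    if (!all(is.na(r))) {
      rho <- spec$rho_target[i]
      lambda <- 0.7 * sqrt((1 - rho) / rho)
      fields[[nm]]$lambda <- lambda
      fields[[nm]]$jitter <- lapply(r, function(rr) {
        rff_field(config$seed, paste0("jitter:", nm, ":", rr),
                  corr_length = 5e3)
      })
      names(fields[[nm]]$jitter) <- as.character(r)
    }
  }
  attr(fields, "columns") <- cols
  fields
}

# Evaluate every covariate column at the given coordinates on its native
# scale, before zero inflation. Returns a tibble of covariate columns.
eval_covariates <- function(fields, config, x, y) {
  spec <- config$covariate_spec
  out <- list()
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    f <- fields[[nm]]
    base_z <- eval_field(f$base, x, y)
    r <- spec$radii[[i]]
    if (all(is.na(r))) {
      out[[nm]] <- transform_latent(base_z, spec$type[i],
                                    spec$meanlog[i], spec$sdlog[i])
    } else {
      for (rr in r) {
        z <- (base_z + f$lambda * eval_field(f$jitter[[as.character(rr)]], x, y)) /
          sqrt(1 + f$lambda^2)
        out[[paste0(nm, "_", rr)]] <-
          transform_latent(z, spec$type[i], spec$meanlog[i], spec$sdlog[i])
      }
    }
  }
  tibble::as_tibble(out)
}

transform_latent <- function(z, type, meanlog, sdlog) {
  switch(type,
    percent = 100 * pnorm(z),
    altitude = 450 * exp(0.6 * z),
    positive = exp(meanlog + sdlog * z),
    abort(sprintf("unknown covariate type '%s'", type))
  )
}

# Spatially coherent zero inflation: within each zone, the rows with the
# lowest latent (equivalently transformed, the map is monotone) values of a
# family are set to exactly zero, in the configured proportion.
apply_zero_inflation <- function(covariates, config, zone) {
  spec <- config$covariate_spec
  for (i in seq_len(nrow(spec))) {
    p <- spec$zero_prop[i]
    if (is.na(p) || p <= 0) next
    r <- spec$radii[[i]]
    cols <- if (all(is.na(r))) spec$name[i] else paste0(spec$name[i], "_", r)
    for (zn in unique(zone)) {
      idx <- which(zone == zn)
      k <- round(p * length(idx))
      if (k < 1) next
      # rank on the family's base member so zeros are consistent across radii
      ranks <- rank(covariates[[cols[1]]][idx], ties.method = "first")
      zero_rows <- idx[ranks <= k]
      for (cl in cols) covariates[[cl]][zero_rows] <- 0
    }
  }
  covariates
}
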