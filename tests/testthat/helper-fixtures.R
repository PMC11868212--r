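# Small fixtures shared across test files, built in code.

tiny_config <- function(n = 60, seed = 11, sigma = 0.3, ...) {
  study_config(n_sites = n, seed = seed, sigma = sigma, ...)
}

# A minimal site table with hand-set columns for filter/fit unit tests.
toy_sites <- function(n = 20, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = paste0("T", seq_len(n)),
      x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
      zone = rep(c("Atlantic", "Continental"), length.out = n),
      moss_species = rep(c("Hc", "Pp"), length.out = n),
      tree_cover = rep(c("deciduous", "coniferous"), length.out = n),
      A = rnorm(n), B = rnorm(n), C = rnorm(n),
      cd = runif(n, 0.05, 1.4)
    )
  })
}

# Brute-force Spearman: rank then Pearson.
spearman_oracle <- function(a, b) {
  cor(rank(a), rank(b))
}

# Brute-force Moran's I by explicit double summation.
moran_oracle <- function(v, w) {
  m <- length(v)
  vb <- mean(v)
  num <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    num <- num + w[i, j] * (v[i] - vb) * (v[j] - vb)
  }
  (m / sum(w)) * num / sum((v - vb)^2)
}

# generate sites without the (expected) overfitting warning for small n
quiet_sites <- function(cfg) suppressWarnings(generate_sites(cfg))
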