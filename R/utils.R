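#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats AIC coef complete.cases cor dist logLik lm median
#'   model.matrix optim pnorm predict pt qnorm quantile rnorm runif sd setNames
#'   terms var vcov as.formula dnorm
#' @importFrom utils head
NULL

# Derive a reproducible substream seed from a master seed and a stream label.
# Keeps results < 2^31 so they remain valid R integer seeds.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 69069 + h * 2654435761) %% 2147483629) + 1L
}

with_substream <- function(seed, stream, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

#' Root-mean-square error
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A single non-negative number, `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((observed - predicted)^2))
}

# Columns that are never treated as quantitative covariates.
.reserved_cols <- c("id", "x", "y", "zone", "moss_species", "tree_cover", "cd")

covariate_columns <- function(sites) {
  setdiff(names(sites)[vapply(sites, is.numeric, logical(1))],
          .reserved_cols)
}

# Split a buffered covariate name into its family base and radius.
# "Forest_5" -> list(base = "Forest", radius = 5); unbuffered names get NA.
parse_covariate_name <- function(x) {
  m <- regmatches(x, regexec("^(.*)_([0-9]+(?:\\.[0-9]+)?)$", x))
  base <- vapply(seq_along(x), function(i) {
    if (length(m[[i]]) == 3) m[[i]][2] else x[i]
  }, character(1))
  radius <- vapply(seq_along(x), function(i) {
    if (length(m[[i]]) == 3) as.numeric(m[[i]][3]) else NA_real_
  }, numeric(1))
  tibble::tibble(variable = x, family = base, radius = radius)
}
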