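#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Sample skewness (moment estimator)
#' @keywords internal
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

## Derive a small set of stage seeds from one master seed, all < 2^31.
## Used so that e.g. panel generation and missingness imposition consume
## independent, reproducible streams within a replication.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

## Standardize the continuous baseline covariate for use in linear
## predictors. Any affine transform is equivalent for the fitted models;
## standardizing keeps coefficients on comparable scales.
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
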