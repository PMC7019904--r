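#' Box-Cox transformation and its inverse
#'
#' `boxcox_transform()` maps positive intakes to an approximately
#' Gaussian scale, `(x^lambda - 1) / lambda`; `boxcox_inverse()` maps
#' back, clamping at zero where the inverse is undefined (an argument
#' below `-1/lambda` corresponds to a negative intake, which cannot
#' occur).
#'
#' @param x Positive amounts.
#' @param z Transformed values.
#' @param lambda Exponent in (0, 1].
#' @return Transformed (or back-transformed) numeric vector.
#' @export
boxcox_transform <- function(x, lambda) {
  stopifnot(lambda > 0)
  (x^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
boxcox_inverse <- function(z, lambda) {
  stopifnot(lambda > 0)
  pmax(lambda * z + 1, 0)^(1 / lambda)
}

#' Select a Box-Cox exponent by profile likelihood on a grid
#'
#' Grid-searches lambda over (0, 1] maximizing the Gaussian profile
#' log-likelihood of the transformed amounts,
#' `-n/2 log(sigma^2(lambda)) + (lambda - 1) sum(log x)` — the Jacobian
#' term makes the criterion scale-invariant, so the selected lambda does
#' not depend on the unit the nutrient is recorded in. Deterministic
#' given the data.
#'
#' @param x Positive daily amounts (zeros must be offset beforehand).
#' @param grid Candidate exponents; default `seq(0.01, 1, by = 0.01)`.
#' @return The maximizing lambda (ties broken toward the smaller value).
#' @export
fit_boxcox_lambda <- function(x, grid = seq(0.01, 1, by = 0.01)) {
  x <- x[is.finite(x)]
  if (!length(x) || all(x == 0)) {
    stop("cannot select a Box-Cox exponent from all-zero intakes",
      call. = FALSE
    )
  }
  if (any(x <= 0)) {
    stop("amounts must be positive; apply a zero offset first", call. = FALSE)
  }
  n <- length(x)
  slog <- sum(log(x))
  ll <- vapply(grid, function(lam) {
    z <- boxcox_transform(x, lam)
    v <- stats::var(z) * (n - 1) / n
    if (!is.finite(v) || v <= 0) {
      return(-Inf)
    }
    -n / 2 * log(v) + (lam - 1) * slog
  }, numeric(1))
  grid[which.max(ll)]
}
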