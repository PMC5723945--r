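#' Truncated Gaussian kernel
#'
#' Isotropic Gaussian weights on a `(2*radius + 1)` square grid, set to zero
#' at Euclidean distance `>= radius` from the centre and normalized to sum
#' to one. This is the neighbourhood weighting of the local Gaussian fitting
#' energy; the same radius bounds the local-entropy window.
#'
#' @param sigma kernel standard deviation in pixels (> 0).
#' @param radius truncation radius in pixels (>= 1).
#' @return object of class `"lgdf_kernel"`: list with `weights` (matrix
#'   summing to 1), `sigma`, `radius`.
#' @examples
#' k <- make_kernel(3, 12)
#' sum(k$weights)
#' @export
make_kernel <- function(sigma, radius) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  radius <- as.integer(radius)
  if (radius < 1) stop("'radius' must be >= 1", call. = FALSE)
  d2 <- outer((-radius:radius)^2, (-radius:radius)^2, "+")
  w <- exp(-d2 / (2 * sigma^2))
  w[sqrt(d2) >= radius] <- 0
  structure(list(weights = w / sum(w), sigma = sigma, radius = radius),
            class = "lgdf_kernel")
}

#' Smoothed Heaviside and Dirac functions
#'
#' The arctangent regularization of the step function,
#' `H_eps(x) = 1/2 * (1 + (2/pi) * atan(x / eps))`, and its derivative
#' `delta_eps(x) = (1/pi) * eps / (eps^2 + x^2)`. `H_eps` converts the sign
#' of the level set function into soft class memberships
#' `M1 = H_eps(phi)`, `M2 = 1 - M1`; `delta_eps` concentrates the contour
#' forces near the zero level set while remaining nonzero everywhere, which
#' lets new contours emerge away from the initialization.
#'
#' @param x numeric scalar, vector or matrix.
#' @param epsilon smoothing width (> 0).
#' @return values in `(0, 1)` for `heaviside`; values in
#'   `(0, 1/(pi * epsilon)]` for `dirac`.
#' @examples
#' heaviside(0, 1)   # 0.5
#' dirac(0, 1)       # 1/pi
#' @export
heaviside <- function(x, epsilon) {
  stopifnot(epsilon > 0)
  0.5 * (1 + (2 / pi) * atan(x / epsilon))
}

#' @rdname heaviside
#' @export
dirac <- function(x, epsilon) {
  stopifnot(epsilon > 0)
  (1 / pi) * epsilon / (epsilon^2 + x^2)
}
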