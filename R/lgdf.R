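# Core of the entropy-weighted local Gaussian distribution fitting (LGDF)
# energy. The data term is
#
#   E_data = sum_i lambda_i sum_x E_r(x) sum_y K(x-y)
#            [ log(sqrt(2 pi) sigma_i) + (I(y) - b(x) c_i)^2 / (2 sigma_i^2) ]
#            M_i(phi(y))
#
# with M1 = H_eps(phi), M2 = 1 - M1, b the multiplicative bias field and
# (c_i, sigma_i^2) scalar per-class Gaussian parameters. All inner sums are
# evaluated with zero-padded convolutions; the closed-form updates below are
# the exact coordinate minimizers of E_data, so alternating them can never
# increase the data term.

state_check <- function(image, state) {
  stopifnot(is.list(state))
  for (f in c("phi", "bias")) {
    if (!all(dim(state[[f]]) == dim(image)))
      stop(sprintf("state$%s shape differs from image", f), call. = FALSE)
  }
  if (any(state$sigma_sq <= 0)) stop("class variances must be positive", call. = FALSE)
  if (any(state$bias <= 0)) stop("bias field must be strictly positive", call. = FALSE)
  invisible(state)
}

memberships <- function(phi, epsilon) {
  m1 <- heaviside(phi, epsilon)
  list(m1 = m1, m2 = 1 - m1)
}

#' Per-class force maps of the gradient flow
#'
#' Evaluates, for each class `i`, the entropy-weighted neighbourhood
#' negative log-likelihood potential
#' `e_i(x) = E_r(x) * sum_y K(x-y) [ log(sqrt(2 pi) sigma_i) +
#' (I(y) - b(x) c_i)^2 / (2 sigma_i^2) ]`, expanded through the three
#' convolutions `K*1`, `K*I`, `K*I^2` so that border pixels use the clipped
#' kernel mass. `e1 - e2` is the data force driving the level set: where
#' class 1 explains the local intensities worse than class 2, the level set
#' function is pushed down and the pixel migrates to class 2.
#'
#' @param image non-negative numeric matrix.
#' @param entropy local entropy map from [local_entropy()], same shape.
#' @param state list with `phi`, `c` (length 2), `sigma_sq` (length 2),
#'   `bias` -- see [segment()].
#' @param kernel kernel from [make_kernel()].
#' @param params parameters from [model_params()].
#' @return list with matrices `e1`, `e2`.
#' @export
compute_force_maps <- function(image, entropy, state, kernel, params) {
  assert_image(image)
  state_check(image, state)
  K <- kernel$weights
  K1 <- conv2_same(matrix(1, nrow(image), ncol(image)), K)
  KI <- conv2_same(image, K)
  KI2 <- conv2_same(image^2, K)
  b <- state$bias
  e <- lapply(1:2, function(i) {
    s <- state$sigma_sq[i]; ci <- state$c[i]
    entropy * (K1 * (0.5 * log(2 * pi * s) + b^2 * ci^2 / (2 * s)) -
                 b * ci * KI / s + KI2 / (2 * s))
  })
  list(e1 = e[[1]], e2 = e[[2]])
}

#' Closed-form update of the class means
#'
#' Exact minimizer of the data term with respect to the scalar class means:
#' `c_i = sum_x E_r(x) b(x) (K * (I M_i))(x) / sum_x E_r(x) b(x)^2 (K * M_i)(x)`.
#' The bias field enters only through the product `b * c_i`, so the means
#' are identified on the bias-corrected intensity scale.
#'
#' @inheritParams compute_force_maps
#' @param bias current bias field (strictly positive matrix).
#' @param phi current level set function.
#' @param c_prev previous means, returned (with a warning) for a class whose
#'   membership mass vanishes.
#' @return numeric vector `c(c1, c2)`.
#' @export
update_c <- function(image, entropy, bias, phi, kernel, params,
                     c_prev = c(NA_real_, NA_real_)) {
  K <- kernel$weights
  m <- memberships(phi, params$epsilon)
  out <- numeric(2)
  for (i in 1:2) {
    mi <- if (i == 1) m$m1 else m$m2
    num <- sum(entropy * bias * conv2_same(image * mi, K))
    den <- sum(entropy * bias^2 * conv2_same(mi, K))
    if (den <= .Machine$double.eps * sum(bias^2)) {
      if (is.na(c_prev[i]))
        stop(sprintf("class %d has no membership mass and no previous mean", i),
             call. = FALSE)
      warning(sprintf("class %d empty; keeping previous mean", i), call. = FALSE)
      out[i] <- c_prev[i]
    } else out[i] <- num / den
  }
  out
}

#' Closed-form update of the bias field
#'
#' Pointwise exact minimizer of the data term in `b`:
#' `b(x) = K * (I * sum_i lambda_i M_i c_i / sigma_i^2) /
#'         K * (sum_i lambda_i M_i c_i^2 / sigma_i^2)`,
#' the stationarity condition of the energy at each pixel (the entropy
#' weight cancels). The result is floored at `params$bias_floor` so the
#' corrected image `I / b` stays finite.
#'
#' @inheritParams update_c
#' @param c current class means (length 2).
#' @param sigma_sq current class variances (length 2, positive).
#' @return positive matrix, same shape as `image`.
#' @export
update_bias <- function(image, phi, c, sigma_sq, kernel, params) {
  if (all(c == 0)) stop("both class means are zero: bias model degenerate", call. = FALSE)
  K <- kernel$weights
  m <- memberships(phi, params$epsilon)
  lam <- c(params$lambda1, params$lambda2)
  wnum <- lam[1] * m$m1 * c[1] / sigma_sq[1] + lam[2] * m$m2 * c[2] / sigma_sq[2]
  wden <- lam[1] * m$m1 * c[1]^2 / sigma_sq[1] + lam[2] * m$m2 * c[2]^2 / sigma_sq[2]
  num <- conv2_same(image * wnum, K)
  den <- conv2_same(wden, K)
  if (all(abs(den) <= .Machine$double.eps))
    stop("bias denominator vanishes everywhere: model degenerate", call. = FALSE)
  pmax(num / pmax(den, .Machine$double.eps), params$bias_floor)
}

#' Closed-form update of the class variances
#'
#' Exact minimizer of the data term in each scalar variance:
#' `sigma_i^2 = sum_x E_r(x) sum_y K(x-y) (I(y) - c_i b(x))^2 M_i(phi(y)) /
#'              sum_x E_r(x) (K * M_i)(x)`,
#' expanded through the convolutions of `M_i`, `I M_i` and `I^2 M_i`. Floored
#' at `params$sigma_floor_frac` times the squared intensity range so a
#' perfectly fit class cannot collapse the likelihood.
#'
#' @inheritParams update_bias
#' @param entropy local entropy map.
#' @param bias current bias field.
#' @param sigma_prev previous variances, retained (with a warning) for a
#'   class with vanishing membership mass.
#' @return numeric vector `c(sigma1_sq, sigma2_sq)`, strictly positive.
#' @export
update_sigma <- function(image, entropy, bias, phi, c, kernel, params,
                         sigma_prev = c(NA_real_, NA_real_)) {
  K <- kernel$weights
  m <- memberships(phi, params$epsilon)
  floor_val <- params$sigma_floor_frac * max(diff(range(image)), 1)^2
  out <- numeric(2)
  for (i in 1:2) {
    mi <- if (i == 1) m$m1 else m$m2
    KM <- conv2_same(mi, K)
    KIM <- conv2_same(image * mi, K)
    KI2M <- conv2_same(image^2 * mi, K)
    num <- sum(entropy * (KI2M - 2 * c[i] * bias * KIM + c[i]^2 * bias^2 * KM))
    den <- sum(entropy * KM)
    if (den <= .Machine$double.eps) {
      if (is.na(sigma_prev[i]))
        stop(sprintf("class %d has no membership mass and no previous variance", i),
             call. = FALSE)
      warning(sprintf("class %d empty; keeping previous variance", i), call. = FALSE)
      out[i] <- sigma_prev[i]
    } else out[i] <- max(num / den, floor_val)
  }
  out
}

#' Total energy of the current state
#'
#' Sum of the entropy-weighted LGDF data term, the contour-length penalty
#' `nu * sum |grad H_eps(phi)|` and the distance-regularization penalty
#' `mu * sum (|grad phi| - 1)^2 / 2`. Gradients use central differences with
#' replicated borders. The alternating driver monitors this value for its
#' stopping rule.
#'
#' @inheritParams compute_force_maps
#' @param parts if `TRUE`, return a list with components `data`, `length`,
#'   `reg`, `total` instead of the scalar total.
#' @return scalar energy, or a list when `parts = TRUE`.
#' @export
total_energy <- function(image, entropy, state, kernel, params, parts = FALSE) {
  assert_image(image)
  state_check(image, state)
  K <- kernel$weights
  m <- memberships(state$phi, params$epsilon)
  lam <- c(params$lambda1, params$lambda2)
  b <- state$bias
  e_data <- 0
  for (i in 1:2) {
    mi <- if (i == 1) m$m1 else m$m2
    s <- state$sigma_sq[i]; ci <- state$c[i]
    KM <- conv2_same(mi, K)
    KIM <- conv2_same(image * mi, K)
    KI2M <- conv2_same(image^2 * mi, K)
    e_data <- e_data + lam[i] * sum(entropy *
      (0.5 * log(2 * pi * s) * KM +
         (KI2M - 2 * b * ci * KIM + b^2 * ci^2 * KM) / (2 * s)))
  }
  gH <- grad_central(heaviside(state$phi, params$epsilon))
  e_len <- sum(sqrt(gH$gx^2 + gH$gy^2))
  g <- grad_central(state$phi)
  e_reg <- 0.5 * sum((sqrt(g$gx^2 + g$gy^2) - 1)^2)
  if (parts)
    list(data = e_data, length = params$nu * e_len, reg = params$mu * e_reg,
         total = e_data + params$nu * e_len + params$mu * e_reg)
  else e_data + params$nu * e_len + params$mu * e_reg
}
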