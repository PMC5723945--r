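#' Model parameters for entropy-weighted LGDF segmentation
#'
#' Collects every tunable of the method with validated defaults. Intensities
#' are assumed on a 0--255 scale (images loaded through [read_image()] are
#' mapped there), which fixes the units of `nu` and the variance floor.
#'
#' @param lambda1,lambda2 positive weights of the two class data terms
#'   (dimensionless). Default 1 for both.
#' @param nu weight of the contour-length penalty, in intensity^2 x pixel
#'   units. Expressed by convention as a fraction of 255^2; default
#'   `0.003 * 255^2`.
#' @param mu weight of the distance-regularization penalty keeping the level
#'   set function close to a signed distance function. Default 1.
#' @param epsilon width of the smoothed Heaviside/Dirac pair, in level-set
#'   units. Default 1.
#' @param dt explicit time step of the gradient-flow update. Default 0.1.
#' @param kernel_sigma standard deviation (pixels) of the truncated Gaussian
#'   kernel defining the local neighbourhoods. Default 3.
#' @param radius_r truncation radius of the kernel and the local-entropy
#'   window (pixels). Default `ceiling(4 * kernel_sigma)`, where the
#'   Gaussian tail is negligible.
#' @param c0 magnitude of the binary-step level set initialization. Default 2.
#' @param max_iters maximum number of alternating-minimization iterations.
#' @param tol energy-change tolerance of the stopping rule
#'   `|F_n - F_{n+1}| < tol * |F_n|` (relative mode) or
#'   `|F_n - F_{n+1}| < tol` (absolute mode).
#' @param tol_mode `"relative"` (default) or `"absolute"`. The absolute form
#'   is scale-dependent (energies grow with image area) but retained for
#'   fidelity to the original stopping rule.
#' @param entropy_offset intensity offset added before computing the local
#'   entropy weights, see [local_entropy()]. Default 1.
#' @param entropy_window `"square"` or `"disk"` local-entropy window.
#' @param sigma_floor_frac floor on the class variances, as a fraction of the
#'   squared intensity range. Default 1e-6.
#' @param bias_floor floor on the estimated bias field. Default 1e-3.
#' @param grad_stab stabilizer added under the square root in `|grad phi|`
#'   when normalizing the gradient. Default 1e-10.
#' @param seed optional integer seed recorded with the run (used by the CLI
#'   for phantom generation; the deterministic solver itself draws no random
#'   numbers).
#'
#' @return an object of class `"model_params"` (a validated list).
#' @examples
#' p <- model_params(kernel_sigma = 2)
#' p$radius_r
#' @export
model_params <- function(lambda1 = 1, lambda2 = 1,
                         nu = 0.003 * 255^2, mu = 1,
                         epsilon = 1, dt = 0.1,
                         kernel_sigma = 3,
                         radius_r = ceiling(4 * kernel_sigma),
                         c0 = 2,
                         max_iters = 500L, tol = 1e-3,
                         tol_mode = c("relative", "absolute"),
                         entropy_offset = 1,
                         entropy_window = c("square", "disk"),
                         sigma_floor_frac = 1e-6,
                         bias_floor = 1e-3,
                         grad_stab = 1e-10,
                         seed = NULL) {
  tol_mode <- match.arg(tol_mode)
  entropy_window <- match.arg(entropy_window)
  p <- list(lambda1 = lambda1, lambda2 = lambda2, nu = nu, mu = mu,
            epsilon = epsilon, dt = dt, kernel_sigma = kernel_sigma,
            radius_r = as.integer(radius_r), c0 = c0,
            max_iters = as.integer(max_iters), tol = tol,
            tol_mode = tol_mode, entropy_offset = entropy_offset,
            entropy_window = entropy_window,
            sigma_floor_frac = sigma_floor_frac, bias_floor = bias_floor,
            grad_stab = grad_stab, seed = seed)
  for (f in c("lambda1", "lambda2", "mu", "epsilon", "dt", "kernel_sigma",
              "c0", "tol", "sigma_floor_frac", "bias_floor", "grad_stab")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", f),
           call. = FALSE)
  }
  if (!is.numeric(nu) || nu < 0) stop("'nu' must be non-negative", call. = FALSE)
  if (p$radius_r < 1) stop("'radius_r' must be >= 1", call. = FALSE)
  if (p$max_iters < 0) stop("'max_iters' must be >= 0", call. = FALSE)
  if (entropy_offset < 0) stop("'entropy_offset' must be >= 0", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("entropy-weighted LGDF model parameters\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) cat(sprintf("  %-18s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}
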