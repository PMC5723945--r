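# Phantom generator: piecewise-constant shapes times a smooth multiplicative
# bias field plus additive Gaussian noise, i.e. the observed-image model
# I = b * J + n with known ground truth for every factor.

#' Piecewise-constant test shapes
#'
#' Renders a two-valued image (`fg_value` on the object, `bg_value`
#' elsewhere) together with its binary ground-truth mask.
#'
#' @param shape_kind `"disk"`, `"star"` (n-pointed polygon), `"two_objects"`
#'   (a disk and a square), or `"cross"`.
#' @param size canvas side in pixels (square canvas).
#' @param fg_value,bg_value object and background intensities; must differ.
#' @param radius object radius in pixels (disk and star outer radius);
#'   default `size / 4`.
#' @param n_points number of star points (star only).
#' @param inner_ratio star inner/outer radius ratio (star only).
#' @return list with `true_image` (numeric matrix) and `mask` (logical).
#' @examples
#' sh <- make_shape("disk", 64, radius = 16)
#' sum(sh$mask)
#' @export
make_shape <- function(shape_kind = c("disk", "star", "two_objects", "cross"),
                       size = 64, fg_value = 120, bg_value = 40,
                       radius = size / 4, n_points = 5, inner_ratio = 0.5) {
  shape_kind <- match.arg(shape_kind)
  if (fg_value == bg_value)
    stop("'fg_value' and 'bg_value' must differ", call. = FALSE)
  if (size < 8) stop("canvas too small", call. = FALSE)
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  if (shape_kind %in% c("disk", "star") && radius > size / 2 - 1)
    stop("shape exceeds canvas", call. = FALSE)
  mask <- switch(shape_kind,
    disk = (rows - ctr)^2 + (cols - ctr)^2 <= radius^2,
    star = {
      ang <- pi / 2 + 2 * pi * seq(0, 2 * n_points - 1) / (2 * n_points)
      rad <- rep(c(radius, radius * inner_ratio), n_points)
      bnd <- cbind(ctr + rad * cos(ang), ctr - rad * sin(ang))
      pts <- cbind(as.vector(cols), as.vector(rows))
      matrix(mgcv::in.out(bnd, pts), size, size)
    },
    two_objects = {
      r1 <- max(3, round(size / 6))
      half <- max(2, round(size / 8))
      c1 <- c(0.3 * size, 0.3 * size); c2 <- c(0.7 * size, 0.7 * size)
      ((rows - c1[1])^2 + (cols - c1[2])^2 <= r1^2) |
        (abs(rows - c2[1]) <= half & abs(cols - c2[2]) <= half)
    },
    cross = {
      arm <- max(2, round(size / 10)); ext <- max(4, round(size / 3))
      (abs(rows - ctr) <= arm & abs(cols - ctr) <= ext) |
        (abs(cols - ctr) <= arm & abs(rows - ctr) <= ext)
    })
  if (!any(mask) || all(mask)) stop("degenerate shape", call. = FALSE)
  list(true_image = ifelse(mask, fg_value, bg_value) * 1.0, mask = mask)
}

#' Smooth multiplicative bias fields
#'
#' Generates a strictly positive smooth field spanning roughly
#' `[1 - amplitude, 1 + amplitude]`, renormalized to mean exactly 1 so the
#' overall intensity scale of the phantom is preserved.
#'
#' @param size canvas side in pixels.
#' @param kind `"linear_ramp"` (left-to-right), `"gaussian_bump"` (bright
#'   centre), or `"sinusoid"` (smooth product of sines).
#' @param amplitude fraction in `[0, 1)`; 0 gives a flat field of ones.
#' @return positive numeric matrix with mean 1 (to 1e-12).
#' @export
make_bias <- function(size, kind = c("linear_ramp", "gaussian_bump", "sinusoid"),
                      amplitude = 0.3) {
  kind <- match.arg(kind)
  if (amplitude < 0 || amplitude >= 1)
    stop("'amplitude' must be in [0, 1)", call. = FALSE)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  b <- switch(kind,
    linear_ramp = 1 + amplitude * (2 * (cols - 1) / (size - 1) - 1),
    gaussian_bump = {
      ctr <- (size + 1) / 2
      g <- exp(-((rows - ctr)^2 + (cols - ctr)^2) / (2 * (size / 4)^2))
      (1 - amplitude) + 2 * amplitude * g
    },
    sinusoid = 1 + amplitude * sin(2 * pi * (rows - 1) / (size - 1)) *
      sin(2 * pi * (cols - 1) / (size - 1)))
  b / mean(b)
}

#' Additive Gaussian noise at a unit-scale variance level
#'
#' Adds zero-mean Gaussian noise whose variance is `noise_level` on the
#' intensity scale normalized to `[0, 1]` -- i.e. the standard deviation is
#' `sqrt(noise_level) * scale` in intensity units, the convention of common
#' image-noise utilities in which levels like 0.05 are unit-scale variances.
#'
#' @param image numeric matrix.
#' @param noise_level variance fraction (>= 0); 0 returns the input.
#' @param seed optional integer seed for reproducibility.
#' @param scale intensity scale treated as 1.0; default 255.
#' @param clip clamp the result to `[0, scale]`, mimicking 8-bit saturation.
#'   Off by default so the additive model holds exactly.
#' @return noisy image, same shape.
#' @export
add_noise <- function(image, noise_level, seed = NULL, scale = 255,
                      clip = FALSE) {
  stopifnot(is.matrix(image), noise_level >= 0, scale > 0)
  if (noise_level == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  out <- image + matrix(rnorm(length(image), sd = sqrt(noise_level) * scale),
                        nrow(image), ncol(image))
  if (clip) out <- pmin(pmax(out, 0), scale)
  out
}

#' Compose a phantom: bias times true image plus noise
#'
#' Applies the observed-image model `I = b * J + n`: the piecewise-constant
#' true image is multiplied elementwise by the bias field, then corrupted by
#' additive Gaussian noise. With `noise_level = 0` the composition is
#' exactly inverted by [bias_correct()] given the true bias.
#'
#' @param true_image numeric matrix `J`, or a list from [make_shape()]
#'   (whose mask is then carried along).
#' @param bias positive matrix with mean 1, or `NULL` for a flat field.
#' @param noise_level unit-scale noise variance, see [add_noise()].
#' @param seed optional integer seed for the noise draw.
#' @param mask optional ground-truth mask (taken from `true_image` when that
#'   is a [make_shape()] result).
#' @param scale,clip passed to [add_noise()].
#' @return object of class `"phantom"`: list with `true_image`, `mask`,
#'   `bias`, `noise_level`, `observed`, `seed`.
#' @export
compose_phantom <- function(true_image, bias = NULL, noise_level = 0,
                            seed = NULL, mask = NULL, scale = 255,
                            clip = FALSE) {
  if (is.list(true_image) && !is.null(true_image$true_image)) {
    mask <- mask %||% true_image$mask
    true_image <- true_image$true_image
  }
  stopifnot(is.matrix(true_image))
  if (is.null(bias)) bias <- matrix(1, nrow(true_image), ncol(true_image))
  if (!all(dim(bias) == dim(true_image)))
    stop("bias and true image shapes differ", call. = FALSE)
  if (any(bias <= 0)) stop("bias must be strictly positive", call. = FALSE)
  observed <- add_noise(bias * true_image, noise_level, seed = seed,
                        scale = scale, clip = clip)
  structure(list(true_image = true_image, mask = mask, bias = bias,
                 noise_level = noise_level, observed = observed, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d, noise level %g, bias range [%.3f, %.3f]\n",
              nrow(x$observed), ncol(x$observed), x$noise_level,
              min(x$bias), max(x$bias)))
  invisible(x)
}
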