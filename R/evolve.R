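# Finite-difference machinery for the level set evolution. All stencils use
# replicated (Neumann) borders and central differences; the curvature
# normalizes the gradient with a small stabilizer so flat regions of phi do
# not divide by zero.

shift_rows <- function(m, by) {
  n <- nrow(m)
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  m[idx, , drop = FALSE]
}
shift_cols <- function(m, by) {
  n <- ncol(m)
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  m[, idx, drop = FALSE]
}

grad_central <- function(m) {
  list(gx = (shift_rows(m, 1L) - shift_rows(m, -1L)) / 2,
       gy = (shift_cols(m, 1L) - shift_cols(m, -1L)) / 2)
}

laplacian5 <- function(m) {
  shift_rows(m, 1L) + shift_rows(m, -1L) +
    shift_cols(m, 1L) + shift_cols(m, -1L) - 4 * m
}

curvature <- function(phi, stab) {
  g <- grad_central(phi)
  mag <- sqrt(g$gx^2 + g$gy^2 + stab)
  nx <- g$gx / mag
  ny <- g$gy / mag
  (shift_rows(nx, 1L) - shift_rows(nx, -1L)) / 2 +
    (shift_cols(ny, 1L) - shift_cols(ny, -1L)) / 2
}

#' One explicit gradient-flow step of the level set function
#'
#' Updates `phi` by
#' `phi <- phi + dt * ( -delta_eps(phi) (lambda1 e1 - lambda2 e2)
#'                     + nu delta_eps(phi) kappa
#'                     + mu (laplacian(phi) - kappa) )`,
#' where `kappa = div(grad phi / |grad phi|)` is the curvature. The first
#' term moves the contour toward the better-fitting class, the second
#' shortens it, and the third nudges `phi` back toward a signed distance
#' function without reinitialization. Derivatives use central differences
#' with replicated borders.
#'
#' @param phi level set function (matrix).
#' @param e1,e2 force maps from [compute_force_maps()].
#' @param params parameters from [model_params()].
#' @return updated `phi`; aborts with a diagnostic if the step produces
#'   non-finite values (time step too large).
#' @export
evolve_phi <- function(phi, e1, e2, params) {
  stopifnot(all(dim(phi) == dim(e1)), all(dim(phi) == dim(e2)))
  d <- dirac(phi, params$epsilon)
  kap <- curvature(phi, params$grad_stab)
  upd <- -d * (params$lambda1 * e1 - params$lambda2 * e2) +
    params$nu * d * kap +
    params$mu * (laplacian5(phi) - kap)
  out <- phi + params$dt * upd
  if (any(!is.finite(out)))
    stop("level set update produced non-finite values; reduce 'dt'", call. = FALSE)
  out
}

#' Binary-step level set initialization
#'
#' Builds `phi0 = -c0` inside the seed region and `+c0` outside. The seed
#' region is given either as a logical matrix or as a geometric spec:
#' `list(kind = "circle", center = c(row, col), radius = r)`,
#' `list(kind = "rectangle", rows = c(r1, r2), cols = c(c1, c2))`, or
#' `list(kind = "halfplane", side = "left"|"right"|"top"|"bottom",
#' frac = 0.5)`. Note the sign convention: with the final mask taken as
#' `phi > 0`, the seeded region starts out as class 2.
#'
#' @param shape integer vector `c(nrow, ncol)` of the image.
#' @param region logical matrix or geometric spec (see Details).
#' @param c0 positive step magnitude.
#' @return matrix taking values `-c0` and `+c0`.
#' @export
initialize_phi <- function(shape, region, c0) {
  stopifnot(length(shape) == 2, all(shape >= 2), c0 > 0)
  nr <- shape[1]; nc <- shape[2]
  if (is.matrix(region)) {
    inside <- region > 0
    if (!all(dim(inside) == shape)) stop("region mask shape mismatch", call. = FALSE)
  } else {
    stopifnot(is.list(region), !is.null(region$kind))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    inside <- switch(region$kind,
      circle = {
        ctr <- region$center %||% c((nr + 1) / 2, (nc + 1) / 2)
        (rows - ctr[1])^2 + (cols - ctr[2])^2 <= region$radius^2
      },
      rectangle = rows >= region$rows[1] & rows <= region$rows[2] &
        cols >= region$cols[1] & cols <= region$cols[2],
      halfplane = {
        frac <- region$frac %||% 0.5
        switch(region$side,
               left = cols <= frac * nc, right = cols > (1 - frac) * nc,
               top = rows <= frac * nr, bottom = rows > (1 - frac) * nr,
               stop("unknown halfplane side", call. = FALSE))
      },
      stop(sprintf("unknown region kind '%s'", region$kind), call. = FALSE))
  }
  if (!any(inside) || all(inside))
    stop("initialization region is degenerate (empty or covers the image)",
         call. = FALSE)
  ifelse(inside, -c0, c0)
}
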