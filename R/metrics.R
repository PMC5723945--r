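as_binary <- function(m, arg) {
  if (is.logical(m)) return(m)
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (logical or 0/1)", arg), call. = FALSE)
  m > 0
}

check_pair <- function(s1, s2) {
  a <- as_binary(s1, "s1"); b <- as_binary(s2, "s2")
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  list(a = a, b = b)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |S1 n S2| / (|S1| + |S2|)`, the pixel-count overlap of two
#' binary masks. Two empty masks agree perfectly (1); one empty mask against
#' a non-empty one scores 0.
#'
#' @param s1,s2 binary (logical or 0/1) matrices of identical shape.
#' @return scalar in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' dsc(a, b)
#' @export
dsc <- function(s1, s2) {
  p <- check_pair(s1, s2)
  na <- sum(p$a); nb <- sum(p$b)
  if (na + nb == 0) return(1)
  2 * sum(p$a & p$b) / (na + nb)
}

#' Jaccard similarity (intersection over union)
#'
#' `JS = |S1 n S2| / |S1 u S2|`. Same empty-mask conventions as [dsc()];
#' the two metrics are linked by `DSC = 2 JS / (1 + JS)`.
#'
#' @inheritParams dsc
#' @return scalar in `[0, 1]`.
#' @export
js <- function(s1, s2) {
  p <- check_pair(s1, s2)
  u <- sum(p$a | p$b)
  if (u == 0) return(1)
  sum(p$a & p$b) / u
}
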