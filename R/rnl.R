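#' Floor non-positive cone catches
#'
#' Cone-catch values at or below zero (possible after camera conversion or
#' synthetic noise) are replaced by a small positive floor so that the
#' log-ratio RNL distances are defined. Positive values pass unchanged.
#'
#' @param x Numeric vector, matrix or array of cone catches.
#' @param floor Replacement value; defaults to 0.001.
#' @return `x` with every value `<= 0` replaced by `floor`.
#' @examples
#' floor_catches(c(-0.2, 0, 0.5))
#' @export
floor_catches <- function(x, floor = 0.001) {
  stopifnot(is.numeric(x), floor > 0)
  x[x <= 0] <- floor
  x
}

#' Chromatic receptor-noise-limited distance
#'
#' Perceptual chromatic distance in just-noticeable-difference (JND) units
#' between two cone-catch vectors under the log-linear receptor-noise-limited
#' model. For receptor channels with log-contrasts
#' \eqn{\Delta f_i = \ln(a_i/b_i)} and noise \eqn{e_i}, the squared distance
#' is the standard n-receptor form
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\prod_{k \ne i,j} e_k)^2
#'   (\Delta f_i - \Delta f_j)^2}{\sum_i (\prod_{k \ne i} e_k)^2}.}
#' The distance is symmetric, zero only when all log-contrasts are equal,
#' and invariant to a common scaling of both stimuli. By default the four
#' single-cone channels (LW, MW, SW, VS) are used.
#'
#' @param catch_a,catch_b Strictly positive cone-catch vectors (equal
#'   length, >= 2 channels), or matrices with one stimulus per row for
#'   vectorised pairwise evaluation.
#' @param viewer A [viewer_model()]. Channel noise is derived from its
#'   chromatic Weber fraction and relative abundances; when the vectors have
#'   fewer/more than 4 channels, equal noise `weber_chromatic` is used per
#'   channel.
#' @return JND distance (scalar, or vector for matrix input).
#' @examples
#' v <- viewer_model()
#' rnl_chromatic_distance(c(1, 1, 1, 1), c(1, 1, 1, 1), v)
#' @export
rnl_chromatic_distance <- function(catch_a, catch_b, viewer = viewer_model()) {
  a <- rbind(catch_a)
  b <- rbind(catch_b)
  if (is.matrix(catch_a)) a <- catch_a
  if (is.matrix(catch_b)) b <- catch_b
  if (ncol(a) != ncol(b) || nrow(a) != nrow(b))
    stop("catch_a and catch_b must have matching dimensions")
  if (ncol(a) < 2L) stop("chromatic distance needs at least 2 channels")
  if (any(a <= 0) || any(b <= 0))
    stop("non-positive cone catch: apply floor_catches() first")
  p <- ncol(a)
  e <- if (p == 4L) receptor_noise(viewer) else rep(viewer$weber_chromatic, p)
  df <- log(a / b)
  # products of noise terms excluding one / two channels
  prod_all <- prod(e)
  excl1 <- (prod_all / e)^2          # (prod_{k != i} e_k)^2
  den <- sum(excl1)
  num <- 0
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      w <- (prod_all / (e[i] * e[j]))^2
      num <- num + w * (df[, i] - df[, j])^2
    }
  }
  unname(sqrt(num / den))
}

#' Luminance receptor-noise-limited distance
#'
#' Achromatic JND distance carried by the double cone:
#' `|ln(ld_a / ld_b)| / weber_luminance`.
#'
#' @param ld_a,ld_b Strictly positive double-cone catches (vectorised).
#' @param viewer A [viewer_model()].
#' @return JND distance, same length as the inputs.
#' @examples
#' rnl_luminance_distance(exp(0.05), 1, viewer_model())  # 1 JND
#' @export
rnl_luminance_distance <- function(ld_a, ld_b, viewer = viewer_model()) {
  if (any(ld_a <= 0) || any(ld_b <= 0))
    stop("non-positive luminance catch: apply floor_catches() first")
  abs(log(ld_a / ld_b)) / viewer$weber_luminance
}
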