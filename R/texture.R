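# Local texture-difference measures between a current and a reference frame,
# built on the level-J wavelet detail planes. The detail pair (W1, W2) acts
# as a gradient vector per pixel; comparing gradient geometry rather than
# raw intensities makes the measures robust to illumination changes.

.check_pyr_pair <- function(pyr1, pyr2, level) {
  if (!inherits(pyr1, "wavelet_pyramid") || !inherits(pyr2, "wavelet_pyramid"))
    stop("inputs must be wavelet_pyramid objects")
  if (level < 1L || level > pyr1$levels || level > pyr2$levels)
    stop(sprintf("'level' must be in 1..%d", min(pyr1$levels, pyr2$levels)))
  .check_same_shape(pyr1$coarse, pyr2$coarse, "pyramids")
  invisible(TRUE)
}

#' Level-J gradient planes of a wavelet pyramid
#'
#' Returns the detail pair `(W1, W2)` at `level` — the per-pixel gradient
#' vector used by the texture measures. `W1` responds to variation along x
#' (columns), `W2` along y (rows).
#'
#' @param pyramid a [dwt_decompose()] pyramid.
#' @param level level index (default: coarsest).
#' @return `list(W1, W2)` of matrices.
#' @export
gradient_planes <- function(pyramid, level = pyramid$levels) {
  level <- as.integer(level)
  if (level < 1L || level > pyramid$levels)
    stop(sprintf("'level' must be in 1..%d", pyramid$levels))
  pyramid$details[[level]]
}

#' Modulus-magnitude difference (MMD) between two frames
#'
#' `MMD(p) = | M_J f1(p) - M_J f2(p) |`, the absolute difference of the
#' wavelet moduli — large where the local gradient strength changed.
#'
#' @param pyr1,pyr2 pyramids of the two frames (same size and depth).
#' @param level detail level (default: coarsest).
#' @return non-negative matrix; symmetric in its arguments.
#' @export
mmd_map <- function(pyr1, pyr2, level = pyr1$levels) {
  level <- as.integer(level)
  .check_pyr_pair(pyr1, pyr2, level)
  abs(wavelet_modulus(pyr1, level) - wavelet_modulus(pyr2, level))
}

#' Texture-difference rate (TDR) between two frames
#'
#' Per pixel `p`, with the 3x3 neighbourhood `N_p` (mirror-padded at the
#' borders):
#' \deqn{TDR(p) = 1 - 2 \sum_{q \in N_p} CC(q) /
#'       \sum_{q \in N_p} (M_1^2(q) + M_2^2(q))}
#' where `CC = W1_1 W1_2 + W2_1 W2_2` is the dot product of the two gradient
#' vectors and `M_i` their moduli. TDR lies in `[0, 2]`: about 0 where the
#' local texture is unchanged, up to 2 where the gradients oppose. Pixels
#' whose whole neighbourhood is textureless in both frames (zero
#' denominator) are defined as unchanged (`TDR = 0`).
#'
#' @inheritParams mmd_map
#' @return matrix with values in `[0, 2]`.
#' @export
tdr_map <- function(pyr1, pyr2, level = pyr1$levels) {
  level <- as.integer(level)
  .check_pyr_pair(pyr1, pyr2, level)
  d1 <- pyr1$details[[level]]; d2 <- pyr2$details[[level]]
  cc <- d1$W1 * d2$W1 + d1$W2 * d2$W2
  mm <- d1$W1^2 + d1$W2^2 + d2$W1^2 + d2$W2^2
  num <- .box3(cc)
  den <- .box3(mm)
  tdr <- ifelse(den > 0, 1 - 2 * num / den, 0)
  # the bound 0 <= TDR <= 2 holds in exact arithmetic (2|CC| <= M1^2 + M2^2);
  # clamp rounding residue
  pmin(pmax(tdr, 0), 2)
}
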