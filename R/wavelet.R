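# Undecimated dyadic wavelet transform (analysis + exact synthesis) with a
# zero-phase spline filter bank.
#
# Analysis filters (frequency responses on [-pi, pi]):
#   H(w) = cos^4(w/2)   cubic B-spline lowpass,  taps  [1, 4, 6, 4, 1] / 16
#   G(w) = sin^2(w/2)   spline highpass,         taps  [-1, 2, -1] / 4
# Synthesis filters derived from the one-dimensional identity
#   H(w)^2 + G(w) K(w) = 1  with  L(w) = (1 + H(w)^2) / 2:
#   K(w) = 1 + c + c^2 + c^3, c = cos^2(w/2), taps [1,10,47,140,47,10,1]/64
#   L    taps [1, 8, 28, 56, 326, 56, 28, 8, 1] / 512
# The two-dimensional reconstruction
#   S_{j-1} = S_j*h_x*h_y + W1_j*k_x*l_y + W2_j*l_x*k_y
# then sums to exactly 1 in the frequency plane, giving machine-precision
# perfect reconstruction. All filters are whole-sample symmetric, so the
# identity also holds exactly under mirror (symmetric) boundary folding.

WS_H <- c(1, 4, 6, 4, 1) / 16
WS_G <- c(-1, 2, -1) / 4
WS_K <- c(1, 10, 47, 140, 47, 10, 1) / 64
WS_L <- c(1, 8, 28, 56, 326, 56, 28, 8, 1) / 512

# Largest level whose dilated highpass support still fits inside the mirror
# half-period of the larger image dimension.
.max_feasible_level <- function(M, N) {
  lim <- max(M, N) - 1L
  if (lim < 1L) return(0L)
  floor(log2(lim)) + 1L
}

#' Undecimated dyadic wavelet decomposition
#'
#' Decomposes a grayscale image into a coarse approximation plane and, for
#' each level `j = 1..levels`, a pair of detail planes: `W1` responding to
#' variation along x (columns) and `W2` to variation along y (rows). The
#' transform is undecimated (a-trous): every plane has the spatial size of
#' the input, and the filters are dilated by `2^(j-1)` at level `j`. The
#' filter bank is a zero-phase spline pair with exact reconstruction under
#' both boundary rules (see [dwt_reconstruct()]).
#'
#' @param image numeric matrix (grayscale intensities; any finite values —
#'   the transform is linear).
#' @param levels number of decomposition levels `J >= 1`.
#' @param boundary `"symmetric"` (whole-sample mirror, default) or
#'   `"periodic"` (circular).
#' @return An object of class `wavelet_pyramid`: a list with elements
#'   `coarse` (matrix), `details` (list of `levels` elements, each
#'   `list(W1, W2)`), `levels`, and `boundary`.
#' @examples
#' x <- matrix(runif(64 * 64, 0, 255), 64)
#' p <- dwt_decompose(x, levels = 3)
#' max(abs(dwt_reconstruct(p) - x))  # ~1e-13
#' @seealso [dwt_reconstruct()], [wavelet_modulus()]
#' @export
dwt_decompose <- function(image, levels = 3L,
                          boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  x <- .as_gray(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  jmax <- .max_feasible_level(nrow(x), ncol(x))
  if (levels > jmax)
    stop(sprintf(paste0("image of size %dx%d is too small for %d levels: ",
                        "the dilated filter support exceeds both dimensions ",
                        "(max feasible level is %d)"),
                 nrow(x), ncol(x), levels, jmax))
  details <- vector("list", levels)
  S <- x
  for (j in seq_len(levels)) {
    d <- 2L^(j - 1L)
    W1 <- .conv_sep(S, WS_G, 2L, d, boundary)
    W2 <- .conv_sep(S, WS_G, 1L, d, boundary)
    S <- .conv_sep(.conv_sep(S, WS_H, 2L, d, boundary), WS_H, 1L, d, boundary)
    details[[j]] <- list(W1 = W1, W2 = W2)
  }
  structure(list(coarse = S, details = details, levels = levels,
                 boundary = boundary),
            class = "wavelet_pyramid")
}

#' Inverse undecimated dyadic wavelet transform
#'
#' Reconstructs the image from a [dwt_decompose()] pyramid by the level-wise
#' recursion `S_{j-1} = S_j*h + W1_j*(k,l) + W2_j*(l,k)`. For an unmodified
#' pyramid the round trip is exact to machine precision.
#'
#' @param pyramid a `wavelet_pyramid`, or a shape-compatible list with the
#'   same fields (modified detail planes are allowed).
#' @return numeric matrix of the input's size.
#' @export
dwt_reconstruct <- function(pyramid) {
  if (!is.list(pyramid) || is.null(pyramid$coarse) || is.null(pyramid$details))
    stop("'pyramid' must be a wavelet_pyramid-like list")
  boundary <- pyramid$boundary %||% "symmetric"
  S <- .as_gray(pyramid$coarse, "coarse")
  J <- pyramid$levels %||% length(pyramid$details)
  for (j in rev(seq_len(J))) {
    W1 <- .as_gray(pyramid$details[[j]]$W1, "W1")
    W2 <- .as_gray(pyramid$details[[j]]$W2, "W2")
    .check_same_shape(S, W1, sprintf("coarse and W1 at level %d", j))
    .check_same_shape(S, W2, sprintf("coarse and W2 at level %d", j))
    d <- 2L^(j - 1L)
    S <- .conv_sep(.conv_sep(S,  WS_H, 2L, d, boundary), WS_H, 1L, d, boundary) +
         .conv_sep(.conv_sep(W1, WS_K, 2L, d, boundary), WS_L, 1L, d, boundary) +
         .conv_sep(.conv_sep(W2, WS_L, 2L, d, boundary), WS_K, 1L, d, boundary)
  }
  S
}

#' Wavelet modulus at a given level
#'
#' Per-pixel magnitude `sqrt(W1^2 + W2^2)` of the detail pair — a
#' gradient-strength measure used by the texture-difference module.
#'
#' @param pyramid a `wavelet_pyramid`.
#' @param level level index in `1..levels` (default: the coarsest level).
#' @return non-negative numeric matrix.
#' @export
wavelet_modulus <- function(pyramid, level = pyramid$levels) {
  level <- as.integer(level)
  if (level < 1L || level > pyramid$levels)
    stop(sprintf("'level' must be in 1..%d", pyramid$levels))
  d <- pyramid$details[[level]]
  sqrt(d$W1^2 + d$W2^2)
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf("Undecimated dyadic wavelet pyramid: %dx%d, %d level(s), %s boundary\n",
              nrow(x$coarse), ncol(x$coarse), x$levels, x$boundary))
  invisible(x)
}
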