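# Wavelet-quotient image (WQI): reflectance estimation in intensity space.
# The anisotropically diffused image (features preserved) is divided by the
# wavelet coarse plane at level J (the low-frequency, illumination-carrying
# component), so the quotient is an illumination-invariant reflectance
# estimate. The self-quotient image (SQI) -- image over its own Gaussian
# smoothing -- is provided as the reference comparator.

.default_epsilon <- function(image) 1e-6 * max(max(image), 1)

#' Wavelet-quotient reflectance estimate
#'
#' `WQI = Diffuse(f) / max(S_J f, epsilon)` where `Diffuse` is
#' [perona_malik()] and `S_J` the coarse plane of [dwt_decompose()] at level
#' `levels`. The epsilon guard is relative to the image maximum so the
#' quotient is invariant under global intensity scaling.
#'
#' @param image non-negative numeric matrix.
#' @param levels wavelet depth `J` for the denominator (default 3).
#' @param diff a [diffusion_params()] object for the numerator.
#' @param epsilon positive denominator guard; default
#'   `1e-6 * max(max(image), 1)`.
#' @param boundary wavelet boundary rule.
#' @param pyramid optional precomputed [dwt_decompose()] pyramid of `image`
#'   (saves a decomposition inside the frame loop).
#' @return non-negative matrix (dimensionless quotient) with attribute
#'   `"epsilon"` recording the guard used.
#' @details The diffusion step is nonlinear (its edge-stopping scale `kappa`
#'   is an absolute intensity), so to keep the quotient invariant under
#'   global intensity scaling the numerator image is diffused on a
#'   brightness-normalized copy (mean mapped to the nominal 8-bit mid-level
#'   128, where the default `kappa` is calibrated) and rescaled back. The
#'   denominator is linear, so the whole quotient is then homogeneous of
#'   degree 0.
#' @export
wavelet_quotient <- function(image, levels = 3L, diff = diffusion_params(),
                             epsilon = NULL, boundary = "symmetric",
                             pyramid = NULL) {
  x <- .as_gray(image)
  if (any(x < 0)) stop("'image' must be non-negative")
  eps <- epsilon %||% .default_epsilon(x)
  if (!is.numeric(eps) || eps <= 0) stop("'epsilon' must be > 0")
  s <- mean(x) / 128
  num <- if (s > 0) s * perona_malik(x / s, diff) else x
  S <- if (is.null(pyramid)) dwt_decompose(x, levels, boundary)$coarse
       else pyramid$coarse
  q <- num / pmax(S, eps)
  attr(q, "epsilon") <- eps
  q
}

#' Self-quotient reflectance estimate (comparator)
#'
#' `SQI = f / (L * f)` with a Gaussian smoothing kernel `L` of scale
#' `sigma`, mirror boundaries, and the same relative epsilon guard as
#' [wavelet_quotient()]. For `sigma` below about 0.3 pixels the kernel
#' degenerates to a delta and the quotient is identically 1.
#'
#' @param image non-negative numeric matrix.
#' @param sigma Gaussian scale in pixels.
#' @param epsilon positive denominator guard (default as in
#'   [wavelet_quotient()]).
#' @return non-negative matrix with attribute `"epsilon"`.
#' @export
self_quotient <- function(image, sigma = 8, epsilon = NULL) {
  x <- .as_gray(image)
  if (any(x < 0)) stop("'image' must be non-negative")
  eps <- epsilon %||% .default_epsilon(x)
  h <- ceiling(3 * sigma)
  if (h < 1) {
    sm <- x
  } else {
    taps <- stats::dnorm(-h:h, sd = sigma)
    taps <- taps / sum(taps)
    sm <- .conv_sep(.conv_sep(x, taps, 1L, 1L, "symmetric"),
                    taps, 2L, 1L, "symmetric")
  }
  q <- x / pmax(sm, eps)
  attr(q, "epsilon") <- eps
  q
}
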