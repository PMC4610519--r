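# Homomorphic wavelet filter (HWF): illumination estimation in log space.
# The multiplicative image model f = i * r becomes additive after a log
# transform; the wavelet coarse plane of log f carries nearly all of the
# slowly varying illumination, and the residual illumination energy sitting
# near the frequency origin of the detail planes is removed with a
# Butterworth high-pass gain before the inverse transform.

#' HWF parameter set
#'
#' @param levels decomposition depth `J` (default 3).
#' @param cutoff Butterworth cutoff amplitude `D0` in the (pixel-indexed)
#'   frequency plane (default 0.95).
#' @param order Butterworth order `n` (default 2).
#' @param all_levels if `TRUE` (default) the high-pass gain is applied to the
#'   detail planes of every level, matching the intent that illumination
#'   leaks into all detail coefficients; if `FALSE` only the level-`J`
#'   details are filtered (the strict single-level reading).
#' @param mask_domain `"fourier"` (default): each detail plane's centred 2-D
#'   spectrum is multiplied by the gain and inverted; `"direct"`: the gain
#'   grid multiplies the coefficient plane pointwise.
#' @param freq_scale `"normalized"` (default): the radial distance `D` is
#'   measured in units of the half-spectrum radius (`u` offsets divided by
#'   `M`, `v` by `N`), so `D0 = 0.95` suppresses essentially all detail
#'   content and the illumination estimate is genuinely slowly varying;
#'   `"pixel"`: `D` in raw pixel-index units as in [butterworth_mask()],
#'   under which `D0 = 0.95` only removes the immediate neighbourhood of
#'   the frequency origin.
#' @return object of class `hwf_params`.
#' @export
hwf_params <- function(levels = 3L, cutoff = 0.95, order = 2L,
                       all_levels = TRUE,
                       mask_domain = c("fourier", "direct"),
                       freq_scale = c("normalized", "pixel")) {
  mask_domain <- match.arg(mask_domain)
  freq_scale <- match.arg(freq_scale)
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  if (!is.numeric(cutoff) || cutoff < 0)
    stop("'cutoff' must be >= 0 (0 = all-pass, no filtering)")
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be a positive integer")
  structure(list(levels = levels, cutoff = cutoff, order = order,
                 all_levels = isTRUE(all_levels), mask_domain = mask_domain,
                 freq_scale = freq_scale),
            class = "hwf_params")
}

#' Log transform of an intensity image
#'
#' Returns `log(pixel + 1)` element-wise; the +1 offset makes zero pixels
#' valid and is undone by [exp_transform()].
#'
#' @param image non-negative numeric matrix.
#' @return matrix in log space.
#' @export
log_transform <- function(image) {
  x <- .as_gray(image)
  if (any(x < 0)) stop("'image' must be non-negative in intensity space")
  log1p(x)
}

#' Inverse of [log_transform()]
#' @param image matrix in log space.
#' @return matrix in intensity space (`exp(x) - 1`).
#' @export
exp_transform <- function(image) {
  expm1(.as_gray(image))
}

#' Butterworth high-pass gain grid
#'
#' `H(u,v) = 1 / (1 + (D0 / D(u,v))^(2n))` with the centred radial distance
#' `D(u,v) = sqrt((u - M/2)^2 + (v - N/2)^2)`, `u, v` zero-based. At the
#' exact centre (`D = 0`) the gain is the limit value 0.
#'
#' @param M,N grid size (rows, columns).
#' @param cutoff cutoff amplitude `D0 >= 0`; 0 gives the all-ones
#'   (no-op) mask.
#' @param order filter order `n`.
#' @return `M x N` matrix of gains in `[0, 1)`, centred at `(M/2, N/2)`.
#' @export
butterworth_mask <- function(M, N, cutoff = 0.95, order = 2L) {
  if (M < 1L || N < 1L) stop("grid size must be positive")
  .butterworth_from_grid(.radial_grid(M, N, "pixel"), cutoff, order)
}

# Centred radial distance grid, in pixel units or normalized to the
# half-spectrum radius.
.radial_grid <- function(M, N, freq_scale = "pixel") {
  du <- (seq_len(M) - 1) - M / 2
  dv <- (seq_len(N) - 1) - N / 2
  if (freq_scale == "normalized") { du <- du / M; dv <- dv / N }
  sqrt(outer(du^2, dv^2, `+`))
}

.butterworth_from_grid <- function(D, cutoff, order) {
  if (cutoff == 0) return(array(1, dim(D)))   # degenerate all-pass
  H <- 1 / (1 + (cutoff / D)^(2 * order))
  H[D == 0] <- 0
  H
}

# Reorder a centred frequency-plane grid so its centre lands on the DC bin
# of an unshifted FFT (ifftshift).
.ifftshift <- function(x) {
  M <- nrow(x); N <- ncol(x)
  ri <- ((seq_len(M) - 1 + floor(M / 2)) %% M) + 1
  ci <- ((seq_len(N) - 1 + floor(N / 2)) %% N) + 1
  x[ri, ci, drop = FALSE]
}

# Multiply a real plane's centred spectrum by a centred gain grid.
.apply_freq_mask <- function(plane, mask_centred) {
  Hu <- .ifftshift(mask_centred)
  Re(stats::fft(stats::fft(plane) * Hu, inverse = TRUE)) / length(plane)
}

#' Estimate the illumination component of an image (HWF)
#'
#' Pipeline: [log_transform()] -> [dwt_decompose()] at `params$levels` ->
#' attenuate the detail planes with the Butterworth high-pass gain ->
#' [dwt_reconstruct()]. The result is the log-domain illumination estimate;
#' use [hwf_filtered_image()] for the intensity-space version.
#'
#' @param image non-negative numeric matrix.
#' @param params an [hwf_params()] object.
#' @param boundary boundary rule passed to the wavelet transform.
#' @return matrix: log-domain illumination estimate, same size as `image`.
#' @export
estimate_illumination <- function(image, params = hwf_params(),
                                  boundary = "symmetric") {
  stopifnot(inherits(params, "hwf_params"))
  Fl <- log_transform(image)
  pyr <- dwt_decompose(Fl, params$levels, boundary)
  H <- .butterworth_from_grid(
    .radial_grid(nrow(Fl), ncol(Fl), params$freq_scale),
    params$cutoff, params$order)
  lev <- if (params$all_levels) seq_len(params$levels) else params$levels
  for (j in lev) {
    if (params$mask_domain == "fourier") {
      pyr$details[[j]]$W1 <- .apply_freq_mask(pyr$details[[j]]$W1, H)
      pyr$details[[j]]$W2 <- .apply_freq_mask(pyr$details[[j]]$W2, H)
    } else {
      pyr$details[[j]]$W1 <- pyr$details[[j]]$W1 * H
      pyr$details[[j]]$W2 <- pyr$details[[j]]$W2 * H
    }
  }
  dwt_reconstruct(pyr)
}

#' HWF-filtered image in intensity space
#'
#' `exp_transform(estimate_illumination(image))`: the illumination estimate
#' mapped back to intensity space. Values are clamped at 0 to absorb
#' rounding residue of order 1e-12.
#'
#' @inheritParams estimate_illumination
#' @return non-negative matrix.
#' @export
hwf_filtered_image <- function(image, params = hwf_params(),
                               boundary = "symmetric") {
  pmax(exp_transform(estimate_illumination(image, params, boundary)), 0)
}

#' Butterworth homomorphic-filter gain grid (baseline)
#'
#' `h(w) = gl + (gh - gl) / (1 + (d0 / |w|)^(2n))`, centred like
#' [butterworth_mask()]; the DC gain is the limit `gl`.
#'
#' @param M,N grid size.
#' @param gl,gh minimal and maximal amplitudes, `gh >= gl > 0`
#'   (defaults 0.5 and 2.0).
#' @param cutoff cutoff frequency `d0` (default 0.95).
#' @param order filter order (default 2).
#' @return `M x N` centred gain grid in `[gl, gh)`.
#' @export
bhpf_mask <- function(M, N, gl = 0.5, gh = 2.0, cutoff = 0.95, order = 2L) {
  if (!(gh >= gl && gl > 0)) stop("need gh >= gl > 0")
  du <- (seq_len(M) - 1) - M / 2
  dv <- (seq_len(N) - 1) - N / 2
  D <- sqrt(outer(du^2, dv^2, `+`))
  h <- gl + (gh - gl) / (1 + (cutoff / D)^(2 * order))
  h[D == 0] <- gl
  h
}

#' Classic homomorphic filtering with a Butterworth high-pass (baseline)
#'
#' log -> centred 2-D Fourier transform -> multiply by [bhpf_mask()] ->
#' inverse transform -> exp. The reference method the wavelet filter is
#' compared against; with `gl = gh = 1` it is the identity.
#'
#' @param image non-negative numeric matrix.
#' @inheritParams bhpf_mask
#' @param freq_scale frequency units, as in [hwf_params()] (default
#'   `"normalized"`, matching the wavelet filter it is compared against).
#' @return filtered matrix in intensity space.
#' @export
bhpf_filtered_image <- function(image, gl = 0.5, gh = 2.0,
                                cutoff = 0.95, order = 2L,
                                freq_scale = c("normalized", "pixel")) {
  freq_scale <- match.arg(freq_scale)
  Fl <- log_transform(image)
  D <- .radial_grid(nrow(Fl), ncol(Fl), freq_scale)
  h <- gl + (gh - gl) / (1 + (cutoff / D)^(2 * order))
  h[D == 0] <- gl
  exp_transform(.apply_freq_mask(Fl, h))
}
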