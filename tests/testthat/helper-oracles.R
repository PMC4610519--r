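# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (explicit loops, direct formulas)
# so that it cannot share code paths with the implementation.

rand_image <- function(M, N = M, lo = 0, hi = 255) {
  matrix(runif(M * N, lo, hi), M, N)
}

# mirror index fold, written independently of the package internals
fold_idx <- function(i, n) {
  if (n == 1) return(1L)
  p <- 2 * n - 2
  j <- ((i - 1) %% p)
  if (j >= n) j <- p - j
  j + 1L
}
wrap_idx <- function(i, n) ((i - 1) %% n) + 1L

# brute-force 2-D convolution with an explicitly dilated separable kernel:
# out[r, c] = sum_{a, b} kr[a] * kc[b] * x[fold(r + (a - ar) * d), fold(c + (b - ac) * d)]
brute_conv2 <- function(x, kr, kc, dilation = 1, boundary = "symmetric") {
  M <- nrow(x); N <- ncol(x)
  ar <- (length(kr) + 1) / 2; ac <- (length(kc) + 1) / 2
  idx <- if (boundary == "symmetric") fold_idx else wrap_idx
  out <- matrix(0, M, N)
  for (r in seq_len(M)) for (c in seq_len(N)) {
    s <- 0
    for (a in seq_along(kr)) for (b in seq_along(kc)) {
      rr <- idx(r + (a - ar) * dilation, M)
      cc <- idx(c + (b - ac) * dilation, N)
      s <- s + kr[a] * kc[b] * x[rr, cc]
    }
    out[r, c] <- s
  }
  out
}

# exhaustive 1-D 3-means: scan every contiguous split pair of the sorted
# values, computing each block's SSE from scratch
exhaustive_kmeans3_sse <- function(x) {
  v <- sort(x); n <- length(v)
  sse <- function(b) if (length(b) < 2) 0 else sum((b - mean(b))^2)
  best <- Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) {
    s <- sse(v[1:i]) + sse(v[(i + 1):j]) + sse(v[(j + 1):n])
    if (s < best) best <- s
  }
  best
}

# brute-force TDR: per-pixel loop over the 3x3 neighbourhood with mirror
# padding, directly from the defining formula
brute_tdr <- function(W1a, W2a, W1b, W2b) {
  M <- nrow(W1a); N <- ncol(W1a)
  out <- matrix(0, M, N)
  for (r in seq_len(M)) for (c in seq_len(N)) {
    num <- 0; den <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- fold_idx(r + dr, M); cc <- fold_idx(c + dc, N)
      num <- num + W1a[rr, cc] * W1b[rr, cc] + W2a[rr, cc] * W2b[rr, cc]
      den <- den + W1a[rr, cc]^2 + W2a[rr, cc]^2 +
                   W1b[rr, cc]^2 + W2b[rr, cc]^2
    }
    out[r, c] <- if (den > 0) 1 - 2 * num / den else 0
  }
  out
}

# build a pyramid-shaped object with prescribed level-1 detail planes
fake_pyramid <- function(W1, W2, coarse = matrix(0, nrow(W1), ncol(W1))) {
  structure(list(coarse = coarse, details = list(list(W1 = W1, W2 = W2)),
                 levels = 1L, boundary = "symmetric"),
            class = "wavelet_pyramid")
}

# naive 3x3 box blur with edge replication
box_blur3 <- function(x) {
  M <- nrow(x); N <- ncol(x)
  out <- matrix(0, M, N)
  for (r in seq_len(M)) for (c in seq_len(N)) {
    rr <- pmin(pmax(r + (-1:1), 1), M)
    cc <- pmin(pmax(c + (-1:1), 1), N)
    out[r, c] <- mean(x[rr, cc])
  }
  out
}

# small scene shortcut for module tests (96x96, scaled-down sow)
small_scene <- function(seed = 1, n_frames = 2, ...) {
  generate_scene(scene_spec(
    size = c(96, 96), n_warmup = 2, n_frames = n_frames,
    lamp_events = NULL,
    animal = list(center_start = c(50, 40), center_end = c(46, 60),
                  axes = c(13, 22), angle = 25, base = 2.0,
                  texture_amp = 0.25, texture_corr = 3),
    piglets = list(list(center = c(22, 26), radius = 4, base = 1.45)),
    seed = seed, ...))
}
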