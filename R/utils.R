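# Internal helpers shared across modules: index folding for boundary rules,
# separable a-trous convolution, and small validators.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map arbitrary integer indices onto 1..n under a boundary rule.
# "symmetric" is whole-sample mirror reflection (period 2n-2), well defined
# for any offset; "periodic" is circular wrap.
.edge_index <- function(i, n, boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  if (n == 1L) return(rep(1L, length(i)))
  if (boundary == "periodic") return(((i - 1L) %% n) + 1L)
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

# Separable convolution of a matrix with a short odd-length zero-phase tap
# vector, dilated a-trous style (taps spaced `dilation` pixels apart).
# along = 1 filters down the rows (y direction), along = 2 across the
# columns (x direction). Boundary handled by index folding, so any dilation
# is valid for any image size >= 2.
.conv_sep <- function(x, taps, along, dilation = 1L, boundary = "symmetric") {
  n <- if (along == 1L) nrow(x) else ncol(x)
  half <- (length(taps) - 1L) %/% 2L
  base <- seq_len(n)
  out <- 0
  for (t in seq_along(taps)) {
    s <- (t - 1L - half) * dilation
    ix <- .edge_index(base + s, n, boundary)
    out <- out + taps[t] * (if (along == 1L) x[ix, , drop = FALSE]
                            else x[, ix, drop = FALSE])
  }
  out
}

# 3x3 neighbourhood sum with mirror-padded borders.
.box3 <- function(x) {
  .conv_sep(.conv_sep(x, c(1, 1, 1), 1L, 1L, "symmetric"),
            c(1, 1, 1), 2L, 1L, "symmetric")
}

# Coerce to a plain numeric matrix and validate finiteness.
.as_gray <- function(x, arg = "image") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop(sprintf("'%s' contains non-finite values", arg))
  x
}

.check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

.as_mask <- function(x, arg = "mask") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.logical(x)) {
    m <- x
  } else {
    m <- .as_gray(x, arg) > 0
  }
  if (!is.matrix(m)) stop(sprintf("'%s' must be a matrix", arg))
  m
}

# Intensity clipping; applied only at I/O boundaries, never inside the math.
.clip255 <- function(x) pmin(pmax(x, 0), 255)
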