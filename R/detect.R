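# Foreground extraction: k-means classification of the synthesized image,
# MMD boundary thresholding, and the four-step morphological combination
# that isolates the animal shape.

#' Detection parameter set
#'
#' @param k number of intensity clusters (default 3: background, mixed,
#'   foreground).
#' @param mth MMD boundary threshold: a positive number, or `"otsu"`
#'   (default) to derive it from the MMD histogram.
#' @param min_area_frac components smaller than this fraction of the image
#'   area are removed during combination (default 0.001).
#' @param se_diameter diameter in pixels of the circular structuring element
#'   used to close the boundary mask (odd; default 3, i.e. the 3x3 cross).
#' @param trim_radius final erosion radius in pixels (default 0: none). The
#'   MMD boundary band at wavelet level `J` is about `2^(J-1)` pixels wide,
#'   so the extracted shape over-covers the object by roughly half that;
#'   the pipeline sets `trim_radius = 2^(J-1)/2` to compensate.
#' @param min_contrast minimum brightening factor, on the offset scale
#'   `syn + 1`, of the foreground cluster over the background cluster
#'   (default 1.5, a gated log-brightening of ~0.4). A synthesized frame
#'   whose brightest cluster does not reach it carries no foreground — the
#'   clusters are then just slices of the background noise — and yields an
#'   empty mask.
#' @param kmeans_seed kept for interface stability; the 1-D clustering used
#'   here is an exact dynamic program and needs no random initialisation.
#' @return object of class `detect_params`.
#' @export
detect_params <- function(k = 3L, mth = "otsu", min_area_frac = 0.001,
                          se_diameter = 3L, trim_radius = 0L,
                          min_contrast = 1.5, kmeans_seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2")
  if (is.character(mth)) {
    if (!identical(mth, "otsu")) stop("'mth' must be a number or \"otsu\"")
  } else if (!is.numeric(mth) || mth <= 0) {
    stop("'mth' must be > 0")
  }
  se_diameter <- as.integer(se_diameter)
  if (se_diameter %% 2L == 0L) stop("'se_diameter' must be odd")
  trim_radius <- as.integer(trim_radius)
  if (trim_radius < 0L) stop("'trim_radius' must be >= 0")
  if (!is.numeric(min_contrast) || min_contrast < 1)
    stop("'min_contrast' must be >= 1")
  structure(list(k = k, mth = mth, min_area_frac = min_area_frac,
                 se_diameter = se_diameter, trim_radius = trim_radius,
                 min_contrast = min_contrast,
                 kmeans_seed = as.integer(kmeans_seed)),
            class = "detect_params")
}

#' Exact 1-D k-means by dynamic programming
#'
#' Globally optimal k-means clustering of scalar values (optimal clusters
#' are contiguous in sorted order; a dynamic program over split points finds
#' the partition minimising the within-cluster sum of squares). Supports
#' weighted values, which lets large images be clustered through their
#' intensity histogram.
#'
#' @param x numeric vector of values.
#' @param k number of clusters (`>= 1`); if `x` has fewer distinct values
#'   than `k`, `k` is degraded with a warning.
#' @param weights optional non-negative weights (same length as `x`).
#' @return `list(centers, boundaries, assignment, sse, k)`: increasing
#'   cluster means, the `k - 1` midpoints separating consecutive clusters,
#'   the cluster index of each input value (1 = lowest), and the total
#'   within-cluster (weighted) sum of squares.
#' @export
kmeans1d <- function(x, k, weights = NULL) {
  if (!is.numeric(x) || !length(x)) stop("'x' must be a non-empty numeric vector")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(weights < 0))
    stop("'weights' must be non-negative and match 'x'")
  keep <- weights > 0
  vv <- x[keep]; ww <- weights[keep]
  o <- order(vv); vv <- vv[o]; ww <- ww[o]
  grp <- cumsum(c(1L, as.integer(diff(vv) != 0)))
  v <- vv[!duplicated(grp)]      # sorted distinct values
  w <- as.vector(rowsum(ww, grp))
  n <- length(v)
  if (n < k) {
    warning(sprintf("only %d distinct values; degrading k from %d", n, k))
    k <- n
  }
  cw0  <- c(0, cumsum(w))
  cwv0 <- c(0, cumsum(w * v))
  cwv20 <- c(0, cumsum(w * v^2))
  cw <- cw0[-1]; cwv <- cwv0[-1]; cwv2 <- cwv20[-1]
  # weighted SSE of the sorted block i..j (vectorized over i or j)
  sse_block <- function(i, j) {
    sw <- cw[j] - cw0[i]
    sv <- cwv[j] - cwv0[i]
    s2 <- cwv2[j] - cwv20[i]
    pmax(s2 - sv^2 / sw, 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)          # first index of the last cluster
  D[1, ] <- sse_block(1, seq_len(n))
  if (k > 1) {
    for (kk in 2:k) {
      for (j in kk:n) {
        i <- kk:j                # candidate starts of the last cluster
        cost <- D[kk - 1, i - 1] + sse_block(i, j)
        m <- which.min(cost)
        D[kk, j] <- cost[m]
        B[kk, j] <- i[m]
      }
    }
  }
  # backtrack split points
  starts <- integer(k); j <- n
  for (kk in k:1) { starts[kk] <- B[kk, j]; j <- starts[kk] - 1L }
  ends <- c(starts[-1] - 1L, n)
  centers <- vapply(seq_len(k), function(kk) {
    i <- starts[kk]:ends[kk]
    sum(w[i] * v[i]) / sum(w[i])
  }, numeric(1))
  boundaries <- if (k > 1) (v[ends[-k]] + v[starts[-1]]) / 2 else numeric(0)
  assignment <- findInterval(x, boundaries) + 1L
  list(centers = centers, boundaries = boundaries,
       assignment = assignment, sse = D[k, n], k = k)
}

#' Foreground mask by intensity clustering of the synthesized image
#'
#' Clusters the pixel intensities into `params$k` groups with exact 1-D
#' k-means and returns the pixels of the bright-side clusters: the
#' brightest cluster, together with any cluster whose centre lies closer
#' to the brightest centre than to the darkest (background) centre. When
#' the clusters are well separated — the brightest intensity level forming
#' its own mode — this is exactly the single brightest cluster; when the
#' synthesized foreground straddles two clusters (its interior brightness
#' rolls off towards the edges at small image scales) the rule keeps the
#' whole bright side instead of splitting the object. Images with more
#' than `max_bins` distinct values are clustered through a weighted
#' intensity histogram (`max_bins` equal-width bins, weighted means as
#' representatives), which keeps the clustering exact on the binned values
#' and deterministic.
#'
#' @param syn numeric matrix (the synthesized image).
#' @param params a [detect_params()] object.
#' @param max_bins histogram resolution for large images (default 512).
#' @return logical matrix: `TRUE` on the bright-side clusters. A constant
#'   image degrades to a single cluster and an all-`TRUE` mask.
#' @export
foreground_by_kmeans <- function(syn, params = detect_params(),
                                 max_bins = 512L) {
  x <- .as_gray(syn, "syn")
  v <- as.vector(x)
  ud <- unique(v)
  if (length(ud) <= max_bins) {
    km <- kmeans1d(v, params$k)
  } else {
    br <- seq(min(v), max(v), length.out = max_bins + 1L)
    bin <- findInterval(v, br, rightmost.closed = TRUE)
    wt <- tabulate(bin, nbins = max_bins)
    sv <- vapply(split(v, bin), mean, numeric(1))
    km <- kmeans1d(sv, params$k, weights = wt[as.integer(names(sv))])
  }
  if (km$k == 1L) return(matrix(TRUE, nrow(x), ncol(x)))
  # no-foreground guard: without genuine brightening the clusters are
  # slices of the background distribution
  if (km$centers[km$k] + 1 < params$min_contrast * (km$centers[1] + 1))
    return(matrix(FALSE, nrow(x), ncol(x)))
  mid <- (km$centers[1] + km$centers[km$k]) / 2
  first_bright <- which(km$centers > mid)[1]   # always <= k, > 1
  thr <- km$boundaries[first_bright - 1L]
  matrix(v > thr, nrow(x), ncol(x))
}

#' Otsu threshold of a non-negative score grid
#'
#' Maximises the between-class variance over a 256-bin histogram of the
#' values; returns the bin-edge threshold.
#'
#' @param x numeric matrix or vector, values `>= 0`.
#' @param n_bins histogram resolution (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(.as_gray(x, "x"))
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(w)
  mu0 <- cumsum(w * mids)
  mu_t <- mu0[n_bins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  br[which.max(bcv) + 1L]
}

#' Boundary mask from an MMD grid
#'
#' `TRUE` where `mmd > Mth`; with `mth = "otsu"` the threshold is computed
#' from the MMD histogram.
#'
#' @param mmd non-negative matrix from [mmd_map()].
#' @param params a [detect_params()] object.
#' @return logical matrix.
#' @export
boundary_by_mmd <- function(mmd, params = detect_params()) {
  m <- .as_gray(mmd, "mmd")
  if (any(m < 0)) stop("'mmd' must be non-negative")
  thr <- if (identical(params$mth, "otsu")) otsu_threshold(m) else params$mth
  m > thr
}

#' 8-connected component labels of a binary mask
#'
#' EBImage's flood labeling is 4-connected; labels touching diagonally are
#' merged through a small label-adjacency graph.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- .as_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  nl <- max(lab)
  if (nl <= 1L) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  M <- nrow(lab); N <- ncol(lab)
  a <- lab[-M, -N]; b <- lab[-1, -1]       # down-right diagonal pairs
  c_ <- lab[-1, -N]; d <- lab[-M, -1]      # up-right diagonal pairs
  e1 <- cbind(as.vector(a), as.vector(b))
  e2 <- cbind(as.vector(c_), as.vector(d))
  ed <- rbind(e1, e2)
  ed <- ed[ed[, 1] > 0 & ed[, 2] > 0 & ed[, 1] != ed[, 2], , drop = FALSE]
  if (!nrow(ed)) return(matrix(as.integer(lab), M, N))
  g <- igraph::graph_from_edgelist(unique(ed), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nl - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(nl)]
  out <- matrix(0L, M, N)
  out[lab > 0] <- as.integer(memb[lab[lab > 0]])
  out
}

.remove_small <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

.shape_features <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  if (area == 0)
    return(list(area = 0L, centroid = c(NA_real_, NA_real_),
                orientation = NA_real_))
  cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
  orientation <- NA_real_
  if (area >= 5) {
    # image y axis points down; use y = -row so a positive angle is
    # counter-clockwise from the x (column) axis, as in standard geometry
    xs <- idx[, 2] - cc; ys <- -(idx[, 1] - cr)
    mu20 <- mean(xs^2); mu02 <- mean(ys^2); mu11 <- mean(xs * ys)
    th <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    if (th <= -90) th <- th + 180
    if (th > 90) th <- th - 180
    orientation <- th
  }
  list(area = as.integer(area), centroid = c(row = cr, col = cc),
       orientation = orientation)
}

#' Combine foreground and boundary masks and extract the animal shape
#'
#' The four-step combination: (1) morphological closing of the boundary
#' mask with a circular structuring element of `se_diameter` pixels;
#' (2) absolute difference (XOR) of foreground and closed boundary, then
#' removal of components smaller than `min_area_frac * M * N` (this
#' separates and discards the smaller animals touching the large one);
#' (3) union with the closed boundary and a second small-component removal;
#' (4) the largest 8-connected component is kept, its holes filled, and its
#' shape features reported.
#'
#' @param fg logical foreground mask ([foreground_by_kmeans()]).
#' @param bou logical boundary mask ([boundary_by_mmd()]).
#' @param params a [detect_params()] object.
#' @return object of class `detection_result`: `list(mask, area, centroid,
#'   orientation, n_components_raw)`. Centroid is `(row, col)` (1-based);
#'   orientation is the angle in degrees in `(-90, 90]` between the x-axis
#'   and the major axis (defined for `area >= 5`). Both empty inputs give
#'   an empty result.
#' @export
combine_and_extract <- function(fg, bou, params = detect_params()) {
  f <- .as_mask(fg, "fg"); b <- .as_mask(bou, "bou")
  .check_same_shape(f, b, "masks")
  min_area <- params$min_area_frac * length(f)
  brush <- if (params$se_diameter == 3L) EBImage::makeBrush(3, "diamond")
           else EBImage::makeBrush(params$se_diameter, "disc")
  b_closed <- if (any(b)) {
    EBImage::imageData(EBImage::closing(b * 1, brush)) > 0
  } else b
  sub <- xor(f, b_closed)
  sub <- .remove_small(sub, min_area)
  com <- sub | b_closed
  com <- .remove_small(com, min_area)
  lab <- label_components(com)
  n_raw <- max(lab)
  if (n_raw == 0) {
    return(structure(list(mask = com, area = 0L,
                          centroid = c(NA_real_, NA_real_),
                          orientation = NA_real_, n_components_raw = 0L),
                     class = "detection_result"))
  }
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  shape <- lab == best
  shape <- EBImage::imageData(EBImage::fillHull(shape * 1)) > 0
  if (params$trim_radius > 0L && any(shape)) {
    tb <- EBImage::makeBrush(2L * params$trim_radius + 1L, "disc")
    er <- EBImage::imageData(EBImage::erode(shape * 1, tb)) > 0
    if (any(er)) {          # erosion may split; keep the largest piece
      lab2 <- label_components(er)
      shape <- lab2 == which.max(tabulate(lab2[lab2 > 0]))
    }
  }
  feats <- .shape_features(shape)
  structure(list(mask = shape, area = feats$area, centroid = feats$centroid,
                 orientation = feats$orientation,
                 n_components_raw = as.integer(n_raw)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$area == 0) {
    cat("detection_result: empty (no foreground object)\n")
  } else {
    cat(sprintf("detection_result: area %d px, centroid (%.1f, %.1f), orientation %.1f deg\n",
                x$area, x$centroid[1], x$centroid[2], x$orientation))
  }
  invisible(x)
}
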