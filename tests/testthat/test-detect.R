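test_that("exact 1-D k-means recovers well-separated modes and degrades gracefully", {
  x <- c(rep(10, 40), rep(100, 30), rep(200, 30))
  km <- kmeans1d(x, 3)
  expect_equal(sort(km$centers), c(10, 100, 200))
  expect_equal(km$sse, 0)
  expect_warning(km2 <- kmeans1d(rep(5, 10), 3), "degrading")
  expect_equal(km2$k, 1)
})

test_that("the dynamic program attains the exhaustive-scan optimum", {
  for (s in 1:10) {
    set.seed(s)
    x <- runif(60, 0, 100)
    expect_equal(kmeans1d(x, 3)$sse, exhaustive_kmeans3_sse(x),
                 tolerance = 1e-9)
  }
})

test_that("weighted clustering equals clustering of replicated values", {
  set.seed(99)
  v <- runif(12); w <- sample(1:4, 12, replace = TRUE)
  a <- kmeans1d(v, 3, weights = w)
  b <- kmeans1d(rep(v, times = w), 3)
  expect_equal(a$sse, b$sse, tolerance = 1e-10)
  expect_equal(sort(a$centers), sort(b$centers), tolerance = 1e-10)
})

test_that("foreground extraction takes the brightest mode and handles degeneracy", {
  img <- matrix(10, 20, 20)
  img[3:8, 3:8] <- 100
  img[12:18, 12:18] <- 200
  fg <- foreground_by_kmeans(img)
  expect_identical(fg, img == 200)
  expect_warning(fg2 <- foreground_by_kmeans(matrix(7, 10, 10)), "degrading")
  expect_true(all(fg2))
})

test_that("otsu separates the modes of a bimodal histogram", {
  set.seed(3)
  lab <- rep(c(0, 1), c(4000, 1000))
  x <- pmax(c(rnorm(4000, 2, 0.5), rnorm(1000, 20, 1.5)), 0)
  th <- otsu_threshold(matrix(x, 50, 100))
  expect_gt(th, 2); expect_lt(th, 20)     # between the component means
  expect_gt(mean((x > th) == lab), 0.999) # classifies the mixture correctly
  # attains the exhaustive between-class-variance optimum (the criterion
  # plateaus across the density gap, so compare attained variance, not
  # threshold location)
  bcv <- function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) / length(x)^2 * (mean(hi) - mean(lo))^2
  }
  xs <- sort(x)
  cands <- (xs[-1] + xs[-length(xs)]) / 2
  best <- max(vapply(cands[seq(1, length(cands), by = 25)], bcv, numeric(1)))
  expect_gt(bcv(th), 0.995 * best)
})

test_that("boundary thresholding follows strict exceedance", {
  m <- matrix(0, 8, 8)
  expect_false(any(boundary_by_mmd(m, detect_params(mth = 5))))
  m[4, 4] <- 9
  b <- boundary_by_mmd(m, detect_params(mth = 5))
  expect_identical(which(b), which(m == 9))
  expect_error(boundary_by_mmd(m - 10, detect_params(mth = 5)), "non-negative")
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 9, 9)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE    # diagonal chain
  m[8, 8] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[4, 4])
  expect_false(lab[8, 8] == lab[2, 2])
})

test_that("combination traces the documented four steps on toy masks", {
  # identical solid disks: the subtraction empties, the closed boundary remains
  d <- matrix(FALSE, 40, 40)
  d[10:30, 10:30] <- TRUE
  res <- combine_and_extract(d, d, detect_params(min_area_frac = 10 / 1600))
  expect_equal(sum(res$mask & d), sum(d))        # disk fully recovered
  expect_equal(res$n_components_raw, 1)
  # block plus a speck, empty boundary: only the block survives
  fg <- matrix(FALSE, 64, 64)
  fg[10:49, 10:49] <- TRUE
  fg[60:61, 60:61] <- TRUE
  res2 <- combine_and_extract(fg, matrix(FALSE, 64, 64),
                              detect_params(min_area_frac = 10 / 4096))
  expect_equal(res2$area, 1600L)
  expect_equal(unname(res2$centroid), c(29.5, 29.5))
  # both masks empty: empty result, not an error
  e <- matrix(FALSE, 16, 16)
  res3 <- combine_and_extract(e, e)
  expect_equal(res3$area, 0L)
})

test_that("shifting both masks shifts the centroid exactly", {
  fg <- matrix(FALSE, 64, 64); fg[10:30, 12:28] <- TRUE
  bou <- matrix(FALSE, 64, 64); bou[9:31, 11:29] <- TRUE & !fg[9:31, 11:29]
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  p <- detect_params(min_area_frac = 0.001)
  r1 <- combine_and_extract(fg, bou, p)
  r2 <- combine_and_extract(shift(fg, 5, 7), shift(bou, 5, 7), p)
  expect_equal(unname(r2$centroid - r1$centroid), c(5, 7))
  expect_equal(r2$area, r1$area)
})

test_that("the extracted shape is a single component or empty", {
  set.seed(6)
  for (rep in 1:5) {
    fg <- matrix(runif(64 * 64) < 0.4, 64, 64)
    bou <- matrix(runif(64 * 64) < 0.1, 64, 64)
    res <- combine_and_extract(fg, bou, detect_params())
    if (res$area > 0)
      expect_equal(max(label_components(res$mask)), 1)
  }
})

test_that("orientation reports the major-axis angle in (-90, 90]", {
  sc <- small_scene(seed = 7)
  cfg <- pipeline_config()
  out <- process_frame(sc$frames[[1]]$image, sc$reference$image, cfg)
  expect_gt(out$result$orientation, 5)
  expect_lt(out$result$orientation, 45)   # generator uses a 25-degree sow
})

test_that("the GMM baseline is quiet on a static scene and fires on a blob", {
  sc <- small_scene(seed = 8, n_frames = 3, straw_dynamics = 0)
  warm <- lapply(sc$warmup, `[[`, "image")
  warm <- c(warm, warm, warm, warm)      # 8 static warm-up frames
  static_seq <- c(warm, list(sc$reference$image))
  g1 <- run_gmm_baseline(static_seq, history = length(warm))
  expect_lt(mean(g1$raw_masks[[1]]), 0.01)
  blob_seq <- c(warm, list(sc$frames[[1]]$image))
  g2 <- run_gmm_baseline(blob_seq, history = length(warm),
                         reference = sc$reference$image)
  am <- sc$frames[[1]]$animal_mask
  expect_gt(mask_iou(g2$masks[[1]], am), 0.3)
  expect_error(run_gmm_baseline(warm, history = 10), "history")
})
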