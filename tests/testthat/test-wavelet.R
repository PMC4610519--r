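test_that("constant images decompose to zero details and a constant coarse", {
  x <- matrix(128, 32, 32)
  p <- dwt_decompose(x, 3)
  for (j in 1:3) {
    expect_equal(max(abs(p$details[[j]]$W1)), 0)
    expect_equal(max(abs(p$details[[j]]$W2)), 0)
    expect_identical(sum(p$details[[j]]$W1), 0)   # zero-mean details, exact
  }
  expect_equal(p$coarse, matrix(128, 32, 32), tolerance = 1e-12)
})

test_that("the transform is linear plane-wise", {
  set.seed(11)
  f <- rand_image(32); g <- rand_image(32)
  a <- 2.5; b <- -1.25
  p1 <- dwt_decompose(a * f + b * g, 3)
  pf <- dwt_decompose(f, 3); pg <- dwt_decompose(g, 3)
  expect_lt(max(abs(p1$coarse - (a * pf$coarse + b * pg$coarse))), 1e-10)
  for (j in 1:3) {
    expect_lt(max(abs(p1$details[[j]]$W1 -
      (a * pf$details[[j]]$W1 + b * pg$details[[j]]$W1))), 1e-10)
    expect_lt(max(abs(p1$details[[j]]$W2 -
      (a * pf$details[[j]]$W2 + b * pg$details[[j]]$W2))), 1e-10)
  }
})

test_that("filter-bank recursion matches brute-force dilated convolution", {
  set.seed(21)
  h <- c(1, 4, 6, 4, 1) / 16
  g <- c(-1, 2, -1) / 4
  for (boundary in c("symmetric", "periodic")) {
    x <- rand_image(16, 20)
    p <- dwt_decompose(x, 2, boundary)
    # level 1: plain kernels on the input
    expect_lt(max(abs(p$details[[1]]$W1 -
      brute_conv2(x, c(1), g, 1, boundary))), 1e-10)
    expect_lt(max(abs(p$details[[1]]$W2 -
      brute_conv2(x, g, c(1), 1, boundary))), 1e-10)
    S1 <- brute_conv2(x, h, h, 1, boundary)
    # level 2: dilated kernels on the level-1 coarse
    expect_lt(max(abs(p$details[[2]]$W1 -
      brute_conv2(S1, c(1), g, 2, boundary))), 1e-10)
    expect_lt(max(abs(p$coarse - brute_conv2(S1, h, h, 2, boundary))), 1e-10)
  }
})

test_that("decompose/reconstruct round trips are exact at J = 1 and J = 3", {
  set.seed(31)
  x <- rand_image(64)
  for (J in c(1, 3))
    expect_lt(max(abs(dwt_reconstruct(dwt_decompose(x, J)) - x)), 1e-8)
  # property over random sizes, both boundary rules
  for (i in 1:10) {
    y <- rand_image(sample(16:64, 1), sample(16:64, 1))
    bd <- sample(c("symmetric", "periodic"), 1)
    expect_lt(max(abs(dwt_reconstruct(dwt_decompose(y, 3, bd)) - y)), 1e-8)
  }
})

test_that("zeroed details with a constant coarse reconstruct a constant", {
  p <- dwt_decompose(matrix(0, 24, 24), 2)
  p$coarse <- matrix(7.5, 24, 24)
  expect_equal(dwt_reconstruct(p), matrix(7.5, 24, 24), tolerance = 1e-10)
})

test_that("decomposition is covariant with circular shifts (periodic)", {
  set.seed(41)
  x <- rand_image(32)
  sh <- function(m, dr, dc)
    m[wrap_idx(seq_len(nrow(m)) + dr, nrow(m)),
      wrap_idx(seq_len(ncol(m)) + dc, ncol(m))]
  p0 <- dwt_decompose(x, 3, "periodic")
  p1 <- dwt_decompose(sh(x, 3, 5), 3, "periodic")
  expect_equal(p1$coarse, sh(p0$coarse, 3, 5), tolerance = 1e-12)
  expect_equal(p1$details[[2]]$W1, sh(p0$details[[2]]$W1, 3, 5),
               tolerance = 1e-12)
})

test_that("the modulus is the per-pixel hypotenuse of the detail pair", {
  p <- fake_pyramid(matrix(3, 4, 4), matrix(4, 4, 4))
  expect_equal(wavelet_modulus(p, 1), matrix(5, 4, 4))
  expect_equal(max(wavelet_modulus(dwt_decompose(matrix(9, 16, 16), 2), 1)), 0)
  set.seed(51)
  pr <- dwt_decompose(rand_image(16), 2)
  for (lev in 1:2) {
    d <- pr$details[[lev]]
    expect_equal(wavelet_modulus(pr, lev), sqrt(d$W1^2 + d$W2^2))
  }
  expect_error(wavelet_modulus(pr, 3), "level")
})

test_that("undersized images and malformed pyramids raise informative errors", {
  expect_error(dwt_decompose(rand_image(8), 4), "max feasible level is 3")
  expect_silent(dwt_decompose(rand_image(8), 3))
  p <- dwt_decompose(rand_image(16), 1)
  p$details[[1]]$W1 <- matrix(0, 8, 8)
  expect_error(dwt_reconstruct(p), "dimensions")
})
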