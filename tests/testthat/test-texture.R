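test_that("gradient planes are the level-J detail pair", {
  set.seed(1)
  f <- rand_image(32)
  p <- dwt_decompose(f, 3)
  gp <- gradient_planes(p)
  expect_identical(gp$W1, p$details[[3]]$W1)
  expect_equal(sqrt(gp$W1^2 + gp$W2^2), wavelet_modulus(p, 3))
  expect_error(gradient_planes(p, 4), "level")
  p0 <- dwt_decompose(matrix(5, 16, 16), 2)
  expect_equal(max(abs(gradient_planes(p0)$W1)), 0)
})

test_that("MMD is the symmetric modulus difference", {
  p1 <- fake_pyramid(matrix(3, 6, 6), matrix(4, 6, 6))
  p2 <- fake_pyramid(matrix(0, 6, 6), matrix(3, 6, 6))
  expect_equal(mmd_map(p1, p2, 1), matrix(2, 6, 6))     # |5 - 3|
  set.seed(2)
  a <- dwt_decompose(rand_image(16), 2)
  b <- dwt_decompose(rand_image(16), 2)
  expect_equal(mmd_map(a, b), mmd_map(b, a))
  expect_true(all(mmd_map(a, b) >= 0))
  expect_equal(mmd_map(a, a), matrix(0, 16, 16))
})

test_that("TDR is 0 for identical frames and 2 for opposed gradients", {
  set.seed(3)
  p <- dwt_decompose(rand_image(16), 2)
  expect_lt(max(abs(tdr_map(p, p))), 1e-12)
  W1 <- matrix(rnorm(64, sd = 4), 8, 8); W2 <- matrix(rnorm(64, sd = 4), 8, 8)
  a <- fake_pyramid(W1, W2); b <- fake_pyramid(-W1, -W2)
  expect_equal(tdr_map(a, b, 1), matrix(2, 8, 8), tolerance = 1e-12)
})

test_that("TDR matches the per-pixel brute-force neighbourhood loop", {
  set.seed(4)
  for (rep in 1:3) {
    W1a <- matrix(rnorm(64), 8, 8); W2a <- matrix(rnorm(64), 8, 8)
    W1b <- matrix(rnorm(64), 8, 8); W2b <- matrix(rnorm(64), 8, 8)
    got <- tdr_map(fake_pyramid(W1a, W2a), fake_pyramid(W1b, W2b), 1)
    expect_lt(max(abs(got - brute_tdr(W1a, W2a, W1b, W2b))), 1e-10)
  }
})

test_that("TDR stays inside [0, 2] and degenerate neighbourhoods give 0", {
  set.seed(5)
  for (rep in 1:5) {
    a <- fake_pyramid(matrix(rnorm(144), 12), matrix(rnorm(144), 12))
    b <- fake_pyramid(matrix(rnorm(144), 12), matrix(rnorm(144), 12))
    td <- tdr_map(a, b, 1)
    expect_true(all(td >= 0 & td <= 2))
  }
  z <- matrix(0, 8, 8)
  expect_equal(tdr_map(fake_pyramid(z, z), fake_pyramid(z, z), 1), z)
})

test_that("TDR ignores global illumination scaling but flags a moved blob", {
  sc <- small_scene(seed = 6, straw_dynamics = 0, noise_sigma = 0)
  f <- sc$frames[[1]]$image
  pf <- dwt_decompose(f, 3)
  # pure gain change: almost no pixel crosses the texture-change threshold
  td_gain <- tdr_map(pf, dwt_decompose(0.5 * f, 3))
  expect_lt(mean(td_gain > 0.5), 0.05)
  # animal present vs empty reference: the blob boundary is flagged
  td_blob <- tdr_map(pf, dwt_decompose(sc$reference$image, 3))
  am <- sc$frames[[1]]$animal_mask
  border <- am & !am[c(1, seq_len(nrow(am) - 1)), ]   # thin upper border band
  expect_gt(mean(td_blob[border] > 0.5), 0.5)
})
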