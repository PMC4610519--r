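test_that("log/exp transforms are the documented inverse pair", {
  expect_equal(log_transform(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(log_transform(matrix(exp(1) - 1, 3, 3)), matrix(1, 3, 3))
  set.seed(1)
  f <- rand_image(16)
  expect_lt(max(abs(exp_transform(log_transform(f)) - f)), 1e-10)
  expect_error(log_transform(matrix(-1, 2, 2)), "non-negative")
})

test_that("the Butterworth gain hits its analytic landmarks", {
  # at D = D0 the gain is exactly 1/2 (cutoff chosen on a lattice point)
  H <- butterworth_mask(8, 8, cutoff = 2, order = 3)
  expect_equal(H[5, 7], 0.5)           # (u, v) = (4, 6), D = 2
  # centre (D = 0) is the limit value 0
  expect_equal(H[5, 5], 0)
  # D = 10 with the default D0 = 0.95, n = 2
  H2 <- butterworth_mask(8, 28, cutoff = 0.95, order = 2)
  expect_equal(H2[5, 25], 1 / (1 + 0.095^4), tolerance = 1e-12)
  # monotone in D along a radius, bounded in [0, 1)
  r <- butterworth_mask(64, 64)[33, 33:64]
  expect_true(all(diff(r) >= 0) && all(r >= 0 & r < 1))
})

test_that("an all-pass mask reduces illumination estimation to a round trip", {
  set.seed(2)
  f <- rand_image(32)
  il <- estimate_illumination(f, hwf_params(cutoff = 0))
  expect_lt(max(abs(il - log_transform(f))), 1e-8)
})

test_that("constant images pass through the HWF unchanged", {
  f <- matrix(42, 24, 24)
  expect_equal(estimate_illumination(f), matrix(log(43), 24, 24),
               tolerance = 1e-10)
  expect_equal(hwf_filtered_image(f), f, tolerance = 1e-8)
})

test_that("hwf_filtered_image composes the two public operations", {
  set.seed(3)
  f <- rand_image(32)
  expect_equal(hwf_filtered_image(f),
               pmax(exp_transform(estimate_illumination(f)), 0),
               tolerance = 1e-12)
  expect_true(all(hwf_filtered_image(f) >= 0))
})

test_that("the illumination estimate varies more slowly than the log image", {
  sc <- small_scene(seed = 4)
  f <- sc$frames[[1]]$image
  m_est <- mean(wavelet_modulus(dwt_decompose(estimate_illumination(f), 1), 1))
  m_raw <- mean(wavelet_modulus(dwt_decompose(log_transform(f), 1), 1))
  expect_lt(m_est, m_raw)
})

test_that("HWF output tracks the true illumination field better than the raw frame", {
  sc <- generate_scene(scene_spec(
    size = c(96, 96), n_warmup = 0, n_frames = 1, lamp_events = NULL,
    animal = NULL, piglets = NULL, seed = 5,
    illumination_field = list(type = "spot", amplitude = 0.3)))
  fr <- sc$frames[[1]]
  ih <- hwf_filtered_image(fr$image)
  expect_lt(mean((ih - fr$true_illum)^2), mean((fr$image - fr$true_illum)^2))
})

test_that("illumination estimation is deterministic", {
  set.seed(6)
  f <- rand_image(32)
  expect_identical(estimate_illumination(f), estimate_illumination(f))
})

test_that("the BHPF gain has its analytic midpoint, DC limit, and identity case", {
  # gain at ||w|| = d0 is gl + (gh - gl)/2 = 1.25 for the defaults
  h <- bhpf_mask(8, 8, gl = 0.5, gh = 2.0, cutoff = 2, order = 2)
  expect_equal(h[5, 7], 1.25)
  expect_equal(h[5, 5], 0.5)           # DC -> gl
  set.seed(7)
  f <- rand_image(32)
  expect_lt(max(abs(bhpf_filtered_image(f, gl = 1, gh = 1) - f)), 1e-8)
  expect_error(bhpf_mask(8, 8, gl = 2, gh = 0.5), "gh >= gl")
})
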