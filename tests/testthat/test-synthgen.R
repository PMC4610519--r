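test_that("a fixed seed reproduces the sequence exactly", {
  sp <- scene_spec(size = c(64, 64), n_warmup = 2, n_frames = 3,
                   animal = list(center_start = c(32, 20), center_end = c(32, 44),
                                 axes = c(9, 15), angle = 10, base = 2,
                                 texture_amp = 0.25, texture_corr = 2),
                   piglets = NULL, seed = 42)
  a <- generate_scene(sp); b <- generate_scene(sp)
  expect_identical(a$frames[[3]]$image, b$frames[[3]]$image)
  expect_identical(a$reference$image, b$reference$image)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_scene(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("an empty noiseless static spec repeats the reference frame", {
  sp <- scene_spec(size = c(48, 48), n_warmup = 2, n_frames = 3,
                   animal = NULL, piglets = NULL, lamp_events = NULL,
                   straw_dynamics = 0, noise_sigma = 0, seed = 5)
  sc <- generate_scene(sp)
  for (fr in c(sc$warmup, sc$frames)) {
    expect_identical(fr$image, sc$reference$image)
    expect_false(fr$event_flag)
  }
})

test_that("a lamp event multiplies the mean intensity by its gain", {
  sp <- scene_spec(size = c(64, 64), n_warmup = 0, n_frames = 6,
                   illumination_field = list(type = "uniform", amplitude = 0),
                   base_level = 60, animal = NULL, piglets = NULL,
                   lamp_events = list(list(frame = 4, gain = 2.0)),
                   straw_dynamics = 0, seed = 6)
  sc <- generate_scene(sp)
  ratio <- mean(sc$frames[[4]]$image) / mean(sc$frames[[3]]$image)
  expect_lt(abs(ratio - 2), 0.1)
  expect_true(sc$frames[[4]]$event_flag)
  expect_false(sc$frames[[3]]$event_flag)
})

test_that("the multiplicative model is self-consistent where unclipped", {
  sp <- scene_spec(size = c(64, 64), n_warmup = 0, n_frames = 1,
                   noise_sigma = 0, straw_dynamics = 0, piglets = NULL, seed = 7)
  fr <- generate_scene(sp)$frames[[1]]
  unclipped <- fr$image > 0 & fr$image < 255
  rec <- fr$image[unclipped] / fr$true_illum[unclipped]
  expect_lt(max(abs(rec - fr$true_refl[unclipped]) / fr$true_refl[unclipped]),
            0.01)
})

test_that("a motionless animal stays put for 50 frames with disjoint masks", {
  an <- list(center_start = c(50, 48), center_end = c(50, 48),
             axes = c(13, 22), angle = 25, base = 2,
             texture_amp = 0.25, texture_corr = 3)
  sc <- generate_scene(scene_spec(size = c(96, 96), n_warmup = 0,
                                  n_frames = 50, lamp_events = NULL,
                                  animal = an, seed = 8))
  m1 <- sc$frames[[1]]$animal_mask
  for (fr in sc$frames[c(10, 30, 50)]) {
    expect_identical(fr$animal_mask, m1)
    expect_false(any(fr$animal_mask & fr$piglet_mask))
  }
  expect_gt(sum(m1), 0)
})

test_that("scenes round-trip through the PNG writer", {
  sp <- scene_spec(size = c(32, 32), n_warmup = 1, n_frames = 1,
                   animal = NULL, piglets = NULL, seed = 9)
  sc <- generate_scene(sp)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  expect_true(file.exists(file.path(d, "reference.png")))
  expect_true(file.exists(file.path(d, "scene.json")))
  back <- read_frames(file.path(d, "frame_0001.png"))[[1]]
  expect_equal(dim(back), c(32, 32))
  expect_lt(max(abs(back - sc$frames[[1]]$image)), 1)   # 8-bit quantisation
})
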