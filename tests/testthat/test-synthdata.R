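test_that("stationary and circular models follow their closed-form geometry", {
  sc <- scene_config(n_frames = 50)
  gt <- simulate_tracks(motion_model("stationary", seed = 42), 3, sc)
  for (id in unique(gt$cell_id)) {
    g <- gt[gt$cell_id == id, ]
    expect_equal(g$x_um, rep(g$x_um[1], nrow(g)))
    expect_equal(g$y_um, rep(g$y_um[1], nrow(g)))
  }

  m <- motion_model("circular", radius = 10, angular_speed = 0.1, seed = 7)
  sc_big <- scene_config(width_px = 400, height_px = 400, n_frames = 80)
  gt <- simulate_tracks(m, 2, sc_big)
  for (id in unique(gt$cell_id)) {
    g <- gt[gt$cell_id == id, ]
    chord <- sqrt(diff(g$x_um)^2 + diff(g$y_um)^2)
    expect_equal(chord, rep(2 * 10 * sin(0.05), length(chord)), tolerance = 1e-10)
    # algebraic circle fit: x^2 + y^2 = 2 a x + 2 b y + c has an exact solution
    fit <- lm(I(x_um^2 + y_um^2) ~ x_um + y_um, data = g)
    r <- sqrt((g$x_um - coef(fit)[2] / 2)^2 + (g$y_um - coef(fit)[3] / 2)^2)
    expect_equal(r, rep(10, nrow(g)), tolerance = 1e-8)
  }
})

test_that("brownian increments have the prescribed variance 2 D dt", {
  sc <- scene_config(width_px = 4000, height_px = 4000, n_frames = 100)
  gt <- simulate_tracks(motion_model("brownian", diffusion_coefficient = 1,
                                     seed = 11), 500, sc)
  incs <- unlist(lapply(split(gt, gt$cell_id),
                        function(g) c(diff(g$x_um), diff(g$y_um))))
  # oracle: direct sample variance over all simulated per-axis increments
  expect_equal(var(incs), 2.0, tolerance = 0.05)
  expect_equal(mean(incs), 0, tolerance = 0.05)
})

test_that("identical model + seed reproduces trajectories and frames exactly", {
  sc <- scene_config(n_frames = 8)
  m <- motion_model("persistent", mean_speed = 2, persistence_time = 10, seed = 3)
  gt1 <- simulate_tracks(m, 4, sc)
  gt2 <- simulate_tracks(m, 4, sc)
  expect_identical(gt1, gt2)
  st1 <- render_frames(gt1, sc, seed = 3)
  st2 <- render_frames(gt2, sc, seed = 3)
  expect_identical(st1$frames, st2$frames)
  gt3 <- simulate_tracks(m, 4, sc, seed = 4)
  expect_false(identical(gt1$x_um, gt3$x_um))
})

test_that("invalid model parameters name the offending field", {
  expect_error(motion_model("brownian"), "diffusion_coefficient")
  expect_error(motion_model("brownian", diffusion_coefficient = -1),
               "diffusion_coefficient")
  expect_error(motion_model("persistent", mean_speed = 1, persistence_time = 0),
               "persistence_time")
  expect_error(motion_model("circular", radius = -2, angular_speed = 1), "radius")
  expect_error(scene_config(resolution = 0), "resolution")
  expect_error(scene_config(cell_radius_range = c(8, 5)), "cell_radius_range")
})

test_that("reflecting boundaries keep every position inside the scene", {
  sc <- scene_config(width_px = 60, height_px = 60, n_frames = 300)
  gt <- simulate_tracks(motion_model("brownian", diffusion_coefficient = 5,
                                     seed = 9), 20, sc)
  w_um <- sc$width_px * sc$resolution
  expect_true(all(gt$x_um >= 0 & gt$x_um <= w_um))
  expect_true(all(gt$y_um >= 0 & gt$y_um <= w_um))
})

test_that("rendering produces the configured plateau, background, and noise", {
  sc <- scene_config(width_px = 64, height_px = 64, n_frames = 3,
                     noise_sigma = 0)
  gt <- planted_truth(20, 22, 6, n_frames = 3, scene = sc)
  st <- render_frames(gt, sc)
  expect_identical(st$frames[[1]], st$frames[[2]])  # static scene, no noise
  px <- round(20 / sc$resolution); py <- round(22 / sc$resolution)
  expect_equal(st$frames[[1]][py + 1, px + 1], sc$cell_intensity,
               tolerance = 1e-6)                    # plateau survives 1-px blur
  expect_equal(st$frames[[1]][5, 5], sc$background_level, tolerance = 1e-6)

  # empty truth -> pure background
  empty <- planted_truth(numeric(), numeric(), numeric(), 2, sc)
  st0 <- render_frames(empty, sc)
  expect_true(all(abs(unlist(st0$frames) - sc$background_level) < 1e-12))

  # noise has the configured sd on background areas
  sc_n <- scene_config(width_px = 128, height_px = 128, n_frames = 1,
                       noise_sigma = 0.05)
  stn <- render_frames(planted_truth(numeric(), numeric(), numeric(), 1, sc_n),
                       sc_n, seed = 2)
  expect_equal(sd(stn$frames[[1]]), 0.05, tolerance = 0.02)

  expect_error(render_frames(planted_truth(20, 20, 0.5, 1, sc), sc),
               "radius below 1 px")
})

test_that("scratch band stays cell-free at t = 0 and invert flips contrast", {
  sc <- scene_config(scratch_band = c(60, 110), n_frames = 2)
  gt <- simulate_tracks(motion_model("brownian", diffusion_coefficient = 1,
                                     seed = 5), 40, sc)
  t0 <- gt[gt$frame == 0, ]
  expect_true(all(t0$x_um < 60 | t0$x_um > 110))

  sc_inv <- scene_config(width_px = 64, height_px = 64, n_frames = 1,
                         noise_sigma = 0, invert = TRUE)
  st <- render_frames(planted_truth(20, 20, 6, 1, sc_inv), sc_inv)
  px <- round(20 / sc_inv$resolution)
  expect_equal(st$frames[[1]][px + 1, px + 1], sc_inv$background_level,
               tolerance = 1e-6)
  expect_equal(st$frames[[1]][5, 5], sc_inv$cell_intensity, tolerance = 1e-6)
})

test_that("two-group datasets are reproducible and empty at n_cells = 0", {
  sc <- scene_config(n_frames = 5)
  mA <- motion_model("brownian", diffusion_coefficient = 0.5)
  mB <- motion_model("brownian", diffusion_coefficient = 5)
  ds1 <- make_two_group_dataset(mA, mB, 3, sc, seed = 21)
  ds2 <- make_two_group_dataset(mA, mB, 3, sc, seed = 21)
  expect_identical(ds1$truth_a, ds2$truth_a)
  expect_identical(ds1$stack_b$frames, ds2$stack_b$frames)
  expect_false(identical(ds1$truth_a$x_um, ds1$truth_b$x_um))

  sc <- scene_config(n_frames = 5, noise_sigma = 0)
  ds0 <- make_two_group_dataset(mA, mB, 0, sc, seed = 1)
  expect_identical(nrow(ds0$truth_a), 0L)
  expect_identical(nrow(ds0$truth_b), 0L)
  expect_true(all(abs(unlist(ds0$stack_a$frames) - sc$background_level) < 1e-12))
})

test_that("ground truth and image stacks round-trip through disk", {
  sc <- scene_config(width_px = 48, height_px = 48, n_frames = 3)
  gt <- simulate_tracks(motion_model("brownian", diffusion_coefficient = 1,
                                     seed = 2), 2, sc)
  td <- withr::local_tempdir()
  gp <- file.path(td, "truth.csv")
  write_ground_truth(gt, gp)
  gt2 <- read_ground_truth(gp, resolution = sc$resolution,
                           frame_interval = sc$frame_interval)
  expect_equal(gt2$x_um, gt$x_um, tolerance = 1e-9)

  st <- render_frames(gt, sc, seed = 1)
  sp <- file.path(td, "stack.tif")
  write_image_stack(st, sp, bit_depth = 16L, seed = 1)
  st2 <- read_image_stack(sp)
  expect_equal(st2$resolution, st$resolution)
  expect_equal(st2$frame_interval, st$frame_interval)
  expect_equal(length(st2$frames), 3L)
  # 16-bit quantization error bounded by one gray level
  expect_lt(max(abs(st2$frames[[1]] - st$frames[[1]])), 1 / 65535 + 1e-9)
})
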