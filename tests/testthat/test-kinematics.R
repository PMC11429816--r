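test_that("spline smoothing reproduces lines, circles, and rest exactly enough", {
  # linear track: unit first derivative, zero second derivative
  tr <- make_track(x = 0:29, y = rep(0, 30))
  st <- smooth_track(tr)
  interior <- 5:25
  expect_equal(st$dx[interior], rep(1, length(interior)), tolerance = 1e-6)
  expect_equal(abs(st$ddx[interior]), rep(0, length(interior)), tolerance = 1e-6)
  expect_equal(st$x, tr$x_um, tolerance = 1e-8)

  # dense noiseless circle: positions preserved to 0.05 um at interior points
  tr <- circle_track(R = 10, omega = 0.1, n = 200)
  st <- smooth_track(tr)
  interior <- 10:190
  expect_lt(max(abs(st$x[interior] - tr$x_um[interior])), 0.05)
  expect_lt(max(abs(st$y[interior] - tr$y_um[interior])), 0.05)

  # constant track: zero derivatives everywhere
  tr <- make_track(rep(3, 20), rep(4, 20))
  st <- smooth_track(tr)
  expect_equal(st$dx, rep(0, 20), tolerance = 1e-8)
  expect_equal(st$ddy, rep(0, 20), tolerance = 1e-8)

  expect_warning(out <- smooth_track(make_track(1:3, 1:3)), "fewer than 4")
  expect_null(out)
  expect_error(smooth_track(make_track(c(1, 2, 2, 3), c(0, 0, 0, 0) ,
                                       dt = 0)), "repeated time")
})

test_that("speed signal matches closed forms (3-4-5 step, circle chord)", {
  st <- smooth_track(make_track(c(0, 3, 6, 9, 12), c(0, 4, 8, 12, 16)))
  expect_equal(speed_signal(st), rep(5, 4), tolerance = 1e-6)

  st <- smooth_track(circle_track(R = 10, omega = 0.1, n = 120), smoothing = -1.5)
  v <- speed_signal(st)
  v_chord <- 2 * 10 * sin(0.1 / 2)   # chord of a 0.1-rad arc per min
  expect_equal(v[10:100], rep(v_chord, 91), tolerance = 1e-3)

  st <- smooth_track(make_track(rep(1, 10), rep(2, 10)))
  expect_equal(speed_signal(st), rep(0, 9), tolerance = 1e-9)
})

test_that("curvature recovers 1/R on circles and 0 on lines", {
  st <- smooth_track(straight_track(speed = 2, n = 50, angle = 0.3))
  expect_equal(curvature_signal(st)[5:45], rep(0, 41), tolerance = 1e-6)

  for (R in c(5, 10, 20)) {
    st <- smooth_track(circle_track(R = R, omega = 0.5 / R, n = 250))
    chi <- curvature_signal(st)[15:235]
    expect_equal(mean(chi), 1 / R, tolerance = 0.05)
  }

  # scaling law: halving R doubles curvature
  chi5 <- mean(curvature_signal(smooth_track(circle_track(R = 5, omega = 0.1,
                                                          n = 250)))[15:235])
  chi10 <- mean(curvature_signal(smooth_track(circle_track(R = 10, omega = 0.1,
                                                           n = 250)))[15:235])
  expect_equal(chi5 / chi10, 2, tolerance = 0.02)

  # curvature is NA where the cell is at rest
  st <- smooth_track(make_track(rep(0, 12), rep(0, 12)))
  expect_true(all(is.na(curvature_signal(st))))
})

test_that("turning angle follows the printed from-+y convention", {
  # step velocity (0, 1): angle 0; (1, 0): angle pi/2 under "printed"
  st_up <- smooth_track(make_track(rep(0, 10), 0:9))
  expect_equal(turning_angle_signal(st_up), rep(0, 9), tolerance = 1e-6)
  st_right <- smooth_track(make_track(0:9, rep(0, 10)))
  expect_equal(turning_angle_signal(st_right), rep(pi / 2, 9), tolerance = 1e-6)
  # the conventional from-+x option
  expect_equal(turning_angle_signal(st_right, convention = "math"),
               rep(0, 9), tolerance = 1e-6)
  expect_equal(turning_angle_signal(st_up, convention = "math"),
               rep(pi / 2, 9), tolerance = 1e-6)

  # isotropic random walk: headings have a near-zero mean resultant vector
  # (the resultant's angle itself is uniform when its length is ~0, so the
  # meaningful isotropy check is on the resultant length)
  set.seed(33)
  tr <- brownian_track(n = 501, D = 1)
  th <- turning_angle_signal(smooth_track(tr, smoothing = 0.2))
  expect_lt(sqrt(mean(sin(th))^2 + mean(cos(th))^2), 0.15)
  expect_lt(abs(mean(sin(th))), 0.1)
  expect_lt(abs(mean(cos(th))), 0.1)
})

test_that("MSD equals the double-loop definition and fits recover D algebraically", {
  # exact msd(tau) = 4 tau pattern: x = sqrt(4 t), y = 0 is not linear in
  # overlapping windows; instead verify the algebra on simulated data plus
  # the exact identity D = exp(y0)/4
  set.seed(4)
  tr <- brownian_track(n = 200, D = 2)
  prof <- msd_profile(smooth_track(tr))
  oracle <- double_loop_msd(tr$x_um, tr$y_um, seq_along(prof$tau))
  expect_equal(prof$msd, oracle, tolerance = 1e-9)
  expect_identical(prof$fit_lags, 1:50)

  # a track with exact msd(tau) = 4 tau: independent increments +/- 2 per axis
  # alternating so every lag-m displacement is exactly 2*sqrt(m)... instead
  # verify on the closed form: positions x = 2*sqrt(t) give |x(t+m)-x(t)|
  # varying, so use the direct algebra:
  expect_equal(diffusion_coefficient(structure(list(y0 = log(4)),
                                               class = "msd_profile")), 1)
  expect_equal(diffusion_coefficient(structure(list(y0 = 0),
                                               class = "msd_profile")), 0.25)

  # stationary track: msd identically 0, fit undefined, D missing
  st <- smooth_track(make_track(rep(1, 20), rep(1, 20)))
  prof0 <- msd_profile(st)
  expect_true(all(prof0$msd == 0))
  expect_true(is.na(prof0$y0))
  expect_true(is.na(diffusion_coefficient(prof0)))

  expect_error(msd_profile(smooth_track(make_track(1:6, 1:6))), "8 samples")
})

test_that("median D over many Brownian tracks recovers the generative value", {
  set.seed(10)
  for (D in c(0.5, 2)) {
    Dhat <- replicate(120, {
      tr <- brownian_track(n = 200, D = D)
      diffusion_coefficient(msd_profile(tr))
    })
    expect_equal(median(Dhat), D, tolerance = 0.15)
  }
})

test_that("descriptors are rotation-invariant and scale-covariant", {
  set.seed(21)
  tr <- brownian_track(n = 100, D = 1)
  rot <- function(tr, a) make_track(cos(a) * tr$x_um - sin(a) * tr$y_um,
                                    sin(a) * tr$x_um + cos(a) * tr$y_um)
  d0 <- summarize_track(smooth_track(tr))
  for (a in c(0.7, 2.1)) {
    dr <- summarize_track(smooth_track(rot(tr, a)))
    expect_equal(dr$mean_speed_um_min, d0$mean_speed_um_min, tolerance = 1e-6)
    expect_equal(dr$mean_curvature_per_um, d0$mean_curvature_per_um,
                 tolerance = 1e-6)
    expect_equal(dr$diffusion_um2_min, d0$diffusion_um2_min, tolerance = 1e-6)
  }
  # rotation changes headings by exactly the rotation (math convention)
  a <- 0.7
  th0 <- turning_angle_signal(smooth_track(tr), convention = "math")
  thr <- turning_angle_signal(smooth_track(rot(tr, a)), convention = "math")
  dth <- (thr - th0 - a + pi) %% (2 * pi) - pi
  expect_equal(dth, rep(0, length(dth)), tolerance = 1e-6)

  # scale covariance: c * positions => c * speed, curvature / c, c^2 * D
  # (fixed moderate spar: the smoother is then exactly linear in the
  # positions and well conditioned)
  c_ <- 3
  trc <- make_track(c_ * tr$x_um, c_ * tr$y_um)
  dc <- summarize_track(smooth_track(trc, smoothing = 0.3))
  d0i <- summarize_track(smooth_track(tr, smoothing = 0.3))
  expect_equal(dc$mean_speed_um_min / d0i$mean_speed_um_min, c_,
               tolerance = 1e-6)
  expect_equal(dc$mean_curvature_per_um / d0i$mean_curvature_per_um, 1 / c_,
               tolerance = 1e-6)
  expect_equal(dc$diffusion_um2_min / d0i$diffusion_um2_min, c_^2,
               tolerance = 1e-6)
})

test_that("summaries cover straight and circular closed forms, batches conserve rows", {
  d <- summarize_track(smooth_track(straight_track(speed = 2, n = 60)))
  expect_equal(d$mean_speed_um_min, 2, tolerance = 1e-6)
  expect_equal(d$mean_curvature_per_um, 0, tolerance = 1e-6)

  d <- summarize_track(smooth_track(circle_track(R = 10, omega = 0.05, n = 250)))
  expect_equal(d$mean_curvature_per_um, 0.1, tolerance = 0.01)

  set.seed(2)
  trs <- bind_tracks(lapply(1:7, function(i) brownian_track(n = 60, D = 1)))
  desc <- summarize_tracks(trs, group = "ctrl")
  expect_identical(nrow(desc), 7L)
  expect_identical(unique(desc$group), "ctrl")

  td <- withr::local_tempdir()
  p <- file.path(td, "desc.csv")
  write_descriptors(desc, p)
  expect_equal(read_descriptors(p)$mean_speed_um_min, desc$mean_speed_um_min,
               tolerance = 1e-9)
})
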