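test_that("breathing waveform hits its anchors and reduces to a sinusoid", {
  rr <- 15; T <- 60 / rr
  expect_equal(breathing_waveform(0, rr, 1 / 3), 0)
  expect_equal(breathing_waveform(T / 3, rr, 1 / 3), 1)
  tt <- seq(0, 8, by = 0.01)
  expect_equal(breathing_waveform(tt, rr, 0.5),
               (1 - cos(2 * pi * tt / T)) / 2, tolerance = 1e-12)
  w <- breathing_waveform(tt, rr, 0.3)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(breathing_waveform(tt, rr, 0.3),
               breathing_waveform(tt + T, rr, 0.3), tolerance = 1e-9)
})

test_that("analytic waveform derivative matches numerical differentiation", {
  rr <- 20; f <- 0.4; h <- 1e-5
  tt <- seq(0.01, 5.9, by = 0.037)
  num <- (breathing_waveform(tt + h, rr, f) -
            breathing_waveform(tt - h, rr, f)) / (2 * h)
  expect_equal(breathing_waveform_deriv(tt, rr, f), num, tolerance = 1e-6)
  # symmetric cycle: peak |flow| for tidal volume vt is pi vt rr / 60
  tt2 <- seq(0, 4, by = 1e-4)
  peak <- max(abs(400 * breathing_waveform_deriv(tt2, rr, 0.5)))
  expect_equal(peak, pi * 400 * rr / 60, tolerance = 1e-3)
})

test_that("dome profile and its numerically integrated volume are correct", {
  expect_equal(dome_height_field(0, 0, c(150, 150)), 1)
  expect_equal(dome_height_field(150, 0, c(150, 150)), 0)
  expect_equal(dome_height_field(0, -150, c(150, 150)), 0)
  # closed form of the integral over an elliptical support: a b (pi/2 - 2/pi)
  for (ax in list(c(150, 150), c(180, 130))) {
    expect_equal(dome_unit_volume(ax),
                 ax[1] * ax[2] * (pi / 2 - 2 / pi), tolerance = 1e-3)
  }
})

test_that("rendered frames honour the scene geometry", {
  cfg <- fast_config("adult", noise_sigma = 0, duration = 2)
  f_exp <- render_frame(cfg, 0)                       # end-expiration
  f_insp <- render_frame(cfg, cfg$insp_fraction * 60 / cfg$rr_true)
  intr <- cfg$intrinsics
  # a corner pixel's ray misses the dome: depth is the bed plane
  expect_equal(f_exp[5, 5], cfg$bed_distance, tolerance = 0.05 + 1e-9)
  cu <- round(intr$cx) + 1; cv <- round(intr$cy) + 1
  expect_lt(f_insp[cu, cv], cfg$bed_distance - cfg$baseline_height)
  # inflation moves the centre towards the camera
  expect_lt(f_insp[cu, cv], f_exp[cu, cv])
})

test_that("same seed gives identical sequences; different seeds differ in noise only", {
  cfg <- fast_config("adult", duration = 1, seed = 5L)
  g1 <- generate_sequence(cfg)
  g2 <- generate_sequence(cfg)
  expect_identical(g1$sequence$frames, g2$sequence$frames)
  g3 <- generate_sequence(fast_config("adult", duration = 1, seed = 6L))
  expect_false(identical(g1$sequence$frames, g3$sequence$frames))
  expect_identical(g1$truth, g3$truth)   # truth is analytic, seed-free
})

test_that("generated sequences carry exact analytic ground truth", {
  cfg <- fast_config("adult", duration = 8)
  gen <- generate_sequence(cfg)
  expect_equal(n_frames(gen$sequence), 8 * 30)
  expect_equal(gen$truth$vt, 400)
  tab <- gen$truth$table
  expect_equal(min(tab$true_volume_ml), 0)
  expect_equal(max(tab$true_volume_ml) - min(tab$true_volume_ml), 400,
               tolerance = 1e-3)
  # flow is the analytic derivative of volume
  num <- diff(tab$true_volume_ml) * cfg$fps
  mid <- (tab$true_flow_ml_s[-1] + tab$true_flow_ml_s[-nrow(tab)]) / 2
  expect_equal(num, mid, tolerance = 0.02)
})

test_that("ground truth is invariant to resolution, distance and dome position", {
  t1 <- phantom_ground_truth(fast_config("adult", duration = 4))
  t2 <- phantom_ground_truth(fast_config("adult", duration = 4,
                                         resolution = c(320L, 288L),
                                         bed_distance = 1500,
                                         torso_center = c(80, -60)))
  expect_equal(t1$table, t2$table, tolerance = 1e-12)
  expect_equal(t1$vt, t2$vt)
})

test_that("noise-free camera summation recovers the added volume within 1%", {
  # gentle wide dome: the surface is near fronto-parallel, so the
  # area x depth-change summation should be exact up to discretisation
  cfg <- gentle_config()
  gen <- generate_sequence(cfg)
  foot <- dome_footprint_mask(cfg)
  am <- area_map(cfg$intrinsics, get_frame(gen$sequence, 1), foot)
  idx <- which(am$mask)
  v0 <- sum((cfg$bed_distance - get_frame(gen$sequence, 1)[idx]) * am$area[idx]) / 1000
  for (k in c(40, 60, 100, 150)) {
    vk <- sum((cfg$bed_distance - get_frame(gen$sequence, k)[idx]) * am$area[idx]) / 1000
    truth <- gen$truth$table$true_volume_ml[k]
    if (truth > 100)   # quantisation noise dominates tiny added volumes
      expect_equal(vk - v0, truth, tolerance = 0.01)
  }
  k_max <- which.max(gen$truth$table$true_volume_ml)
  v_max <- sum((cfg$bed_distance - get_frame(gen$sequence, k_max)[idx]) * am$area[idx]) / 1000
  expect_equal(v_max - v0, cfg$vt_true, tolerance = 0.01)
})

test_that("misconfigured phantoms are rejected", {
  expect_error(phantom_config("adult", vt_true = -1), class = "depthresp_config")
  expect_error(phantom_config("adult", insp_fraction = 1.2), class = "depthresp_config")
  expect_error(phantom_config("adult", torso_center = c(900, 0)),
               class = "depthresp_config")  # dome outside the field of view
})

test_that("the intensity frame shades slopes and is flat off the dome", {
  cfg <- fast_config("adult", noise_sigma = 0, duration = 1)
  ir <- render_ir_frame(cfg, 0.8)
  expect_equal(ir[3, 3], 1)
  expect_true(min(ir) < 1)       # dome slopes darken
  expect_true(all(ir > 0 & ir <= 1))
})
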