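test_that("a static scene yields a constant raw series and a zero signal", {
  s <- flat_sequence(d = 1000, n = 30)
  intr <- s$intrinsics
  mask <- rasterize_obb(oriented_bbox(80, 72, 60, 50, 0), s$width, s$height)
  am <- area_map(intr, get_frame(s, 1), mask)
  raw <- compute_volume_series(s, am)
  expect_equal(diff(range(raw$volume)), 0)
  vz <- invert_and_zero(raw)
  expect_true(all(vz$volume == 0))
})

test_that("volume summation converts units correctly (single-pixel ROI)", {
  intr <- camera_intrinsics(500, 500, 2, 2, 5, 5)
  s <- depth_sequence(list(matrix(1000, 5, 5)), 30, intr)
  mask <- matrix(FALSE, 5, 5); mask[3, 3] <- TRUE
  am <- area_map(intr, get_frame(s, 1), mask)
  raw <- compute_volume_series(s, am)
  # 1000 mm depth x 4 mm^2 = 4000 mm^3 = 4 mL
  expect_equal(raw$volume, 4, tolerance = 1e-9)
})

test_that("inversion flips sign around the first sample", {
  raw <- volume_series(0:3 / 30, c(1000, 900, 700, 600), 30)
  vz <- invert_and_zero(raw)
  expect_equal(vz$volume, c(0, 100, 300, 400))
  expect_equal(vz$volume[1], 0)
  # double inversion restores the zeroed raw shape
  expect_equal(invert_and_zero(vz)$volume, raw$volume - raw$volume[1])
})

test_that("phantom inspiration-to-expiration difference recovers -Vt", {
  cfg <- gentle_config(duration = 4)
  gen <- generate_sequence(cfg)
  am <- area_map(cfg$intrinsics, get_frame(gen$sequence, 1),
                 dome_footprint_mask(cfg))
  raw <- compute_volume_series(gen$sequence, am)
  k_insp <- which.max(gen$truth$table$true_volume_ml)
  k_exp <- 1
  expect_equal(raw$volume[k_insp] - raw$volume[k_exp], -cfg$vt_true,
               tolerance = 0.01)
})

test_that("dropouts are held from the last valid frame and flagged", {
  intr <- default_intrinsics(c(20L, 20L))
  f1 <- matrix(1000, 20, 20)
  f2 <- f1; f2[5:10, 5:10] <- 0       # 36 of 400 pixels drop out
  f3 <- f1 + 1
  s <- depth_sequence(list(f1, f2, f3), 30, intr)
  mask <- matrix(TRUE, 20, 20); mask[c(1, 20), ] <- FALSE; mask[, c(1, 20)] <- FALSE
  am <- area_map(intr, get_frame(s, 1), mask)
  raw <- compute_volume_series(s, am)
  expect_equal(raw$volume[2], raw$volume[1], tolerance = 1e-9)  # held values
  expect_gt(raw$meta$held_fraction[2], 0)
  expect_equal(raw$meta$held_fraction[1], 0)
  expect_false(raw$meta$quality_warning)  # 36/324 ~ 11% < 20%

  f2b <- f1; f2b[3:18, 3:18] <- 0          # ~79% dropout
  s2 <- depth_sequence(list(f1, f2b, f3), 30, intr)
  raw2 <- compute_volume_series(s2, area_map(intr, get_frame(s2, 1), mask))
  expect_true(raw2$meta$quality_warning)
})

test_that("baseline method: a 1 mm approach over a 40,000 mm^2 ROI gives +40 mL", {
  intr <- camera_intrinsics(500, 500, 80, 72, 160, 144)
  f1 <- matrix(1000, 160, 144)
  f2 <- matrix(999, 160, 144)
  s <- depth_sequence(list(f1, f2), 30, intr)
  mask <- matrix(FALSE, 160, 144); mask[21:120, 21:120] <- TRUE
  vb <- compute_volume_baseline(s, mask, intr)
  # S = 10,000 px x (999.5^2/25e4) mm^2; depth change -1 mm -> +S/1000 mL
  s_total <- 10000 * mean(c(999.5))^2 / 2.5e5
  expect_equal(vb$volume, c(0, s_total / 1000), tolerance = 0.005)
  expect_equal(vb$volume[2], 40, tolerance = 0.01)
})

test_that("baseline and pixel-wise tidal volumes agree on a near-flat dome", {
  cfg <- gentle_config(duration = 6)
  gen <- generate_sequence(cfg)
  mask <- rasterize_obb(phantom_roi(cfg), cfg$resolution[1], cfg$resolution[2])
  am <- area_map(cfg$intrinsics, get_frame(gen$sequence, 1), mask)
  vz <- invert_and_zero(compute_volume_series(gen$sequence, am))
  vb <- compute_volume_baseline(gen$sequence, mask, cfg$intrinsics)
  pt <- function(v) diff(range(v$volume))
  expect_equal(pt(vb), pt(vz), tolerance = 0.1)
})

test_that("estimated volume scales linearly with the breathing amplitude", {
  pt <- function(vt) {
    cfg <- gentle_config(vt_true = vt, duration = 10, rr_true = 20)
    gen <- generate_sequence(cfg)
    a <- analyze_sequence(gen$sequence, roi = phantom_roi(cfg))
    diff(range(a$volume$volume))
  }
  expect_equal(pt(400) / pt(200), 2, tolerance = 0.01)
})

test_that("estimated Vt is invariant to camera distance and lateral offset", {
  est_vt <- function(...) {
    cfg <- gentle_config(duration = 10, rr_true = 20, ...)
    gen <- generate_sequence(cfg)
    a <- analyze_sequence(gen$sequence, roi = phantom_roi(cfg))
    a$report$mean_vt
  }
  by_dist <- vapply(c(700, 1100, 1500),
                    function(d) est_vt(bed_distance = d), numeric(1))
  expect_lt(diff(range(by_dist)) / mean(by_dist), 0.02)
  by_off <- vapply(list(c(0, 0), c(100, 0), c(-100, 0), c(0, 100)),
                   function(ctr) est_vt(torso_center = ctr), numeric(1))
  expect_lt(diff(range(by_off)) / mean(by_off), 0.02)
})

test_that("pixel-wise volume beats the baseline method on a tilted dome", {
  # dome viewed obliquely (off-centre): pixel areas vary across the
  # ROI, which only the pixel-wise weighting accounts for
  cfg <- phantom_config("adult", torso_center = c(280, 180),
                        noise_sigma = 0, duration = 10, rr_true = 20,
                        resolution = c(320L, 288L), seed = 2L)
  gen <- generate_sequence(cfg)
  mask <- rasterize_obb(phantom_roi(cfg), 320, 288)
  am <- area_map(cfg$intrinsics, get_frame(gen$sequence, 1), mask)
  vz <- invert_and_zero(compute_volume_series(gen$sequence, am))
  vb <- compute_volume_baseline(gen$sequence, mask, cfg$intrinsics)
  err <- function(v) abs(diff(range(v$volume[60:280])) - cfg$vt_true)
  expect_lte(err(vz), err(vb))
})
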