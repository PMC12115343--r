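test_that("FIR design is DC-normalised, symmetric, and matches reference responses", {
  spec <- filter_spec(30)
  h <- design_fir(spec)
  expect_length(h, 11)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_equal(h, rev(h), tolerance = 1e-12)
  # frozen magnitude responses (independently computed with a reference
  # windowed-sinc implementation)
  expect_equal(fir_response(h, 0.25, 30), 0.99524047, tolerance = 1e-6)
  expect_equal(fir_response(h, 0.667, 30), 0.96657206, tolerance = 1e-6)
  expect_equal(fir_response(h, 1.333, 30), 0.87254532, tolerance = 1e-6)
  expect_gte(fir_response(h, 0.25, 30), 0.99)
  # ripple well attenuated at 5 Hz
  expect_lt(fir_response(h, 5, 30), 0.2)
})

test_that("the filter spec rejects invalid configurations", {
  expect_error(filter_spec(30, order = 9), class = "depthresp_config")
  expect_error(filter_spec(30, cutoff_hz = 15), class = "depthresp_config")
  expect_error(filter_spec(30, cutoff_hz = 0), class = "depthresp_config")
})

test_that("filtering preserves DC, respiratory amplitudes, and removes noise", {
  const <- volume_series(0:99 / 30, rep(5, 100), 30)
  expect_equal(filter_volume(const)$volume, rep(5, 100), tolerance = 1e-12)

  s <- sine_series(A = 100, f = 0.25)
  sf <- filter_volume(s)
  core <- setdiff(seq_along(sf$volume), sf$meta$edge_region)
  expect_equal(diff(range(sf$volume[core])), 200, tolerance = 0.01)
  # group-delay compensation keeps the output aligned with the input
  expect_equal(sf$volume[core], 0.99524047 * s$volume[core], tolerance = 1e-3)

  set.seed(8)
  noisy <- volume_series(0:599 / 30, rnorm(600), 30)
  expect_lt(var(filter_volume(noisy)$volume), var(noisy$volume))

  short <- volume_series(0:5 / 30, rnorm(6), 30)
  expect_error(filter_volume(short), class = "depthresp_config")
})

test_that("causal mode lags by the group delay instead of compensating", {
  s <- sine_series(A = 50, f = 0.25, duration = 10)
  offline <- filter_volume(s)
  causal <- filter_volume(s, causal = TRUE)
  n <- length(s$volume)
  expect_equal(causal$volume[6:n], offline$volume[1:(n - 5)], tolerance = 1e-9)
})

test_that("minimum peak distance follows round(fps * 60 / max_rr)", {
  expect_identical(min_distance_frames(30, 120), 15L)
  expect_identical(min_distance_frames(15, 120), 8L)   # 7.5 rounds up
  expect_identical(min_distance_frames(30, 60), 30L)
})

test_that("cycle detection on a sinusoid matches the brute-force extrema scan", {
  # A sin(2 pi 0.25 t), 30 s at 30 FPS: peaks at t = 1, 5, ..., 29 (8),
  # troughs at t = 3, 7, ..., 27 (7) -> 6 complete trough-peak-trough cycles
  s <- sine_series(A = 100, f = 0.25, duration = 30)
  mk <- detect_cycles(s)
  expect_length(mk$peak_indices, 8)
  expect_length(mk$trough_indices, 7)
  expect_equal(nrow(mk$cycles), 6)
  expect_equal(s$time[mk$peak_indices], seq(1, 29, by = 4), tolerance = 1 / 30)
  # brute-force oracle: strict local maxima over +/- 1 sample
  x <- s$volume
  brute <- which(vapply(2:(length(x) - 1), function(i)
    x[i] > x[i - 1] && x[i] >= x[i + 1], logical(1))) + 1L
  expect_setequal(mk$peak_indices, brute[x[brute] > 50])
})

test_that("cycle detection fails informatively on degenerate signals", {
  const <- volume_series(0:299 / 30, rep(1, 300), 30)
  expect_error(detect_cycles(const), class = "depthresp_no_cycle")
  short <- sine_series(duration = 0.5)
  expect_error(detect_cycles(short), class = "depthresp_no_cycle")
})

test_that("a small high-frequency ripple does not perturb markers after filtering", {
  tt <- seq(0, 30 - 1 / 30, by = 1 / 30)
  clean <- volume_series(tt, 100 * sin(2 * pi * 0.25 * tt), 30)
  rippled <- volume_series(tt, clean$volume + 4 * sin(2 * pi * 5 * tt), 30)
  mk1 <- detect_cycles(filter_volume(clean))
  mk2 <- detect_cycles(filter_volume(rippled))
  expect_equal(length(mk1$peak_indices), length(mk2$peak_indices))
  expect_lte(max(abs(mk1$peak_indices - mk2$peak_indices)), 1)
  expect_lte(max(abs(mk1$trough_indices - mk2$trough_indices)), 1)
})

test_that("negating the series swaps peaks and troughs exactly", {
  cfg <- fast_config("adult", duration = 10)
  gen <- generate_sequence(cfg)
  a <- analyze_sequence(gen$sequence, roi = phantom_roi(cfg))
  s <- a$filtered
  neg <- volume_series(s$time, -s$volume, s$fps, s$meta)
  mk <- detect_cycles(s); mkn <- detect_cycles(neg)
  expect_identical(mk$peak_indices, mkn$trough_indices)
  expect_identical(mk$trough_indices, mkn$peak_indices)
})

test_that("flat extrema resolve to their leftmost sample", {
  x <- c(0, 1, 3, 3, 3, 1, 0, 2, 0)
  p <- depthresp:::find_signal_peaks(x)
  expect_equal(p, c(3L, 8L))
})

test_that("peak picking agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  # amplitude-modulated breathing-like tone: peaks well separated and
  # all prominent, so both distance conventions must agree
  tt <- seq(0, 30, by = 1 / 30)
  x <- (1 + 0.3 * sin(2 * pi * 0.05 * tt)) * sin(2 * pi * 0.3 * tt)
  ours <- depthresp:::find_signal_peaks(x, min_distance = 15)
  ref <- pracma::findpeaks(x, minpeakdistance = 15)
  expect_setequal(ours, sort(ref[, 2]))
})

test_that("flow differentiates volume and integrates back to it", {
  tt <- 0:299 / 30
  ramp <- volume_series(tt, 10 * tt, 30)
  fr <- compute_flow(ramp)
  expect_equal(fr$flow[2:299], rep(10, 298), tolerance = 1e-9)

  s <- sine_series(A = 100, f = 0.25, duration = 30)
  fl <- compute_flow(s)
  expect_equal(max(fl$flow), 2 * pi * 0.25 * 100, tolerance = 0.005)

  const <- volume_series(tt, rep(3, 300), 30)
  expect_true(all(compute_flow(const)$flow == 0))

  # cumulative sum of flow / fps reconstructs the series within 1% RMS
  # (central-difference flow integrates to the midpoints between samples)
  x <- s$volume; n <- length(x)
  rec <- x[1] + cumsum(fl$flow[2:(n - 1)]) / 30
  target <- (x[2:(n - 1)] + x[3:n]) / 2 - (x[1] + x[2]) / 2 + x[1]
  rel_rms <- sqrt(mean((rec - target)^2)) / sqrt(mean(x^2))
  expect_lt(rel_rms, 0.01)
})
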