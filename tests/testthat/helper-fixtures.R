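# Shared fixtures. Unit tests run on reduced-resolution phantoms
# (160 x 144 or 320 x 288); the sensor geometry in mm is unchanged
# because focal lengths scale with resolution.

fast_config <- function(..., resolution = c(160L, 144L), duration = 10,
                        noise_sigma = 1.1, seed = 42L) {
  phantom_config(..., resolution = resolution, duration = duration,
                 noise_sigma = noise_sigma, seed = seed)
}

# a gentle, wide dome: slopes shallow enough that the camera-side volume
# summation is exact up to discretisation
gentle_config <- function(..., torso_semi_axes = c(260, 190),
                          baseline_height = 5, vt_true = 200,
                          noise_sigma = 0, duration = 6,
                          resolution = c(320L, 288L), seed = 7L) {
  phantom_config("adult", torso_semi_axes = torso_semi_axes,
                 baseline_height = baseline_height, vt_true = vt_true,
                 noise_sigma = noise_sigma, duration = duration,
                 resolution = resolution, seed = seed, ...)
}

# pixel mask of the dome's analytic footprint (rays traced to the bed)
dome_footprint_mask <- function(config) {
  intr <- config$intrinsics
  w <- intr$width; h <- intr$height
  ug <- matrix(0:(w - 1), w, h)
  vg <- matrix(0:(h - 1), w, h, byrow = TRUE)
  x <- (ug - intr$cx) * config$bed_distance / intr$fx - config$torso_center[1]
  y <- (vg - intr$cy) * config$bed_distance / intr$fy - config$torso_center[2]
  (x / config$torso_semi_axes[1])^2 + (y / config$torso_semi_axes[2])^2 < 1
}

# flat-scene sequence: constant depth plus optional noise
flat_sequence <- function(d = 1000, n = 40, width = 160L, height = 144L,
                          noise = 0, fps = 30, seed = 1L) {
  intr <- default_intrinsics(c(width, height))
  set.seed(seed)
  frames <- lapply(seq_len(n), function(k) {
    f <- matrix(d, width, height)
    if (noise > 0) f <- f + rnorm(width * height, 0, noise)
    f
  })
  depth_sequence(frames, fps, intr)
}

# independent point-in-rotated-rectangle oracle: half-plane tests
# against the four polygon edges
polygon_contains <- function(corners, u, v, eps = 1e-9) {
  inside <- rep(TRUE, length(u))
  for (i in 1:4) {
    j <- i %% 4 + 1
    ex <- corners[j, 1] - corners[i, 1]
    ey <- corners[j, 2] - corners[i, 2]
    cr <- ex * (v - corners[i, 2]) - ey * (u - corners[i, 1])
    inside <- inside & cr >= -eps * max(1, abs(ex), abs(ey))
  }
  inside
}

# sampled sinusoidal volume series A sin(2 pi f t)
sine_series <- function(A = 100, f = 0.25, duration = 30, fps = 30) {
  tt <- seq(0, duration - 1 / fps, by = 1 / fps)
  volume_series(tt, A * sin(2 * pi * f * tt), fps,
                meta = list(inverted = TRUE, zeroed = TRUE))
}
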