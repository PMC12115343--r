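#' Normalised breathing waveform
#'
#' Periodic amplitude profile of one respiratory cycle: a raised-cosine
#' rise from 0 (end-expiration) to 1 (end-inspiration) over the
#' inspiratory fraction of the period, followed by a raised-cosine fall
#' over the remainder. Continuous, periodic, and equal to the offset
#' sinusoid `(1 - cos(2 pi t / T)) / 2` when `insp_fraction = 0.5`.
#'
#' @param t Time(s) in seconds (vectorised, `t >= 0`).
#' @param rr Respiratory rate in breaths/min; the period is `60 / rr`.
#' @param insp_fraction Fraction of the cycle spent in inspiration,
#'   strictly between 0 and 1.
#' @return Normalised amplitude in `[0, 1]`.
#' @export
breathing_waveform <- function(t, rr, insp_fraction) {
  check_scalar_number(rr, "rr", 0, 120, strict_lower = TRUE)
  check_scalar_number(insp_fraction, "insp_fraction", 0, 1 - 1e-9,
                      strict_lower = TRUE)
  period <- 60 / rr
  u <- (t %% period) / period
  ifelse(u < insp_fraction,
         (1 - cos(pi * u / insp_fraction)) / 2,
         (1 + cos(pi * (u - insp_fraction) / (1 - insp_fraction))) / 2)
}

#' Time derivative of the breathing waveform
#'
#' Analytic derivative of [breathing_waveform()] in 1/s; multiplied by
#' the tidal volume it gives the ground-truth flow trace.
#'
#' @inheritParams breathing_waveform
#' @return d(amplitude)/dt in 1/s.
#' @export
breathing_waveform_deriv <- function(t, rr, insp_fraction) {
  period <- 60 / rr
  u <- (t %% period) / period
  f <- insp_fraction
  ifelse(u < f,
         pi / (2 * f * period) * sin(pi * u / f),
         -pi / (2 * (1 - f) * period) * sin(pi * (u - f) / (1 - f)))
}

#' Dome height profile
#'
#' Unit-amplitude height of the phantom's torso dome at a point on the
#' bed plane: `cos^2(pi r / 2)` for normalised elliptical radius
#' `r = sqrt((x/a)^2 + (y/b)^2) <= 1`, zero outside. Smooth, compactly
#' supported, maximal (1) at the centre.
#'
#' @param x,y Coordinates on the bed plane in mm, relative to the dome
#'   centre (vectorised).
#' @param semi_axes Numeric `c(a, b)`: semi-axes of the elliptical
#'   support in mm.
#' @return Height per unit amplitude (dimensionless, in `[0, 1]`).
#' @export
dome_height_field <- function(x, y, semi_axes) {
  r2 <- (x / semi_axes[1])^2 + (y / semi_axes[2])^2
  out <- numeric(length(r2))
  inside <- r2 < 1
  out[inside] <- cos(pi * sqrt(r2[inside]) / 2)^2
  dim(out) <- dim(r2)
  out
}

#' Volume under the unit-amplitude dome
#'
#' Numerically integrates [dome_height_field()] over its elliptical
#' support (2D midpoint quadrature). The result (mm^3 per mm of
#' amplitude) converts between dome amplitude and added volume; it is
#' computed once per configuration and cached there.
#'
#' @param semi_axes Numeric `c(a, b)` in mm.
#' @param step Quadrature step in mm; defaults to `min(a, b) / 400`.
#' @return Volume in mm^3 per mm amplitude.
#' @export
dome_unit_volume <- function(semi_axes, step = NULL) {
  a <- semi_axes[1]; b <- semi_axes[2]
  if (is.null(step)) step <- min(a, b) / 400
  xs <- seq(-a + step / 2, a - step / 2, by = step)
  ys <- seq(-b + step / 2, b - step / 2, by = step)
  g <- dome_height_field(matrix(xs, length(xs), length(ys)),
                         matrix(ys, length(xs), length(ys), byrow = TRUE),
                         semi_axes)
  sum(g) * step^2
}

#' Breathing-torso phantom configuration
#'
#' Defines a synthetic scene: a camera looking straight down at a bed
#' plane carrying a cosine-squared torso dome whose amplitude follows
#' [breathing_waveform()], scaled so that the peak-to-trough added
#' volume equals the requested tidal volume. Presets reflect the two
#' bedside setups the method targets: an adult observed from 1.10 m and
#' a small child from 0.80 m. The dome is deliberately shallow
#' (baseline height of a few mm) so the surface stays near
#' fronto-parallel, matching the single-camera perpendicular-motion
#' assumption under which depth change equals surface displacement.
#'
#' @param preset `"adult"` (bed 1100 mm, Vt 400 mL, RR 15, 30 s) or
#'   `"child"` (bed 800 mm, Vt 50 mL, RR 40, 60 s).
#' @param bed_distance Camera-to-bed distance, mm.
#' @param torso_center `c(x, y)` dome centre on the bed plane, mm.
#' @param torso_semi_axes `c(a, b)` dome support semi-axes, mm.
#' @param baseline_height Static dome height at the apex, mm.
#' @param vt_true Tidal volume, mL (> 0).
#' @param rr_true Respiratory rate, breaths/min (0 < rr <= 120).
#' @param insp_fraction Inspiratory fraction of the cycle in (0, 1);
#'   defaults give I:E of 1:2 (adult) and 1:1.5 (child).
#' @param duration Recording length, s.
#' @param fps Frame rate, frames/s.
#' @param noise_sigma Per-pixel Gaussian depth noise sd, mm (1.1 mm is
#'   the sensor's stated accuracy at 1 m).
#' @param resolution `c(width, height)` in pixels; 640 x 576 is the
#'   sensor's full-resolution narrow-field mode, 320 x 288 a fast
#'   reduced mode for quick experiments.
#' @param seed Integer RNG seed for the depth noise.
#' @return A `phantom_config` object (also carrying derived intrinsics,
#'   the cached unit dome volume and the amplitude scaling).
#' @export
phantom_config <- function(preset = c("adult", "child"),
                           bed_distance = NULL, torso_center = c(0, 0),
                           torso_semi_axes = NULL, baseline_height = NULL,
                           vt_true = NULL, rr_true = NULL,
                           insp_fraction = NULL, duration = NULL,
                           fps = 30, noise_sigma = 1.1,
                           resolution = c(640L, 576L), seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    adult = list(bed_distance = 1100, torso_semi_axes = c(180, 130),
                 baseline_height = 5, vt_true = 400, rr_true = 15,
                 insp_fraction = 1 / 3, duration = 30),
    child = list(bed_distance = 800, torso_semi_axes = c(110, 85),
                 baseline_height = 5, vt_true = 50, rr_true = 40,
                 insp_fraction = 0.4, duration = 60))
  pick <- function(x, nm) if (is.null(x)) defaults[[nm]] else x
  bed_distance    <- pick(bed_distance, "bed_distance")
  torso_semi_axes <- pick(torso_semi_axes, "torso_semi_axes")
  baseline_height <- pick(baseline_height, "baseline_height")
  vt_true         <- pick(vt_true, "vt_true")
  rr_true         <- pick(rr_true, "rr_true")
  insp_fraction   <- pick(insp_fraction, "insp_fraction")
  duration        <- pick(duration, "duration")

  check_scalar_number(vt_true, "vt_true", 0, strict_lower = TRUE)
  check_scalar_number(rr_true, "rr_true", 0, 120, strict_lower = TRUE)
  check_scalar_number(insp_fraction, "insp_fraction", 0, 1,
                      strict_lower = TRUE)
  if (insp_fraction >= 1)
    stop_depthresp("config", "insp_fraction must be < 1")
  check_scalar_number(duration, "duration", 0, strict_lower = TRUE)
  check_scalar_number(fps, "fps", 0, strict_lower = TRUE)
  check_scalar_number(noise_sigma, "noise_sigma", 0)
  check_scalar_number(bed_distance, "bed_distance", 0, strict_lower = TRUE)
  check_scalar_number(baseline_height, "baseline_height", 0)

  intr <- default_intrinsics(resolution)
  unit_volume <- dome_unit_volume(torso_semi_axes)
  amplitude <- vt_true * 1000 / unit_volume   # mm of apex motion, peak-to-trough

  cfg <- structure(
    list(bed_distance = bed_distance, torso_center = torso_center,
         torso_semi_axes = torso_semi_axes,
         baseline_height = baseline_height,
         vt_true = vt_true, rr_true = rr_true,
         insp_fraction = insp_fraction, duration = duration, fps = fps,
         noise_sigma = noise_sigma,
         resolution = as.integer(resolution), seed = as.integer(seed),
         preset = preset, intrinsics = intr,
         unit_volume_mm3 = unit_volume, amplitude_mm = amplitude),
    class = "phantom_config")

  # the fully inflated dome must project inside the field of view
  dmin <- bed_distance - baseline_height - amplitude
  if (dmin <= 0)
    stop_depthresp("config", "dome taller than the camera distance")
  ext_u <- intr$cx + (torso_center[1] + c(-1, 1) * torso_semi_axes[1]) *
    intr$fx / dmin
  ext_v <- intr$cy + (torso_center[2] + c(-1, 1) * torso_semi_axes[2]) *
    intr$fy / dmin
  if (ext_u[1] < 0 || ext_u[2] > intr$width - 1 ||
      ext_v[1] < 0 || ext_v[2] > intr$height - 1)
    stop_depthresp("config", "dome projects outside the camera field of view")
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_config:%s> Vt %g mL, RR %g /min, %g s @ %g FPS, bed %g mm,\n",
    "  dome %gx%g mm (apex excursion %.1f mm), noise %.2f mm, %dx%d px, seed %d\n"),
    x$preset, x$vt_true, x$rr_true, x$duration, x$fps, x$bed_distance,
    x$torso_semi_axes[1], x$torso_semi_axes[2], x$amplitude_mm,
    x$noise_sigma, x$resolution[1], x$resolution[2], x$seed))
  invisible(x)
}

#' Render one phantom depth frame
#'
#' Solves, for every pixel, the depth at which the pinhole ray meets the
#' breathing surface (fixed-point iteration, 3 steps; the dome height is
#' far smaller than the camera distance so convergence is immediate),
#' adds Gaussian depth noise and quantises to 0.1 mm. Draws from the
#' current R RNG stream; seed externally (or use [generate_sequence()],
#' which seeds from the configuration) for reproducibility.
#'
#' @param config A [phantom_config()].
#' @param t Time in seconds.
#' @return `width x height` numeric matrix of depths in mm.
#' @export
render_frame <- function(config, t) {
  stopifnot(inherits(config, "phantom_config"))
  .render_frame_int(config, t) * 0.1
}

.render_frame_int <- function(config, t) {
  amp <- config$amplitude_mm *
    breathing_waveform(t, config$rr_true, config$insp_fraction)
  intr <- config$intrinsics
  .render_frame_cpp(intr$width, intr$height, intr$fx, intr$fy,
                    intr$cx, intr$cy,
                    config$bed_distance,
                    config$torso_center[1], config$torso_center[2],
                    config$torso_semi_axes[1], config$torso_semi_axes[2],
                    config$baseline_height + amp,
                    config$noise_sigma)
}

#' Render a Lambertian intensity frame
#'
#' An infrared-like shading image of the phantom surface (cosine of the
#' local surface tilt, 1 on flat areas), provided as a stand-in input
#' for intensity-based ROI detectors.
#'
#' @inheritParams render_frame
#' @return `width x height` matrix of intensities in `(0, 1]`.
#' @export
render_ir_frame <- function(config, t) {
  stopifnot(inherits(config, "phantom_config"))
  intr <- config$intrinsics
  amp <- config$baseline_height + config$amplitude_mm *
    breathing_waveform(t, config$rr_true, config$insp_fraction)
  w <- intr$width; h <- intr$height
  ug <- matrix(0:(w - 1L), w, h); vg <- matrix(0:(h - 1L), w, h, byrow = TRUE)
  x <- (ug - intr$cx) * config$bed_distance / intr$fx - config$torso_center[1]
  y <- (vg - intr$cy) * config$bed_distance / intr$fy - config$torso_center[2]
  a <- config$torso_semi_axes[1]; b <- config$torso_semi_axes[2]
  r <- sqrt((x / a)^2 + (y / b)^2)
  # |grad h| for h = amp cos^2(pi r / 2): amp (pi/2) sin(pi r) |grad r|
  gr <- sqrt((x / a^2)^2 + (y / b^2)^2) / pmax(r, 1e-12)
  slope <- ifelse(r < 1, amp * (pi / 2) * sin(pi * r) * gr, 0)
  1 / sqrt(1 + slope^2)
}

#' Generate a phantom depth sequence with ground truth
#'
#' Renders `duration * fps` frames of the breathing phantom and returns
#' them with the analytic ground truth. The truth is computed from the
#' waveform and the cached dome volume integral, never through the
#' camera pipeline: `true_volume(t) = vt_true * waveform(t)` and
#' `true_flow` is its analytic derivative, so recovery errors measured
#' against it reflect the pipeline alone.
#'
#' @param config A [phantom_config()].
#' @return List with `sequence` (a [depth_sequence()]) and `truth` (a
#'   `ground_truth` object: per-frame `table` of `time_s`,
#'   `true_volume_ml`, `true_flow_ml_s`, plus the scalar cycle
#'   parameters under both peak-flow conventions).
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  nf <- as.integer(round(config$duration * config$fps))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  tt <- series_time(nf, config$fps)
  frames <- vector("list", nf)
  for (k in seq_len(nf)) frames[[k]] <- .render_frame_int(config, tt[k])
  seq_out <- depth_sequence(frames, config$fps, config$intrinsics,
                            meta = list(synthetic = TRUE,
                                        seed = config$seed,
                                        config = config))
  list(sequence = seq_out, truth = phantom_ground_truth(config))
}

#' Analytic ground truth of a phantom configuration
#'
#' @param config A [phantom_config()].
#' @return A `ground_truth` object (see [generate_sequence()]).
#' @export
phantom_ground_truth <- function(config) {
  nf <- as.integer(round(config$duration * config$fps))
  tt <- series_time(nf, config$fps)
  w <- breathing_waveform(tt, config$rr_true, config$insp_fraction)
  dw <- breathing_waveform_deriv(tt, config$rr_true, config$insp_fraction)
  period <- 60 / config$rr_true
  ti <- config$insp_fraction * period
  te <- period - ti
  pif_std <- config$vt_true * pi / (2 * ti)
  pef_std <- config$vt_true * pi / (2 * te)
  structure(
    list(table = data.frame(time_s = tt,
                            true_volume_ml = config$vt_true * w,
                            true_flow_ml_s = config$vt_true * dw),
         vt = config$vt_true, rr = config$rr_true,
         ti = ti, te = te, ie = te / ti,
         pif_standard = pif_std, pef_standard = pef_std,
         pif_difference = pif_std + pef_std,
         pef_difference = pif_std + pef_std,
         fps = config$fps, insp_fraction = config$insp_fraction),
    class = "ground_truth")
}

#' Fixed ROI box covering the phantom torso
#'
#' Projects the dome support (plus a margin of surrounding bed, which
#' adds no volume variation) into pixel coordinates at the dome's
#' closest approach, giving the oriented box a clinician would draw
#' around the thorax.
#'
#' @param config A [phantom_config()].
#' @param margin Multiplicative margin on the dome semi-axes.
#' @return An [oriented_bbox()] with confidence 1.
#' @export
phantom_roi <- function(config, margin = 1.25) {
  stopifnot(inherits(config, "phantom_config"))
  intr <- config$intrinsics
  dref <- config$bed_distance - config$baseline_height - config$amplitude_mm
  oriented_bbox(
    center_u = intr$cx + config$torso_center[1] * intr$fx / dref,
    center_v = intr$cy + config$torso_center[2] * intr$fy / dref,
    width_box = 2 * config$torso_semi_axes[1] * margin * intr$fx / dref,
    height_box = 2 * config$torso_semi_axes[2] * margin * intr$fy / dref,
    angle = 0, confidence = 1)
}
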