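#' Volume time series
#'
#' The thoracic volume signal in mL at the sequence frame rate, with
#' processing provenance (zeroing, inversion, filtering, edge region,
#' dropout statistics) carried in `meta`.
#'
#' @param time Sample times, s (strictly increasing at `1/fps`).
#' @param volume Volume, mL.
#' @param fps Frame rate, frames/s.
#' @param meta List of provenance fields.
#' @return A `volume_series` object.
#' @export
volume_series <- function(time, volume, fps, meta = list()) {
  if (length(time) != length(volume))
    stop_depthresp("config", "time and volume lengths differ")
  structure(list(time = time, volume = volume, fps = fps, meta = meta),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> %d samples @ %g FPS, range [%.2f, %.2f] mL%s\n",
              length(x$volume), x$fps, min(x$volume), max(x$volume),
              if (isTRUE(x$meta$inverted)) " (inverted, zeroed)" else " (raw)"))
  invisible(x)
}

#' Raw camera-to-thorax volume series (pixel-wise method)
#'
#' For each frame, every effective-ROI pixel's depth (mm) is multiplied
#' by its frozen reference-frame area (mm^2) and the products are
#' summed, giving the volume of the space between camera and surface in
#' mL (mm^3 / 1000). Pixels that drop out (depth 0) in later frames
#' keep their most recent valid depth (temporal hold), preserving the
#' fixed-area assumption; the per-frame held fraction is recorded in
#' `meta$held_fraction`, with `meta$quality_warning` set when it ever
#' exceeds 20 %.
#'
#' @param sequence A [depth_sequence()].
#' @param amap An [area_map()] built once from the sequence's
#'   [reference_surface()] and frozen for the whole acquisition.
#' @return A raw (uninverted) [volume_series()].
#' @seealso [invert_and_zero()] to obtain the physiological signal,
#'   [compute_volume_baseline()] for the mean-depth-times-total-area
#'   variant.
#' @export
compute_volume_series <- function(sequence, amap) {
  stopifnot(inherits(sequence, "depth_sequence"), inherits(amap, "area_map"))
  idx <- which(amap$mask)
  if (length(idx) == 0L) stop_depthresp("empty_roi", "effective ROI mask is empty")
  w_area <- amap$area[idx]
  nf <- n_frames(sequence)
  scale <- sequence$depth_scale
  vol <- numeric(nf)
  held <- numeric(nf)
  last <- sequence$frames[[1]][idx] * scale   # reference frame: all valid by construction
  for (k in seq_len(nf)) {
    d <- sequence$frames[[k]][idx] * scale
    bad <- d <= 0
    if (any(bad)) {
      d[bad] <- last[bad]
      held[k] <- mean(bad)
    }
    last <- d
    vol[k] <- sum(d * w_area) / 1000
  }
  meta <- list(inverted = FALSE, zeroed = FALSE, method = "pixelwise",
               n_pixels = length(idx), held_fraction = held,
               quality_warning = any(held > 0.2))
  volume_series(series_time(nf, sequence$fps), vol, sequence$fps, meta)
}

#' Invert and zero a volume series
#'
#' The camera measures the space between itself and the thorax, which
#' shrinks as the lungs fill; the physiological signal is therefore the
#' negated deviation from the first sample:
#' `v'(k) = -(v(k) - v(1))`, so `v'(1) = 0` and inspiration is positive.
#'
#' @param raw A raw [volume_series()].
#' @return A zeroed, inverted [volume_series()].
#' @export
invert_and_zero <- function(raw) {
  stopifnot(inherits(raw, "volume_series"))
  if (length(raw$volume) == 0L)
    stop_depthresp("config", "empty volume series")
  meta <- raw$meta
  meta$inverted <- TRUE; meta$zeroed <- TRUE
  volume_series(raw$time, -(raw$volume - raw$volume[1]), raw$fps, meta)
}

#' Baseline volume series (average depth times total area)
#'
#' The simpler of the two volume estimators, kept for comparison: the
#' mean ROI depth change from the reference frame is multiplied by the
#' total ROI area, `V(k) = D(k) * S / 1000`, and the result is inverted
#' and zeroed like the pixel-wise series. Unlike the pixel-wise method
#' it cannot weight each pixel's depth change by that pixel's own 3D
#' area, so it degrades when the surface is tilted or pixel areas vary
#' across the ROI.
#'
#' @param sequence A [depth_sequence()].
#' @param roi_mask Logical ROI mask.
#' @param intr A [camera_intrinsics()]; the total area `S` is taken from
#'   an [area_map()] of the denoised [reference_surface()].
#' @return A zeroed, inverted [volume_series()].
#' @export
compute_volume_baseline <- function(sequence, roi_mask, intr) {
  stopifnot(inherits(sequence, "depth_sequence"))
  amap <- area_map(intr, reference_surface(sequence), roi_mask)
  total_area <- sum(amap$area)
  idx <- which(amap$mask)
  nf <- n_frames(sequence)
  scale <- sequence$depth_scale
  mean_d <- numeric(nf)
  last <- sequence$frames[[1]][idx] * scale
  for (k in seq_len(nf)) {
    d <- sequence$frames[[k]][idx] * scale
    bad <- d <= 0
    if (any(bad)) d[bad] <- last[bad]
    last <- d
    mean_d[k] <- mean(d)
  }
  raw <- volume_series(series_time(nf, sequence$fps),
                       (mean_d - mean_d[1]) * total_area / 1000,
                       sequence$fps,
                       list(inverted = FALSE, zeroed = TRUE,
                            method = "baseline", n_pixels = length(idx)))
  invert_and_zero(raw)
}
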