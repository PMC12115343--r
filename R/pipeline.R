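#' Run the full analysis pipeline on a depth sequence
#'
#' Chains ROI selection, reference-frame area mapping, pixel-wise
#' volume summation, inversion/zeroing, FIR filtering, cycle detection,
#' flow derivation and report assembly. The area map is frozen from the
#' first frame for the whole acquisition.
#'
#' @param sequence A [depth_sequence()].
#' @param roi ROI selection: `"variance"` (motion-variance detector),
#'   an [oriented_bbox()], or a `"fixed:cu,cv,w,h,angle_deg"` string.
#' @param spec Filter specification; defaults to the order-10, 2 Hz
#'   design at the sequence's frame rate.
#' @param vt_convention,flow_convention Passed to [assemble_report()].
#' @param causal Use causal (uncompensated) filtering.
#' @param include_baseline Also compute the average-depth-times-area
#'   baseline series (slower; for method comparison).
#' @param verbose Emit progress messages (detected ROI, mask size,
#'   dropout statistics, cycle count).
#' @return A `resp_analysis` object: list with `report`, `roi`,
#'   `area` (the [area_map()]), `raw`, `volume` (inverted/zeroed),
#'   `filtered`, `flow`, `markers`, and `baseline` (or `NULL`).
#' @export
analyze_sequence <- function(sequence, roi = "variance",
                             spec = filter_spec(sequence$fps),
                             vt_convention = "expiratory",
                             flow_convention = "difference",
                             causal = FALSE,
                             include_baseline = FALSE,
                             verbose = FALSE) {
  stopifnot(inherits(sequence, "depth_sequence"))
  say <- function(...) if (verbose) message(sprintf(...))

  box <- if (inherits(roi, "oriented_bbox")) roi
  else if (identical(roi, "variance")) detect_roi_variance(sequence)
  else if (is.character(roi) && startsWith(roi, "fixed:"))
    fixed_roi(sub("^fixed:", "", roi))
  else stop_depthresp("config", "roi must be 'variance', 'fixed:...' or an oriented_bbox")
  say("ROI: centre (%.1f, %.1f), %.1f x %.1f px, %.1f deg, confidence %.2f",
      box$center_u, box$center_v, box$width_box, box$height_box,
      box$angle * 180 / pi, box$confidence)

  mask <- rasterize_obb(box, sequence$width, sequence$height)
  amap <- area_map(sequence$intrinsics, reference_surface(sequence), mask)
  say("effective mask: %d pixels (%d dropped), total area %.0f mm^2",
      sum(amap$mask), amap$dropped, sum(amap$area))

  raw <- compute_volume_series(sequence, amap)
  say("held-pixel fraction: max %.3f", max(raw$meta$held_fraction))
  vol <- invert_and_zero(raw)
  filt <- filter_volume(vol, spec, causal = causal)
  markers <- detect_cycles(filt, sequence$fps)
  say("detected %d peaks, %d troughs, %d complete cycles",
      length(markers$peak_indices), length(markers$trough_indices),
      nrow(markers$cycles))
  flow <- compute_flow(filt)
  report <- assemble_report(filt, flow, markers,
                            vt_convention = vt_convention,
                            flow_convention = flow_convention,
                            extra_quality = list(
                              roi_confidence = box$confidence,
                              roi_pixels = sum(amap$mask),
                              roi_dropped = amap$dropped))
  baseline <- if (include_baseline)
    compute_volume_baseline(sequence, mask, sequence$intrinsics) else NULL

  structure(list(report = report, roi = box, area = amap,
                 raw = raw, volume = vol, filtered = filt,
                 flow = flow, markers = markers, baseline = baseline),
            class = "resp_analysis")
}

#' @export
print.resp_analysis <- function(x, ...) {
  cat(sprintf("<resp_analysis> ROI %d px (conf %.2f)\n",
              sum(x$area$mask), x$roi$confidence))
  print(x$report)
  invisible(x)
}
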