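#' Oriented bounding box
#'
#' A rotated rectangular ROI in pixel coordinates: centre, extents, a
#' rotation angle (radians, counter-clockwise about the centre,
#' normalised into `(-pi/2, pi/2]` -- a rectangle is invariant under
#' half-turns) and a detection confidence in `[0, 1]`.
#'
#' @param center_u,center_v Centre in 0-based pixel coordinates.
#' @param width_box,height_box Extents in pixels (> 0).
#' @param angle Rotation in radians.
#' @param confidence Detection confidence in `[0, 1]`.
#' @return An `oriented_bbox` object.
#' @export
oriented_bbox <- function(center_u, center_v, width_box, height_box,
                          angle = 0, confidence = 1) {
  check_scalar_number(width_box, "width_box", 0, strict_lower = TRUE)
  check_scalar_number(height_box, "height_box", 0, strict_lower = TRUE)
  check_scalar_number(confidence, "confidence", 0, 1)
  check_scalar_number(angle, "angle")
  angle <- angle %% pi
  if (angle > pi / 2) angle <- angle - pi
  structure(list(center_u = center_u, center_v = center_v,
                 width_box = width_box, height_box = height_box,
                 angle = angle, confidence = confidence),
            class = "oriented_bbox")
}

#' @export
print.oriented_bbox <- function(x, ...) {
  cat(sprintf(
    "<oriented_bbox> centre (%.1f, %.1f), %.1f x %.1f px, %.1f deg, conf %.2f\n",
    x$center_u, x$center_v, x$width_box, x$height_box,
    x$angle * 180 / pi, x$confidence))
  invisible(x)
}

#' Point-in-oriented-box test
#'
#' A point is inside iff, after rotating it by `-angle` about the box
#' centre, both coordinates lie within the half-extents. The boundary is
#' inclusive (with a small numeric tolerance so that exact-boundary
#' points are kept).
#'
#' @param obb An [oriented_bbox()].
#' @param u,v Point coordinates (vectorised).
#' @return Logical vector.
#' @export
point_in_obb <- function(obb, u, v) {
  stopifnot(inherits(obb, "oriented_bbox"))
  du <- u - obb$center_u; dv <- v - obb$center_v
  ca <- cos(obb$angle); sa <- sin(obb$angle)
  lu <- ca * du + sa * dv
  lv <- -sa * du + ca * dv
  eps <- 1e-9 * max(1, obb$width_box, obb$height_box)
  abs(lu) <= obb$width_box / 2 + eps & abs(lv) <= obb$height_box / 2 + eps
}

#' Corners of an oriented box
#'
#' @param obb An [oriented_bbox()].
#' @return 4 x 2 matrix of `(u, v)` corner coordinates.
#' @export
obb_corners <- function(obb) {
  hw <- obb$width_box / 2; hh <- obb$height_box / 2
  local <- rbind(c(-hw, -hh), c(hw, -hh), c(hw, hh), c(-hw, hh))
  ca <- cos(obb$angle); sa <- sin(obb$angle)
  cbind(u = obb$center_u + ca * local[, 1] - sa * local[, 2],
        v = obb$center_v + sa * local[, 1] + ca * local[, 2])
}

#' Rasterize an oriented box to a pixel mask
#'
#' A pixel belongs to the mask iff its centre (integer coordinates)
#' passes [point_in_obb()]; the mask is clipped to the frame.
#'
#' @param obb An [oriented_bbox()].
#' @param width,height Frame dimensions in pixels.
#' @return Logical `width x height` matrix.
#' @export
rasterize_obb <- function(obb, width, height) {
  stopifnot(inherits(obb, "oriented_bbox"))
  mask <- matrix(FALSE, width, height)
  crn <- obb_corners(obb)
  us <- max(0L, floor(min(crn[, 1]))):min(width - 1L, ceiling(max(crn[, 1])))
  vs <- max(0L, floor(min(crn[, 2]))):min(height - 1L, ceiling(max(crn[, 2])))
  if (length(us) == 0L || length(vs) == 0L || min(crn[, 1]) > width - 1 ||
      max(crn[, 1]) < 0 || min(crn[, 2]) > height - 1 || max(crn[, 2]) < 0)
    stop_depthresp("empty_roi", "oriented box lies outside the frame")
  ug <- matrix(us, length(us), length(vs))
  vg <- matrix(vs, length(us), length(vs), byrow = TRUE)
  sub <- matrix(point_in_obb(obb, as.vector(ug), as.vector(vg)),
                length(us), length(vs))
  mask[us + 1L, vs + 1L] <- sub
  if (!any(mask))
    stop_depthresp("empty_roi", "oriented box covers no pixel centre inside the frame")
  mask
}

#' Fixed (user-configured) ROI
#'
#' Wraps a manually specified oriented box as a detector result with
#' confidence 1. Accepts either explicit geometry arguments or a
#' compact `"cu,cv,w,h,angle_deg"` string as used on the command line.
#'
#' @param spec Either a numeric vector `c(cu, cv, w, h, angle_deg)` or a
#'   comma-separated string of those five numbers.
#' @return An [oriented_bbox()] with confidence 1.
#' @export
fixed_roi <- function(spec) {
  if (is.character(spec))
    spec <- suppressWarnings(as.numeric(strsplit(spec, ",")[[1]]))
  if (length(spec) != 5L || anyNA(spec))
    stop_depthresp("config",
                   "fixed ROI must be five numbers: cu,cv,w,h,angle_deg")
  oriented_bbox(spec[1], spec[2], spec[3], spec[4],
                angle = spec[5] * pi / 180, confidence = 1)
}

# Minimum-area enclosing rotated rectangle of a 2-D point set
# (rotating calipers over the convex hull). Degenerate (collinear)
# sets fall back to an axis-of-spread-aligned box with extents padded
# to at least 1 px so the box invariants hold.
min_area_rect <- function(pts) {
  pts <- unique(pts)
  best <- NULL
  if (nrow(pts) >= 3L) {
    hull <- pts[chull(pts), , drop = FALSE]
    n <- nrow(hull)
    for (i in seq_len(n)) {
      e <- hull[i %% n + 1L, ] - hull[i, ]
      len <- sqrt(sum(e^2))
      if (len < 1e-12) next
      theta <- atan2(e[2], e[1])
      ca <- cos(theta); sa <- sin(theta)
      xr <- ca * hull[, 1] + sa * hull[, 2]
      yr <- -sa * hull[, 1] + ca * hull[, 2]
      w <- diff(range(xr)); h <- diff(range(yr))
      if (is.null(best) || w * h < best$area) {
        cxr <- mean(range(xr)); cyr <- mean(range(yr))
        best <- list(area = w * h, angle = theta,
                     cu = ca * cxr - sa * cyr, cv = sa * cxr + ca * cyr,
                     w = w, h = h)
      }
    }
  }
  if (is.null(best)) {   # < 3 distinct points or collinear hull
    best <- list(angle = 0,
                 cu = mean(range(pts[, 1])), cv = mean(range(pts[, 2])),
                 w = diff(range(pts[, 1])), h = diff(range(pts[, 2])))
  }
  oriented_bbox(best$cu, best$cv, max(best$w, 1), max(best$h, 1),
                angle = best$angle, confidence = 1)
}

#' Motion-variance ROI detector
#'
#' A heuristic detector standing in for a learned thorax detector, with
#' the same contract (depth sequence in, oriented box plus confidence
#' out): per-pixel temporal standard deviation of depth is computed over
#' the first `n_frames`; pixels above the `quantile` of the resulting
#' map form the candidate (breathing-motion) set; the detector returns
#' the minimum-area rotated rectangle around the largest connected
#' candidate component. Confidence is the fraction of all candidate
#' pixels inside the returned box, mirroring a detector's
#' highest-confidence selection.
#'
#' Deterministic given the sequence. Fails (so the caller can fall back
#' to a fixed ROI) when fewer than `min_candidates` pixels show
#' coherent motion -- either too few candidates overall or, on a static
#' noisy scene where the threshold only picks up scattered noise
#' pixels, a largest connected component below that size.
#'
#' @param sequence A [depth_sequence()].
#' @param n_frames Number of leading frames to analyse (>= 10); `NULL`
#'   (default) uses the whole sequence, which gives the tightest noise
#'   floor for offline analysis.
#' @param quantile Candidate threshold quantile of the deviation map.
#' @param min_candidates Minimum candidate-set size before failing.
#' @return An [oriented_bbox()].
#' @export
detect_roi_variance <- function(sequence, n_frames = NULL, quantile = 0.98,
                                min_candidates = 50L) {
  stopifnot(inherits(sequence, "depth_sequence"))
  nf <- n_frames(sequence)
  if (is.null(n_frames)) n_frames <- nf
  if (n_frames < 10L)
    stop_depthresp("config", "variance detection needs at least 10 frames")
  n_frames <- min(n_frames, nf)

  s <- matrix(0, sequence$width, sequence$height)
  s2 <- matrix(0, sequence$width, sequence$height)
  for (k in seq_len(n_frames)) {
    x <- sequence$frames[[k]] * sequence$depth_scale
    s <- s + x
    s2 <- s2 + x * x
  }
  sdev <- sqrt(pmax((s2 - s * s / n_frames) / (n_frames - 1), 0))

  thr <- stats::quantile(sdev, quantile, names = FALSE)
  cand <- sdev > thr
  n_cand <- sum(cand)
  if (n_cand < min_candidates)
    stop_depthresp("detection_failure", sprintf(
      "only %d pixels above the motion threshold (need %d); no coherent breathing motion",
      n_cand, min_candidates), n_candidates = n_cand)

  labels <- EBImage::bwlabel(cand * 1L)
  tab <- tabulate(labels[labels > 0])
  biggest <- which.max(tab)
  # coherence check: isolated noise pixels pass the quantile threshold on
  # any scene; breathing produces one large connected candidate blob
  if (tab[biggest] < min_candidates)
    stop_depthresp("detection_failure", sprintf(
      "largest connected candidate component has %d pixels (need %d); no coherent breathing motion",
      tab[biggest], min_candidates), n_candidates = n_cand)
  idx <- which(labels == biggest)
  pts <- cbind((idx - 1L) %% sequence$width,         # u
               (idx - 1L) %/% sequence$width)        # v
  box <- min_area_rect(pts)

  cidx <- which(cand)
  cu <- (cidx - 1L) %% sequence$width
  cv <- (cidx - 1L) %/% sequence$width
  box$confidence <- mean(point_in_obb(box, cu, cv))
  box
}
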