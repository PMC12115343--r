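#' Pinhole camera intrinsics
#'
#' Bundles the focal lengths, principal point and sensor resolution of an
#' ideal (distortion-free) pinhole depth camera. Pixel coordinates are
#' 0-based `(u, v) = (column, row)` with a pixel's centre at integer
#' coordinates; depths are millimetres along the optical axis.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels, `0 <= cx < width`,
#'   `0 <= cy < height`.
#' @param width,height Sensor resolution in pixels (>= 3).
#' @return A `camera_intrinsics` object.
#' @seealso [default_intrinsics()] for the stock time-of-flight geometry.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  check_scalar_number(fx, "fx", 0, strict_lower = TRUE)
  check_scalar_number(fy, "fy", 0, strict_lower = TRUE)
  check_scalar_number(width, "width", 3)
  check_scalar_number(height, "height", 3)
  check_scalar_number(cx, "cx", 0, width - 1e-9)
  check_scalar_number(cy, "cy", 0, height - 1e-9)
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy,
         width = as.integer(width), height = as.integer(height)),
    class = "camera_intrinsics"
  )
}

#' Default depth-camera intrinsics
#'
#' Intrinsics for a narrow-field-of-view time-of-flight depth sensor
#' (75 x 65 degrees; 640 x 576 at full resolution), the acquisition mode
#' the pipeline is designed around. Focal lengths are derived from the
#' field of view; the principal point is the sensor centre.
#'
#' @param resolution Integer vector `c(width, height)` in pixels.
#' @param hfov_deg,vfov_deg Horizontal/vertical field of view in degrees.
#' @return A [camera_intrinsics()] object.
#' @export
default_intrinsics <- function(resolution = c(640L, 576L),
                               hfov_deg = 75, vfov_deg = 65) {
  w <- resolution[1]; h <- resolution[2]
  camera_intrinsics(
    fx = (w / 2) / tan(hfov_deg / 2 * pi / 180),
    fy = (h / 2) / tan(vfov_deg / 2 * pi / 180),
    cx = (w - 1) / 2, cy = (h - 1) / 2,
    width = w, height = h
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> %dx%d px, fx=%.2f fy=%.2f cx=%.2f cy=%.2f\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Unproject depth pixels to 3D points
#'
#' Maps pixel coordinates plus measured depth to camera-centred 3D
#' coordinates (mm): `x = (u - cx) d / fx`, `y = (v - cy) d / fy`,
#' `z = d`.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param u,v 0-based pixel column(s)/row(s); vectorised.
#' @param d Depth(s) in mm; must be strictly positive.
#' @return A numeric matrix with columns `x`, `y`, `z` (mm), one row per
#'   input pixel.
#' @export
unproject <- function(intr, u, v, d) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  n <- max(length(u), length(v), length(d))
  u <- rep_len(u, n); v <- rep_len(v, n); d <- rep_len(d, n)
  if (any(u < 0 | u >= intr$width | v < 0 | v >= intr$height))
    stop_depthresp("bounds", "pixel coordinates outside the sensor")
  if (any(!is.finite(d) | d <= 0))
    stop_depthresp("invalid_pixel", "non-positive depth marks an invalid pixel")
  cbind(x = (u - intr$cx) * d / intr$fx,
        y = (v - intr$cy) * d / intr$fy,
        z = d)
}

#' Project 3D points back to the image plane
#'
#' Inverse of [unproject()]: `u = x fx / z + cx`, `v = y fy / z + cy`.
#' Used mainly to verify the unprojection round trip.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param points Matrix with columns `x`, `y`, `z` (mm), `z > 0`.
#' @return Matrix with columns `u`, `v` (pixels, 0-based, fractional).
#' @export
project_points <- function(intr, points) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  points <- rbind(points)
  z <- points[, 3]
  if (any(z <= 0))
    stop_depthresp("invalid_pixel", "points behind the camera cannot project")
  cbind(u = points[, 1] * intr$fx / z + intr$cx,
        v = points[, 2] * intr$fy / z + intr$cy)
}

# Unproject a pixel if valid, else NULL. Depths are taken from the frame.
.unproject_or_null <- function(intr, frame, u, v) {
  if (u < 0 || u >= intr$width || v < 0 || v >= intr$height) return(NULL)
  d <- frame[u + 1L, v + 1L]
  if (!is.finite(d) || d <= 0) return(NULL)
  c((u - intr$cx) * d / intr$fx, (v - intr$cy) * d / intr$fy, d)
}

#' Surface area of a single depth pixel
#'
#' Estimates the 3D surface area (mm^2) covered by one pixel from its
#' immediate neighbours: the neighbours at `(u +/- 1, v)` and
#' `(u, v +/- 1)` are unprojected at their own measured depths, the two
#' central-difference tangent vectors are formed, and the area is the
#' magnitude of their cross product. At frame borders, or where one
#' neighbour is invalid, a one-sided difference against the centre pixel
#' is used instead. The cross product correctly accounts for surface
#' tilt, which a naive product of pixel spacings does not.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param frame Depth frame in mm: a `width x height` matrix indexed
#'   `[u + 1, v + 1]`; values `<= 0` mark invalid pixels.
#' @param u,v 0-based pixel coordinates (scalar).
#' @return Pixel area in mm^2.
#' @examples
#' intr <- camera_intrinsics(500, 500, 320, 288, 640, 576)
#' frame <- matrix(1000, 640, 576)
#' pixel_area(intr, frame, 320, 288)   # d^2/(fx fy) = 4 mm^2
#' @export
pixel_area <- function(intr, frame, u, v) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  p0 <- .unproject_or_null(intr, frame, u, v)
  if (is.null(p0))
    stop_depthresp("invalid_pixel", sprintf("pixel (%d, %d) has no valid depth", u, v))
  tangent <- function(pp, pm) {
    if (!is.null(pp) && !is.null(pm)) (pp - pm) / 2
    else if (!is.null(pp)) pp - p0
    else if (!is.null(pm)) p0 - pm
    else NULL
  }
  tu <- tangent(.unproject_or_null(intr, frame, u + 1L, v),
                .unproject_or_null(intr, frame, u - 1L, v))
  tv <- tangent(.unproject_or_null(intr, frame, u, v + 1L),
                .unproject_or_null(intr, frame, u, v - 1L))
  if (is.null(tu) || is.null(tv))
    stop_depthresp("invalid_pixel",
                   sprintf("pixel (%d, %d) has no valid neighbour on one axis", u, v))
  cr <- c(tu[2] * tv[3] - tu[3] * tv[2],
          tu[3] * tv[1] - tu[1] * tv[3],
          tu[1] * tv[2] - tu[2] * tv[1])
  sqrt(sum(cr^2))
}

# shift a width x height matrix by one pixel along u (du) and v (dv),
# filling the exposed border with NA
.shift2 <- function(m, du, dv) {
  w <- nrow(m); h <- ncol(m)
  out <- matrix(NA_real_, w, h)
  us <- seq_len(w) + du; vs <- seq_len(h) + dv
  ok_u <- us >= 1 & us <= w; ok_v <- vs >= 1 & vs <= h
  out[ok_u, ok_v] <- m[us[ok_u], vs[ok_v]]
  out
}

#' Per-pixel area map over an ROI
#'
#' Computes [pixel_area()] for every ROI pixel of a reference frame in
#' one vectorised pass. The map is computed once per acquisition, on the
#' reference (first) frame, and reused for all frames: freezing the area
#' yields a volume signal unaffected by frame-to-frame area jitter.
#'
#' ROI pixels whose reference depth is invalid (or that have no valid
#' neighbour along one axis) are removed from the effective mask and
#' counted in `dropped`.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param reference_frame Depth frame in mm (`width x height` matrix).
#' @param roi_mask Logical matrix of the same shape.
#' @return An `area_map` object: list with `area` (matrix, mm^2, zero
#'   outside the effective mask), `mask` (effective logical mask) and
#'   `dropped` (number of ROI pixels removed).
#' @export
area_map <- function(intr, reference_frame, roi_mask) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (!all(dim(reference_frame) == c(intr$width, intr$height)))
    stop_depthresp("config", "reference frame does not match the intrinsics' resolution")
  if (!all(dim(roi_mask) == dim(reference_frame)))
    stop_depthresp("config", "roi_mask shape differs from the frame")
  roi_mask <- roi_mask & TRUE
  n_roi <- sum(roi_mask)
  if (n_roi == 0L) stop_depthresp("empty_roi", "ROI mask is empty")

  z <- reference_frame
  z[!is.finite(z) | z <= 0] <- NA_real_
  w <- intr$width; h <- intr$height
  ug <- matrix(0:(w - 1L), w, h)
  vg <- matrix(0:(h - 1L), w, h, byrow = TRUE)
  x <- (ug - intr$cx) * z / intr$fx
  y <- (vg - intr$cy) * z / intr$fy

  axis_tangent <- function(m, du, dv) {
    mp <- .shift2(m, du, dv); mm <- .shift2(m, -du, -dv)
    t_c <- (mp - mm) / 2          # central
    t_p <- mp - m                 # forward one-sided
    t_m <- m - mm                 # backward one-sided
    t_c[is.na(t_c)] <- t_p[is.na(t_c)]
    t_c[is.na(t_c)] <- t_m[is.na(t_c)]
    t_c
  }
  tux <- axis_tangent(x, 1L, 0L); tuy <- axis_tangent(y, 1L, 0L)
  tuz <- axis_tangent(z, 1L, 0L)
  tvx <- axis_tangent(x, 0L, 1L); tvy <- axis_tangent(y, 0L, 1L)
  tvz <- axis_tangent(z, 0L, 1L)

  crx <- tuy * tvz - tuz * tvy
  cry <- tuz * tvx - tux * tvz
  crz <- tux * tvy - tuy * tvx
  area <- sqrt(crx^2 + cry^2 + crz^2)

  ok <- !is.na(z) & !is.na(area)
  eff <- roi_mask & ok
  dropped <- n_roi - sum(eff)
  if (!any(eff))
    stop_depthresp("empty_roi", "no ROI pixel has a valid reference depth")
  area[!eff] <- 0
  structure(list(area = area, mask = eff, dropped = dropped),
            class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  cat(sprintf("<area_map> %d pixels, total %.1f mm^2, %d dropped\n",
              sum(x$mask), sum(x$area), x$dropped))
  invisible(x)
}
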