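#' Depth-frame sequence
#'
#' An ordered set of depth frames at a fixed frame rate, with the camera
#' intrinsics they were acquired under. Frames are stored internally as
#' integer matrices in units of 0.1 mm (the container's quantisation;
#' value 0 marks an invalid pixel) and exposed in mm via [get_frame()].
#'
#' @param frames List of `width x height` matrices. Numeric matrices are
#'   interpreted as mm and quantised to 0.1 mm (round half to even);
#'   integer matrices are taken to be 0.1 mm units already.
#' @param fps Frame rate (frames/s, > 0).
#' @param intrinsics A [camera_intrinsics()] object matching the frame
#'   dimensions.
#' @param meta Optional list of provenance metadata (e.g. the phantom
#'   configuration for synthetic sequences).
#' @return A `depth_sequence` object.
#' @export
depth_sequence <- function(frames, fps, intrinsics, meta = list()) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"), is.list(frames))
  if (length(frames) == 0L)
    stop_depthresp("config", "a depth sequence needs at least one frame")
  check_scalar_number(fps, "fps", 0, strict_lower = TRUE)
  dims <- c(intrinsics$width, intrinsics$height)
  frames <- lapply(seq_along(frames), function(k) {
    f <- frames[[k]]
    if (!is.matrix(f) || !all(dim(f) == dims))
      stop_depthresp("format", sprintf(
        "frame %d is not a %dx%d matrix", k, dims[1], dims[2]))
    if (is.integer(f)) f
    else matrix(as.integer(round(f * 10)), dims[1], dims[2])
  })
  structure(list(frames = frames, fps = fps, intrinsics = intrinsics,
                 width = dims[1], height = dims[2],
                 depth_scale = 0.1, meta = meta),
            class = "depth_sequence")
}

#' Number of frames in a depth sequence
#' @param sequence A [depth_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(sequence) length(sequence$frames)

#' Extract one depth frame in mm
#'
#' @param sequence A [depth_sequence()].
#' @param k Frame index (1-based).
#' @return `width x height` numeric matrix of depths in mm; 0 marks
#'   invalid pixels.
#' @export
get_frame <- function(sequence, k) {
  stopifnot(inherits(sequence, "depth_sequence"))
  if (k < 1 || k > n_frames(sequence))
    stop_depthresp("bounds", sprintf("frame index %d out of range", k))
  sequence$frames[[k]] * sequence$depth_scale
}

#' @export
print.depth_sequence <- function(x, ...) {
  cat(sprintf("<depth_sequence> %d frames, %dx%d px @ %g FPS (%.1f s)\n",
              n_frames(x), x$width, x$height, x$fps, n_frames(x) / x$fps))
  invisible(x)
}

# time stamps of the sequence/series samples, starting at 0
series_time <- function(n, fps) (seq_len(n) - 1L) / fps

#' Denoised reference surface for area mapping
#'
#' Per-pixel temporal mean of the first `n_frames` valid depths. The
#' per-pixel 3D area is a cross product of neighbour differences, so
#' independent depth noise of sd sigma inflates it by roughly
#' `sigma^2 (1/dx^2 + 1/dy^2) / 2` (dx, dy the 3D pixel spacings) if a
#' single raw frame is used; averaging ~2 s of frames suppresses this
#' bias to negligible levels while the breathing excursion (a few mm
#' against ~1 m of depth) leaves the surface geometry essentially
#' unchanged. Pixels with no valid sample in the window stay invalid.
#'
#' @param sequence A [depth_sequence()].
#' @param n_frames Number of leading frames to average; default two
#'   seconds of recording (capped at the sequence length).
#' @return `width x height` numeric matrix of depths in mm (0 where a
#'   pixel was never valid).
#' @export
reference_surface <- function(sequence, n_frames = NULL) {
  stopifnot(inherits(sequence, "depth_sequence"))
  nf <- n_frames(sequence)
  if (is.null(n_frames)) n_frames <- min(nf, as.integer(ceiling(2 * sequence$fps)))
  n_frames <- max(1L, min(n_frames, nf))
  acc <- matrix(0, sequence$width, sequence$height)
  cnt <- matrix(0, sequence$width, sequence$height)
  for (k in seq_len(n_frames)) {
    x <- sequence$frames[[k]] * sequence$depth_scale
    ok <- x > 0
    acc <- acc + x * ok
    cnt <- cnt + ok
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- 0
  out
}
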