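# Sequence container: a directory holding sidecar.json plus one binary
# blob per frame (frames/frame_NNNNNN.u16, 16-bit unsigned little-endian,
# row-major in u, depth in 0.1 mm units, 0 = invalid). The 0.1 mm integer
# quantisation preserves sensor-scale precision in a compact,
# platform-independent form.

CONTAINER_VERSION <- 1L

.pack_u16 <- function(x) {
  v <- as.integer(x)
  if (any(v < 0L | v > 65535L))
    stop_depthresp("format", "depth value outside the 16-bit container range")
  r <- raw(2L * length(v))
  r[c(TRUE, FALSE)] <- as.raw(v %% 256L)
  r[c(FALSE, TRUE)] <- as.raw(v %/% 256L)
  r
}

.frame_file <- function(dir, k) file.path(dir, "frames", sprintf("frame_%06d.u16", k))

#' Write a depth sequence container
#'
#' Serialises a [depth_sequence()] to a directory: `sidecar.json` with
#' the acquisition metadata (format version, intrinsics, frame rate,
#' frame count, depth unit and invalid-pixel convention, plus the
#' generating seed/configuration for synthetic sequences) and one
#' 16-bit little-endian blob per frame under `frames/`. Depths are
#' quantised to 0.1 mm (round half to even) on write; a write-read
#' round trip is bit-identical.
#'
#' @param sequence A [depth_sequence()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(sequence, path) {
  stopifnot(inherits(sequence, "depth_sequence"))
  dir.create(file.path(path, "frames"), recursive = TRUE, showWarnings = FALSE)
  intr <- sequence$intrinsics
  sidecar <- list(
    format_version = CONTAINER_VERSION,
    intrinsics = list(fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
                      width = intr$width, height = intr$height,
                      depth_unit = "mm"),
    fps = sequence$fps,
    frame_count = n_frames(sequence),
    depth_scale = sequence$depth_scale,
    invalid_value = 0L)
  if (isTRUE(sequence$meta$synthetic)) {
    cfg <- sequence$meta$config
    sidecar$synthetic <- list(
      seed = sequence$meta$seed,
      preset = cfg$preset, vt_true = cfg$vt_true, rr_true = cfg$rr_true,
      insp_fraction = cfg$insp_fraction, bed_distance = cfg$bed_distance,
      torso_center = cfg$torso_center, torso_semi_axes = cfg$torso_semi_axes,
      baseline_height = cfg$baseline_height, noise_sigma = cfg$noise_sigma,
      duration = cfg$duration)
  }
  jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_len(n_frames(sequence))) {
    con <- file(.frame_file(path, k), "wb")
    writeBin(.pack_u16(sequence$frames[[k]]), con)
    close(con)
  }
  invisible(path)
}

#' Read a depth sequence container
#'
#' Validates and loads a container written by [write_sequence()].
#' Shape or version mismatches raise a format error naming the failing
#' frame.
#'
#' @param path Container directory.
#' @return A [depth_sequence()].
#' @export
read_sequence <- function(path) {
  sidecar_path <- file.path(path, "sidecar.json")
  if (!file.exists(sidecar_path))
    stop_depthresp("format", sprintf("no sidecar.json under '%s'", path))
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$format_version) || sc$format_version != CONTAINER_VERSION)
    stop_depthresp("format", sprintf("unsupported format_version '%s'",
                                     sc$format_version))
  intr <- camera_intrinsics(sc$intrinsics$fx, sc$intrinsics$fy,
                            sc$intrinsics$cx, sc$intrinsics$cy,
                            sc$intrinsics$width, sc$intrinsics$height)
  npix <- intr$width * intr$height
  frames <- vector("list", sc$frame_count)
  for (k in seq_len(sc$frame_count)) {
    f <- .frame_file(path, k)
    if (!file.exists(f) || file.size(f) != 2 * npix)
      stop_depthresp("format", sprintf(
        "frame %d: missing or truncated blob (expected %d bytes)", k, 2 * npix))
    con <- file(f, "rb")
    v <- readBin(con, "integer", n = npix, size = 2L, signed = FALSE,
                 endian = "little")
    close(con)
    frames[[k]] <- matrix(v, intr$width, intr$height)
  }
  meta <- if (!is.null(sc$synthetic))
    list(synthetic = TRUE, seed = sc$synthetic$seed, sidecar = sc$synthetic)
  else list()
  depth_sequence(frames, sc$fps, intr, meta = meta)
}

#' Write phantom ground truth
#'
#' Writes the per-frame trace as CSV (`time_s`, `true_volume_ml`,
#' `true_flow_ml_s`) and the scalar cycle parameters as a JSON sidecar
#' next to it (same path with extension `.json`).
#'
#' @param truth A `ground_truth` object.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(truth$table, path, row.names = FALSE)
  scal <- truth[setdiff(names(truth), "table")]
  jsonlite::write_json(scal, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read phantom ground truth
#'
#' Loads a ground-truth CSV; scalar parameters come from the JSON
#' sidecar when present and are otherwise recovered from the clean
#' trace itself (tidal volume as the trace's range, rate and phase
#' times by running cycle detection on the noise-free signal).
#'
#' @param path CSV file path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("time_s", "true_volume_ml", "true_flow_ml_s")
  if (!all(need %in% names(tab)))
    stop_depthresp("format", "ground-truth CSV lacks the expected columns")
  fps <- 1 / stats::median(diff(tab$time_s))
  jpath <- sub("\\.csv$", ".json", path)
  if (file.exists(jpath)) {
    scal <- jsonlite::read_json(jpath, simplifyVector = TRUE)
    out <- c(list(table = tab), scal)
  } else {
    vs <- volume_series(tab$time_s, tab$true_volume_ml, fps)
    mk <- detect_cycles(vs, fps, prominence_fraction = 0.5)
    ph <- phase_times(mk)
    out <- list(table = tab,
                vt = max(tab$true_volume_ml) - min(tab$true_volume_ml),
                rr = respiratory_rate(mk),
                ti = ph$mean_ti, te = ph$mean_te, ie = ph$ie_ratio,
                fps = fps)
  }
  structure(out, class = "ground_truth")
}

#' Serialise a respiratory report to JSON
#'
#' Stable field names matching the report object; numbers keep full
#' precision so a write-read round trip is lossless.
#'
#' @param report A [assemble_report()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "respiratory_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a respiratory report from JSON
#' @param path File written by [write_report()].
#' @return A `respiratory_report` object.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cycles <- as.data.frame(x$cycles)
  structure(x, class = "respiratory_report")
}

#' Export a volume series as CSV
#'
#' Columns `time_s`, `volume_ml`; with `raw` supplied, a third column
#' `raw_volume_ml` carries the uninverted camera-to-thorax volume.
#'
#' @param series A [volume_series()] (post inversion/zeroing).
#' @param path Output file.
#' @param raw Optional raw [volume_series()] on the same time base.
#' @return `path`, invisibly.
#' @export
write_volume_csv <- function(series, path, raw = NULL) {
  tab <- data.frame(time_s = series$time, volume_ml = series$volume)
  if (!is.null(raw)) tab$raw_volume_ml <- raw$volume
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export a flow series as CSV (columns `time_s`, `flow_ml_s`)
#' @param flow A [compute_flow()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, path) {
  utils::write.csv(data.frame(time_s = flow$time, flow_ml_s = flow$flow),
                   path, row.names = FALSE)
  invisible(path)
}
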