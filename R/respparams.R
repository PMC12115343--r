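#' Respiratory rate
#'
#' Number of complete cycles divided by the time they span (start of
#' the first cycle to end of the last), scaled to breaths/min. Using
#' the complete-cycle span as the denominator keeps the exact identity
#' `minute ventilation = mean Vt x RR`.
#'
#' @param markers A [detect_cycles()] result.
#' @param fps Frame rate (defaults to the markers' rate).
#' @return Respiratory rate in breaths/min.
#' @export
respiratory_rate <- function(markers, fps = markers$fps) {
  stopifnot(inherits(markers, "cycle_markers"))
  cyc <- markers$cycles
  if (nrow(cyc) == 0L) stop_depthresp("no_cycle", "no complete cycle")
  span <- cyc$t_end[nrow(cyc)] - cyc$t_start[1]
  nrow(cyc) / span * 60
}

#' Per-cycle tidal volumes
#'
#' Tidal volume is the peak-to-trough volume excursion of a cycle. The
#' default expiratory definition -- volume at the peak minus volume at
#' the cycle's ending trough -- measures the air exhaled during the
#' cycle; the inspiratory variant (peak minus starting trough) is
#' available and agrees with it for symmetric breathing.
#'
#' @param filtered The filtered [volume_series()] the markers were
#'   detected on.
#' @param markers A [detect_cycles()] result.
#' @param convention `"expiratory"` (default) or `"inspiratory"`.
#' @return Numeric vector of per-cycle tidal volumes, mL.
#' @export
tidal_volumes <- function(filtered, markers,
                          convention = c("expiratory", "inspiratory")) {
  stopifnot(inherits(filtered, "volume_series"),
            inherits(markers, "cycle_markers"))
  convention <- match.arg(convention)
  cyc <- markers$cycles
  v <- filtered$volume
  ref <- if (convention == "expiratory") cyc$i_end else cyc$i_start
  v[cyc$i_peak] - v[ref]
}

#' Minute ventilation
#'
#' Sum of all complete-cycle tidal volumes divided by the span of those
#' cycles, normalised to one minute (mL/min). Identical to
#' `mean(vt) x respiratory_rate(markers)` by construction.
#'
#' @param vts Per-cycle tidal volumes from [tidal_volumes()].
#' @param markers A [detect_cycles()] result.
#' @return Minute ventilation in mL/min.
#' @export
minute_ventilation <- function(vts, markers) {
  stopifnot(inherits(markers, "cycle_markers"))
  cyc <- markers$cycles
  if (nrow(cyc) == 0L) stop_depthresp("no_cycle", "no complete cycle")
  span <- cyc$t_end[nrow(cyc)] - cyc$t_start[1]
  sum(vts) / span * 60
}

#' Inspiratory/expiratory times and I:E ratio
#'
#' Per cycle, the inspiratory time runs from the starting trough to the
#' peak and the expiratory time from the peak to the ending trough. The
#' I:E ratio follows the ventilator convention of setting inspiration
#' to 1: `1 : (mean Te / mean Ti)`.
#'
#' @param markers A [detect_cycles()] result.
#' @return List with `mean_ti`, `mean_te` (s), `ie_ratio` (the `x` in
#'   `1 : x`) and per-cycle vectors `ti`, `te`.
#' @export
phase_times <- function(markers) {
  stopifnot(inherits(markers, "cycle_markers"))
  cyc <- markers$cycles
  ti <- cyc$t_peak - cyc$t_start
  te <- cyc$t_end - cyc$t_peak
  list(mean_ti = mean(ti), mean_te = mean(te),
       ie_ratio = mean(te) / mean(ti), ti = ti, te = te)
}

#' Per-cycle peak inspiratory and expiratory flows
#'
#' Two conventions are reported. Under `"difference"` (default), peak flows
#' are flow-extremum differences: PEF is the cycle's flow maximum minus
#' the flow minimum that follows it (expiratory drop), and PIF is the
#' flow maximum minus the preceding cycle's flow minimum (the opposite
#' direction; for the first cycle, where no preceding minimum exists,
#' its own minimum is used). These differences are about twice the
#' conventional ventilator reading. Under `"standard"`, PIF is the
#' maximum flow during inspiration and PEF the maximum expiratory flow
#' magnitude, directly comparable to ventilator displays.
#'
#' @param flow A [compute_flow()] result.
#' @param markers A [detect_cycles()] result.
#' @param convention `"difference"` or `"standard"`.
#' @return Data frame with per-cycle `pif` and `pef` (mL/s); `NA` where
#'   a cycle contains no flow excursion.
#' @export
peak_flows <- function(flow, markers, convention = c("difference", "standard")) {
  stopifnot(inherits(flow, "flow_series"), inherits(markers, "cycle_markers"))
  convention <- match.arg(convention)
  cyc <- markers$cycles
  nc <- nrow(cyc)
  pif <- pef <- rep(NA_real_, nc)
  if (convention == "standard") {
    for (k in seq_len(nc)) {
      insp <- flow$flow[cyc$i_start[k]:cyc$i_peak[k]]
      expn <- flow$flow[cyc$i_peak[k]:cyc$i_end[k]]
      if (diff(range(flow$flow[cyc$i_start[k]:cyc$i_end[k]])) > 0) {
        pif[k] <- max(insp)
        pef[k] <- -min(expn)
      }
    }
  } else {
    fmax <- fmin <- rep(NA_real_, nc)
    for (k in seq_len(nc)) {
      seg <- flow$flow[cyc$i_start[k]:cyc$i_end[k]]
      if (diff(range(seg)) > 0) { fmax[k] <- max(seg); fmin[k] <- min(seg) }
    }
    pef <- fmax - fmin
    prev_min <- c(fmin[1], fmin[-nc])
    pif <- fmax - prev_min
  }
  data.frame(pif = pif, pef = pef)
}

#' Assemble the respiratory parameter report
#'
#' Aggregates all cycle-level quantities into the ventilator-equivalent
#' report: respiratory rate, mean tidal volume, minute ventilation,
#' mean inspiratory/expiratory times, I:E ratio, mean peak flows, the
#' per-cycle table, and quality flags (frame dropout, cycles touching
#' the filter edge region).
#'
#' @param filtered The filtered [volume_series()].
#' @param flow The matching [compute_flow()] result.
#' @param markers A [detect_cycles()] result.
#' @param vt_convention Passed to [tidal_volumes()].
#' @param flow_convention Passed to [peak_flows()].
#' @param extra_quality Optional named list merged into the quality
#'   block (e.g. ROI provenance).
#' @return A `respiratory_report` object.
#' @export
assemble_report <- function(filtered, flow, markers,
                            vt_convention = "expiratory",
                            flow_convention = "difference",
                            extra_quality = list()) {
  vts <- tidal_volumes(filtered, markers, vt_convention)
  ph <- phase_times(markers)
  pfl <- peak_flows(flow, markers, flow_convention)
  cyc <- markers$cycles
  cycles <- data.frame(t_start = cyc$t_start, t_peak = cyc$t_peak,
                       t_end = cyc$t_end, vt = vts,
                       ti = ph$ti, te = ph$te,
                       pif = pfl$pif, pef = pfl$pef)
  edge <- filtered$meta$edge_region
  edge_cycles <- if (is.null(edge)) 0L else
    sum(cyc$i_start <= max(utils::head(edge, length(edge) / 2), 0) |
          cyc$i_end >= min(utils::tail(edge, length(edge) / 2), Inf))
  held <- filtered$meta$held_fraction
  quality <- c(list(
    n_samples = length(filtered$volume),
    edge_cycles = edge_cycles,
    max_held_fraction = if (is.null(held)) 0 else max(held),
    quality_warning = isTRUE(filtered$meta$quality_warning)),
    extra_quality)
  structure(list(
    rr = respiratory_rate(markers),
    mean_vt = mean(vts),
    minute_ventilation = minute_ventilation(vts, markers),
    mean_ti = ph$mean_ti, mean_te = ph$mean_te, ie_ratio = ph$ie_ratio,
    mean_pif = mean(pfl$pif, na.rm = TRUE),
    mean_pef = mean(pfl$pef, na.rm = TRUE),
    n_cycles = nrow(cycles),
    cycles = cycles,
    conventions = list(vt = vt_convention, flow = flow_convention),
    quality = quality),
    class = "respiratory_report")
}

#' @export
print.respiratory_report <- function(x, ...) {
  cat("<respiratory_report>\n")
  cat(sprintf("  RR     %6.1f breaths/min   (%d complete cycles)\n",
              x$rr, x$n_cycles))
  cat(sprintf("  Vt     %6.1f mL            MV %7.0f mL/min\n",
              x$mean_vt, x$minute_ventilation))
  cat(sprintf("  Ti     %6.2f s   Te %5.2f s   I:E  1:%.2f\n",
              x$mean_ti, x$mean_te, x$ie_ratio))
  cat(sprintf("  PIF    %6.0f mL/s  PEF %6.0f mL/s  (%s convention)\n",
              x$mean_pif, x$mean_pef, x$conventions$flow))
  invisible(x)
}

#' Compare a report and volume series against phantom ground truth
#'
#' Error metrics for parameter-recovery experiments: Pearson
#' correlation between the estimated and true volume waveforms
#' (computed outside the filter edge region; correlation is invariant
#' to the different zero references), mean absolute percentage error of
#' per-cycle tidal volume, respiratory-rate error, and minute-
#' ventilation percentage error (true minute ventilation being
#' `true vt x true rr`).
#'
#' @param report A [assemble_report()] result.
#' @param series The estimated [volume_series()] on the phantom's time
#'   base.
#' @param truth A `ground_truth` object from [generate_sequence()].
#' @return List with `pearson_r`, `vt_mape_pct`, `rr_error_bpm`,
#'   `mev_error_pct`.
#' @export
evaluate_against_truth <- function(report, series, truth) {
  stopifnot(inherits(report, "respiratory_report"),
            inherits(series, "volume_series"),
            inherits(truth, "ground_truth"))
  tv <- truth$table$true_volume_ml
  if (length(tv) != length(series$volume))
    stop_depthresp("alignment", sprintf(
      "series (%d) and truth (%d) lengths differ",
      length(series$volume), length(tv)))
  keep <- setdiff(seq_along(tv), series$meta$edge_region)
  r <- stats::cor(series$volume[keep], tv[keep])
  vt_mape <- mean(abs(report$cycles$vt - truth$vt) / truth$vt) * 100
  mev_true <- truth$vt * truth$rr
  list(pearson_r = r,
       vt_mape_pct = vt_mape,
       rr_error_bpm = report$rr - truth$rr,
       mev_error_pct = (report$minute_ventilation - mev_true) / mev_true * 100)
}
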