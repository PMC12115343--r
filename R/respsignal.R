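#' FIR filter specification
#'
#' Low-pass specification for the respiratory signal: order 10 (11
#' symmetric taps) with a 2 Hz cutoff by default -- 2 Hz corresponds to
#' 120 breaths/min, the physiological maximum respiratory rate, so
#' everything above it is treated as noise. The order must be even so
#' the group delay is an integer number of samples.
#'
#' @param fps Sampling rate, frames/s.
#' @param order Filter order (taps - 1); even.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(fps, order = 10L, cutoff_hz = 2) {
  check_scalar_number(fps, "fps", 0, strict_lower = TRUE)
  check_scalar_number(order, "order", 2)
  if (order %% 2 != 0)
    stop_depthresp("config", "filter order must be even (integer group delay)")
  if (cutoff_hz <= 0 || cutoff_hz >= fps / 2)
    stop_depthresp("config", sprintf(
      "cutoff %g Hz outside (0, Nyquist = %g Hz)", cutoff_hz, fps / 2))
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz, fps = fps),
            class = "filter_spec")
}

#' Windowed-sinc FIR low-pass coefficients
#'
#' Linear-phase low-pass design by the window method: the ideal sinc
#' impulse response truncated to `order + 1` taps, weighted by a Hamming
#' window, and normalised to exactly unit DC gain (the coefficients sum
#' to 1, so a constant signal passes unchanged).
#'
#' @param spec A [filter_spec()].
#' @return Numeric vector of `order + 1` symmetric coefficients.
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  m <- 0:spec$order
  k <- m - spec$order / 2
  fc <- spec$cutoff_hz / spec$fps
  hd <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  win <- 0.54 - 0.46 * cos(2 * pi * m / spec$order)
  h <- hd * win
  h / sum(h)
}

#' FIR magnitude response
#'
#' @param coef Filter coefficients.
#' @param freq_hz Frequencies at which to evaluate (vectorised).
#' @param fps Sampling rate, frames/s.
#' @return Magnitude response `|H(f)|`.
#' @export
fir_response <- function(coef, freq_hz, fps) {
  vapply(freq_hz, function(f)
    Mod(sum(coef * exp(-2i * pi * f * (seq_along(coef) - 1) / fps))),
    numeric(1))
}

#' Low-pass filter a volume series
#'
#' Convolves the series with the [design_fir()] kernel. In the default
#' offline mode the output is shifted back by the filter's group delay
#' (`order/2` samples) so it stays aligned with the input timestamps;
#' the first and last `order/2` samples, where the kernel is truncated
#' (and renormalised over the available samples), are flagged as the
#' edge region in `meta$edge_region`. With `causal = TRUE` no
#' compensation is applied (streaming use; output lags by the group
#' delay).
#'
#' @param series A [volume_series()].
#' @param spec A [filter_spec()]; defaults to the standard order-10,
#'   2 Hz design at the series' frame rate.
#' @param causal Logical; skip group-delay compensation.
#' @return A filtered [volume_series()].
#' @export
filter_volume <- function(series, spec = filter_spec(series$fps),
                          causal = FALSE) {
  stopifnot(inherits(series, "volume_series"), inherits(spec, "filter_spec"))
  x <- series$volume
  n <- length(x)
  if (n <= spec$order)
    stop_depthresp("config", sprintf(
      "series of %d samples too short for an order-%d filter", n, spec$order))
  h <- design_fir(spec)
  half <- spec$order / 2
  y <- as.numeric(stats::filter(x, h, sides = 2))
  # truncated-kernel, renormalised edges
  for (i in seq_len(half)) {
    lo <- h[(half - i + 2):length(h)]
    y[i] <- sum(lo * x[1:(i + half)]) / sum(lo)
    hi <- h[1:(half + i)]
    y[n - i + 1] <- sum(hi * x[(n - i + 1 - half):n]) / sum(hi)
  }
  if (causal) {
    y <- c(rep(y[1], half), y[1:(n - half)])
    edge <- seq_len(spec$order)
  } else {
    edge <- c(seq_len(half), n - half + seq_len(half))
  }
  meta <- series$meta
  meta$filtered <- TRUE
  meta$filter <- spec
  meta$edge_region <- edge
  volume_series(series$time, y, series$fps, meta)
}

#' Minimum peak separation in frames
#'
#' Converts the maximum physiological respiratory rate into the minimum
#' number of frames between consecutive detected peaks:
#' `round(fps * 60 / max_rr)` (half rounds up). At 30 FPS with the
#' 120 breaths/min maximum this is 15 frames (one peak per 0.5 s).
#'
#' @param fps Frame rate, frames/s.
#' @param max_rr Maximum expected respiratory rate, breaths/min.
#' @return Integer number of frames.
#' @export
min_distance_frames <- function(fps, max_rr = 120) {
  check_scalar_number(fps, "fps", 0, strict_lower = TRUE)
  check_scalar_number(max_rr, "max_rr", 0, strict_lower = TRUE)
  as.integer(floor(fps * 60 / max_rr + 0.5))
}

# Local maxima with plateau handling (leftmost sample), minimum
# inter-peak distance (greedy, highest first) and minimum prominence
# (extend left/right to the nearest higher point or series end; the
# prominence base is the higher of the two interval minima).
find_signal_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)  # leftmost of plateau
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(cand) == 0L) return(integer(0))

  if (min_distance > 1L && length(cand) > 1L) {
    keep <- rep(TRUE, length(cand))
    for (o in order(x[cand], decreasing = TRUE)) {
      if (!keep[o]) next
      too_close <- keep & abs(cand - cand[o]) < min_distance &
        seq_along(cand) != o
      keep[too_close] <- FALSE
    }
    cand <- cand[keep]
  }

  if (min_prominence > 0) {
    prom <- vapply(cand, function(p) {
      l <- p
      while (l > 1L && x[l - 1L] <= x[p]) l <- l - 1L
      r <- p
      while (r < n && x[r + 1L] <= x[p]) r <- r + 1L
      x[p] - max(min(x[l:p]), min(x[p:r]))
    }, numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  cand
}

#' Detect respiratory cycles
#'
#' Finds peaks (end-inspiration) and troughs (end-expiration, via the
#' negated series) in the filtered volume signal. Extrema must be at
#' least [min_distance_frames()] apart and have prominence of at least
#' `prominence_fraction` of the signal's global range (rejecting ripple
#' without suppressing shallow breaths). Flat extrema resolve to their
#' leftmost sample. Peaks and troughs are then merged into a strictly
#' alternating sequence (of two same-kind neighbours the more extreme
#' survives) and paired into complete trough-peak-trough cycles;
#' unpaired leading/trailing extrema are dropped.
#'
#' @param filtered A filtered [volume_series()].
#' @param fps Frame rate (defaults to the series' rate).
#' @param prominence_fraction Minimum prominence as a fraction of the
#'   global signal range.
#' @param max_rr Maximum respiratory rate for the distance rule.
#' @return A `cycle_markers` object: `peak_indices`, `trough_indices`
#'   (1-based frame indices) and `cycles`, a data frame with one row per
#'   complete cycle (`i_start`, `i_peak`, `i_end`, `t_start`, `t_peak`,
#'   `t_end`).
#' @export
detect_cycles <- function(filtered, fps = filtered$fps,
                          prominence_fraction = 0.2, max_rr = 120) {
  stopifnot(inherits(filtered, "volume_series"))
  x <- filtered$volume
  md <- min_distance_frames(fps, max_rr)
  if (length(x) < 2L * md)
    stop_depthresp("no_cycle", sprintf(
      "series of %d samples is shorter than two minimum peak distances (%d)",
      length(x), md))
  rng <- max(x) - min(x)
  if (rng <= 0)
    stop_depthresp("no_cycle", "signal is constant; no respiratory motion")
  prom <- prominence_fraction * rng
  peaks <- find_signal_peaks(x, md, prom)
  troughs <- find_signal_peaks(-x, md, prom)
  if (length(peaks) == 0L || length(troughs) == 0L)
    stop_depthresp("no_cycle", sprintf(
      "found %d peaks and %d troughs; need at least one of each",
      length(peaks), length(troughs)),
      n_peaks = length(peaks), n_troughs = length(troughs))

  ev <- rbind(data.frame(i = peaks, peak = TRUE),
              data.frame(i = troughs, peak = FALSE))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  for (k in seq_len(nrow(ev) - 1L)) {
    if (!keep[k]) next
    nxt <- k + 1L
    while (nxt <= nrow(ev) && !keep[nxt]) nxt <- nxt + 1L
    if (nxt > nrow(ev)) break
    if (ev$peak[k] == ev$peak[nxt]) {
      a <- ev$i[k]; b <- ev$i[nxt]
      drop <- if (ev$peak[k]) { if (x[a] >= x[b]) nxt else k }
              else            { if (x[a] <= x[b]) nxt else k }
      keep[drop] <- FALSE
    }
  }
  ev <- ev[keep, ]

  tr <- ev$i[!ev$peak]; pk <- ev$i[ev$peak]
  cyc <- list()
  for (k in seq_along(tr)[-length(tr)]) {
    p <- pk[pk > tr[k] & pk < tr[k + 1L]]
    if (length(p) == 1L)
      cyc[[length(cyc) + 1L]] <- c(tr[k], p, tr[k + 1L])
  }
  if (length(cyc) == 0L)
    stop_depthresp("no_cycle", sprintf(
      "no complete trough-peak-trough cycle (%d peaks, %d troughs after alternation)",
      length(pk), length(tr)),
      n_peaks = length(pk), n_troughs = length(tr))
  cyc <- do.call(rbind, cyc)
  cycles <- data.frame(i_start = cyc[, 1], i_peak = cyc[, 2], i_end = cyc[, 3])
  cycles$t_start <- filtered$time[cycles$i_start]
  cycles$t_peak <- filtered$time[cycles$i_peak]
  cycles$t_end <- filtered$time[cycles$i_end]
  structure(list(peak_indices = pk, trough_indices = tr,
                 cycles = cycles, fps = fps),
            class = "cycle_markers")
}

#' @export
print.cycle_markers <- function(x, ...) {
  cat(sprintf("<cycle_markers> %d peaks, %d troughs, %d complete cycles\n",
              length(x$peak_indices), length(x$trough_indices),
              nrow(x$cycles)))
  invisible(x)
}

#' Flow series from a volume series
#'
#' The flow is the time derivative of volume: central differences
#' scaled by the frame rate in the interior, one-sided differences at
#' the ends. Units mL/s.
#'
#' @param filtered A [volume_series()] (normally the filtered one, so
#'   the derivative is smooth).
#' @return A `flow_series` object: list with `time`, `flow`, `fps`.
#' @export
compute_flow <- function(filtered) {
  stopifnot(inherits(filtered, "volume_series"))
  x <- filtered$volume
  n <- length(x)
  if (n < 3L) stop_depthresp("config", "need at least 3 samples for a derivative")
  fl <- numeric(n)
  fl[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * filtered$fps
  fl[1] <- (x[2] - x[1]) * filtered$fps
  fl[n] <- (x[n] - x[n - 1]) * filtered$fps
  structure(list(time = filtered$time, flow = fl, fps = filtered$fps),
            class = "flow_series")
}
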