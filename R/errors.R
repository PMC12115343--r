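# Classed conditions so callers can branch on failure mode
# (e.g. detection failure -> fall back to a fixed ROI).

stop_depthresp <- function(subclass, message, ..., call = sys.call(-1)) {
  data <- list(...)
  cond <- structure(
    class = c(paste0("depthresp_", subclass), "depthresp_error",
              "error", "condition"),
    list(message = message, call = call, data = data)
  )
  stop(cond)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_depthresp("config", sprintf("`%s` must be a finite number", name))
  bad_low <- if (strict_lower) x <= lower else x < lower
  if (bad_low || x > upper)
    stop_depthresp("config", sprintf(
      "`%s` = %g outside allowed range %s%g, %g]",
      name, x, if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}
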