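#' Pressure waveform container
#'
#' A single-cycle, uniformly sampled pressure trace at a named arterial
#' site, optionally carrying the concurrent flow trace. All pressures are
#' in mmHg, times in seconds, flows in mL/s.
#'
#' @param time numeric vector of sample times (s), uniformly spaced,
#'   starting at 0.
#' @param pressure numeric vector of pressures (mmHg), same length as
#'   `time`.
#' @param site character site label, e.g. `"aortic_root"`,
#'   `"left_common_carotid"`, `"brachial"`.
#' @param flow optional numeric vector of flows (mL/s).
#' @param period cycle period T = 60/HR (s); defaults to the time span
#'   extended by one sample interval.
#'
#' @return An object of class `pressure_waveform`: a list with elements
#'   `time`, `pressure`, `flow` (may be `NULL`), `site`, `period`.
#' @export
pressure_waveform <- function(time, pressure, site = "unknown", flow = NULL,
                              period = NULL) {
  if (length(time) < 2 && is.null(period))
    period <- if (length(time)) max(time, 1e-3) else 1e-3
  if (length(time) != length(pressure))
    stop_invalid("time and pressure must have equal length")
  if (length(time) >= 2) {
    dt <- diff(time)
    if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
      stop_invalid("time grid must be uniform and increasing")
  }
  if (!is.null(flow) && length(flow) != length(time))
    stop_invalid("flow must match time length")
  if (is.null(period)) {
    dt <- time[2] - time[1]
    period <- max(time) - min(time) + dt
  }
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 flow = if (is.null(flow)) NULL else as.numeric(flow),
                 site = site, period = as.numeric(period)),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("<pressure_waveform> site=%s  n=%d  period=%.3f s  P=[%.1f, %.1f] mmHg%s\n",
              x$site, length(x$time), x$period,
              min(x$pressure), max(x$pressure),
              if (is.null(x$flow)) "" else "  (+flow)"))
  invisible(x)
}

#' Summarize a pressure waveform
#'
#' Extracts systolic (max), diastolic (min), pulse pressure and the
#' time-averaged mean pressure over the cycle (trapezoidal rule over the
#' closed cycle). This waveform-average MAP is distinct from the cuff
#' formula (SBP + 2 DBP)/3 used for calibration.
#'
#' @param wave a [pressure_waveform()].
#' @return A list of class `pressure_summary` with `sbp`, `dbp`, `map`,
#'   `pp` (all mmHg) and `site`.
#' @export
summarize_pressure <- function(wave) {
  stopifnot(inherits(wave, "pressure_waveform"))
  p <- wave$pressure
  if (!length(p)) stop_invalid("empty waveform")
  sbp <- max(p); dbp <- min(p)
  structure(list(sbp = sbp, dbp = dbp, map = cycle_mean(wave$time, p, wave$period),
                 pp = sbp - dbp, site = wave$site),
            class = "pressure_summary")
}

#' @export
print.pressure_summary <- function(x, ...) {
  cat(sprintf("<pressure_summary> %s  SBP %.1f  DBP %.1f  MAP %.1f  PP %.1f mmHg\n",
              x$site, x$sbp, x$dbp, x$map, x$pp))
  invisible(x)
}

# Time average over one closed cycle: trapezoid on the samples plus the
# wrap-around panel from the last sample back to the first at t = period.
cycle_mean <- function(time, x, period = NULL) {
  n <- length(x)
  if (n == 1) return(x)
  if (is.null(period)) period <- max(time) - min(time)
  span <- max(time) - min(time)
  area <- sum((x[-1] + x[-n]) / 2 * diff(time))
  if (period > span + 1e-12) { # wrap-around panel
    area <- area + (x[n] + x[1]) / 2 * (period - span)
    return(area / period)
  }
  area / span
}

#' Write / read waveforms in the shared delimited-text dialect
#'
#' Comma-separated with a one-line header `time_s,pressure_mmhg[,flow_ml_s]`.
#'
#' @param wave a [pressure_waveform()].
#' @param path file path.
#' @rdname waveform_io
#' @export
write_waveform <- function(wave, path) {
  stopifnot(inherits(wave, "pressure_waveform"))
  df <- data.frame(time_s = wave$time, pressure_mmhg = wave$pressure)
  if (!is.null(wave$flow)) df$flow_ml_s <- wave$flow
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param site site label to attach on read.
#' @rdname waveform_io
#' @export
read_waveform <- function(path, site = "unknown") {
  df <- read.csv(path)
  need <- c("time_s", "pressure_mmhg")
  if (!all(need %in% names(df)))
    stop_invalid("waveform file must have columns time_s, pressure_mmhg: ", path)
  pressure_waveform(df$time_s, df$pressure_mmhg, site = site,
                    flow = if ("flow_ml_s" %in% names(df)) df$flow_ml_s else NULL)
}

#' Rotate a periodic waveform to a new time origin
#'
#' Re-references one steady-state cycle so that `t0` becomes t = 0
#' (samples before `t0` wrap to the end of the cycle). Used to express
#' cycles foot-to-foot, so that diastole runs to the cycle end.
#'
#' @param wave a [pressure_waveform()].
#' @param t0 new origin (s) within the cycle.
#' @return the rotated [pressure_waveform()].
#' @export
rotate_waveform <- function(wave, t0) {
  stopifnot(inherits(wave, "pressure_waveform"))
  t <- wave$time
  i0 <- which.min(abs(t - (t0 %% wave$period)))
  idx <- c(seq(i0, length(t)), seq_len(i0 - 1L))
  pressure_waveform(t - t[1], wave$pressure[idx], site = wave$site,
                    flow = if (is.null(wave$flow)) NULL else wave$flow[idx],
                    period = wave$period)
}

# Foot (onset of the systolic upstroke) located by the intersecting-tangent
# method: the steepest-ascent tangent within a quarter cycle after the
# diastolic minimum, intersected with the horizontal through that minimum.
pulse_foot_time <- function(wave) {
  p <- wave$pressure; t <- wave$time
  imin <- which.min(p)
  hi <- min(length(p) - 1L, imin + ceiling(0.25 * wave$period / (t[2] - t[1])))
  dp <- diff(p) / diff(t)
  up <- imin + which.max(dp[imin:hi]) - 1L
  t[up] - (p[up] - p[imin]) / dp[up]
}
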