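#' Two-element Windkessel fixture
#'
#' A 0-D pressure-pulse generator with analytically known decay constant
#' `true_rc = R * C`, used as ground truth for the diastolic-decay
#' estimator. Inflow is a half-sine of duration `ejection_duration`
#' followed by zero flow (closed valve), so the diastolic limb decays as
#' a pure exponential toward the venous reference (0 mmHg) with time
#' constant RC.
#'
#' @param resistance peripheral resistance R (mmHg s/mL).
#' @param compliance total arterial compliance C (mL/mmHg).
#' @param heart_rate beats per minute.
#' @param ejection_duration systolic inflow duration (s); must be shorter
#'   than the cycle period 60/heart_rate.
#' @param peak_inflow peak of the half-sine inflow (mL/s).
#' @param sampling_rate output sampling rate (Hz).
#' @return Object of class `windkessel_fixture` with a `true_rc` field.
#' @export
windkessel_fixture <- function(resistance = 1.0, compliance = 1.14,
                               heart_rate = 73, ejection_duration = 0.3,
                               peak_inflow = 300, sampling_rate = 1000) {
  check_positive(resistance, "resistance")
  check_positive(compliance, "compliance")
  check_positive(heart_rate, "heart_rate")
  check_positive(ejection_duration, "ejection_duration")
  check_positive(peak_inflow, "peak_inflow")
  check_positive(sampling_rate, "sampling_rate")
  if (ejection_duration >= 60 / heart_rate)
    stop_invalid("ejection_duration must be shorter than the cycle period")
  structure(list(resistance = resistance, compliance = compliance,
                 heart_rate = heart_rate, ejection_duration = ejection_duration,
                 peak_inflow = peak_inflow, sampling_rate = sampling_rate,
                 true_rc = resistance * compliance),
            class = "windkessel_fixture")
}

#' Closed-form exponential pressure segment
#'
#' Samples P(t) = p_infinity + (p0 - p_infinity) exp(-t/rc) on a uniform
#' grid including t = 0. This is the exact mono-exponential model that
#' [fit_mono_exponential()] assumes, so it serves as its oracle.
#'
#' @param p_infinity asymptotic pressure (mmHg).
#' @param p0 initial pressure (mmHg); must exceed `p_infinity`.
#' @param rc decay time constant (s), positive.
#' @param duration segment length (s); 0 gives the single sample at t = 0.
#' @param sampling_rate sampling rate (Hz).
#' @return A [pressure_waveform()] at site `"fixture"`.
#' @export
generate_exponential_segment <- function(p_infinity, p0, rc, duration,
                                         sampling_rate = 1000) {
  check_positive(rc, "rc")
  check_positive(sampling_rate, "sampling_rate")
  if (!is.finite(duration) || duration < 0)
    stop_invalid("duration must be non-negative")
  if (duration == 0)
    return(pressure_waveform(0, p0, site = "fixture", period = 1 / sampling_rate))
  if (p0 <= p_infinity) stop_invalid("p0 must exceed p_infinity")
  t <- seq(0, duration, by = 1 / sampling_rate)
  pressure_waveform(t, p_infinity + (p0 - p_infinity) * exp(-t / rc),
                    site = "fixture", period = duration + 1 / sampling_rate)
}

#' Simulate a two-element Windkessel pulse to periodic steady state
#'
#' Integrates C dP/dt = Q(t) - P/R with half-sine systolic inflow by
#' fixed-step RK4 (step <= 0.1 ms), cycle by cycle, until the cycle-to-cycle
#' maximum pressure difference falls below `tol` or `n_cycles` is reached.
#'
#' @param fixture a [windkessel_fixture()].
#' @param n_cycles maximum number of cycles (default 40).
#' @param tol periodicity tolerance on max cycle-to-cycle |dP| (mmHg).
#' @param p_init initial pressure (mmHg); defaults to the steady-state
#'   mean R x mean inflow so that only a small transient remains.
#' @return A [pressure_waveform()] for the final cycle with the inflow in
#'   `$flow`, plus attributes `t_flow_zero` (time inflow reaches zero,
#'   i.e. `ejection_duration`) and `converged`; a warning is signalled
#'   if periodicity was not reached.
#' @export
generate_windkessel_pulse <- function(fixture, n_cycles = 40, tol = 0.01,
                                      p_init = NULL) {
  stopifnot(inherits(fixture, "windkessel_fixture"))
  if (n_cycles < 1) stop_invalid("n_cycles must be >= 1")
  T <- 60 / fixture$heart_rate
  dt <- T / ceiling(T / 1e-4)           # fixed step <= 0.1 ms
  steps <- round(T / dt)
  ed <- fixture$ejection_duration
  R <- fixture$resistance; C <- fixture$compliance
  qfun <- function(t) ifelse(t < ed, fixture$peak_inflow * sin(pi * t / ed), 0)
  if (is.null(p_init))
    p_init <- R * fixture$peak_inflow * (2 / pi) * (ed / T)

  # inflow precomputed on the full- and half-step grid of one cycle
  tgrid <- (0:steps) * dt
  q_full <- qfun(tgrid)                      # t_s and t_{s+1}
  q_half <- qfun(tgrid[-length(tgrid)] + dt / 2)

  out_every <- max(1L, round((1 / fixture$sampling_rate) / dt))
  rec_at <- seq(1L, steps, by = out_every)  # step indices recorded (1-based)
  n_out <- length(rec_at)
  p <- p_init
  prev <- NULL; rec <- numeric(n_out)
  converged <- FALSE
  a <- 1 / (R * C)
  for (cyc in seq_len(n_cycles)) {
    i <- 0L
    for (s in seq_len(steps)) {
      if (s %% out_every == 1L || out_every == 1L) {
        i <- i + 1L; if (i <= n_out) rec[i] <- p
      }
      k1 <- q_full[s] / C - a * p
      k2 <- q_half[s] / C - a * (p + dt / 2 * k1)
      k3 <- q_half[s] / C - a * (p + dt / 2 * k2)
      k4 <- q_full[s + 1] / C - a * (p + dt * k3)
      p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!is.null(prev) && max(abs(rec - prev)) < tol) { converged <- TRUE; break }
    prev <- rec
  }
  trec <- (rec_at - 1L) * dt
  wave <- pressure_waveform(trec, rec, site = "windkessel",
                            flow = qfun(trec), period = T)
  attr(wave, "t_flow_zero") <- ed
  attr(wave, "converged") <- converged
  if (!converged)
    warning(sprintf("Windkessel pulse not periodic after %d cycles", n_cycles))
  wave
}
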