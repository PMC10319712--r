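#' Cardiac parameters for the time-varying-elastance heart
#'
#' Ventricular pressure is modelled as P_lv = E(t) (V - V_d), with E(t)
#' interpolating between end-diastolic and end-systolic elastance along a
#' double-Hill activation peaking at `t_maxE`. The ventricle fills from a
#' constant-pressure venous source through `venous_resistance` and ejects
#' through an ideal diode valve with a small series resistance.
#'
#' @param E_es end-systolic elastance (mmHg/mL).
#' @param E_ed end-diastolic elastance (mmHg/mL).
#' @param filling_pressure venous filling pressure (mmHg).
#' @param heart_rate beats per minute.
#' @param t_maxE time of maximal elastance (s), default 0.340.
#' @param V_d ventricular dead volume (mL), default 15.
#' @param venous_resistance filling resistance (mmHg s/mL), default 0.003.
#' @param valve_resistance aortic valve series resistance (mmHg s/mL).
#' @param valve_inertance blood inertance of the valve/outflow-tract
#'   column (mmHg s^2/mL); prevents non-physical valve chatter when
#'   reflected waves transiently raise root pressure mid-systole.
#' @return list of class `cardiac_params`.
#' @export
cardiac_params <- function(E_es = 2.265, E_ed = 0.125, filling_pressure = 15,
                           heart_rate = 73, t_maxE = 0.340, V_d = 15,
                           venous_resistance = 0.003,
                           valve_resistance = 0.006,
                           valve_inertance = 5e-4) {
  check_positive(E_es, "E_es"); check_positive(E_ed, "E_ed")
  if (E_es <= E_ed) stop_invalid("E_es must exceed E_ed")
  check_positive(filling_pressure, "filling_pressure")
  check_positive(heart_rate, "heart_rate")
  check_positive(t_maxE, "t_maxE")
  structure(list(E_es = E_es, E_ed = E_ed, filling_pressure = filling_pressure,
                 heart_rate = heart_rate, t_maxE = t_maxE, V_d = V_d,
                 venous_resistance = venous_resistance,
                 valve_resistance = valve_resistance,
                 valve_inertance = valve_inertance),
            class = "cardiac_params")
}

#' Normalized ventricular activation
#'
#' Double-Hill activation rescaled so that its value is exactly 1 at
#' `t = t_maxE`; near zero at t = 0 and in late diastole.
#'
#' @param t time within the cycle (s); must satisfy 0 <= t < 60/HR.
#' @param t_maxE time of maximal elastance (s).
#' @param heart_rate beats per minute (defines the admissible cycle).
#' @return activation in \[0, 1\].
#' @export
normalized_elastance <- function(t, t_maxE = 0.340, heart_rate = 73) {
  if (any(t < 0) || any(t >= 60 / heart_rate))
    stop_invalid("t must lie within the cycle [0, 60/heart_rate)")
  .hill_activation(t / t_maxE)
}

#' Simulation configuration
#'
#' @param dt_max maximum integration step (s); default 1e-4 (0.1 ms).
#' @param out_dt output sampling interval (s); default 1e-3 (1 kHz).
#' @param max_cycles maximum cardiac cycles to integrate.
#' @param tol periodicity tolerance: max cycle-to-cycle pressure
#'   difference (mmHg) at the recorded sites.
#' @param min_cycles minimum cycles before declaring periodicity.
#' @param elem_len_cm target lumped-element length (cm).
#' @param min_elements minimum elements per segment.
#' @param wall_visc_tau Voigt wall-viscosity relaxation time (s): each
#'   node compliance carries a series resistance R_w = wall_visc_tau / C.
#'   Damps the non-physical high-frequency ringing of a lossless lumped
#'   line; has no effect on mean pressures.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(dt_max = 1e-4, out_dt = 1e-3, max_cycles = 40,
                       tol = 0.01, min_cycles = 4, elem_len_cm = 2.5,
                       min_elements = 4, wall_visc_tau = 0.05) {
  structure(list(dt_max = dt_max, out_dt = out_dt, max_cycles = max_cycles,
                 tol = tol, min_cycles = min_cycles, elem_len_cm = elem_len_cm,
                 min_elements = min_elements, wall_visc_tau = wall_visc_tau),
            class = "sim_config")
}

#' Simulate one virtual subject
#'
#' Integrates the elastance heart coupled to the discretized arterial
#' tree to periodic steady state and returns one cycle of concurrent
#' pressure (and flow) waveforms at the aortic root, the left common
#' carotid artery and the left brachial artery, together with pressure
#' summaries and derived hemodynamic metrics.
#'
#' @param cardiac a [cardiac_params()].
#' @param tree an `arterial_tree` with terminals
#'   (see [set_vascular_targets()] / [build_scaled_tree()]).
#' @param config a [sim_config()].
#' @param sites named segments to record in addition to the aortic root;
#'   defaults to the carotid and brachial measurement sites.
#' @return list of class `subject_simulation` with `waveforms` (named
#'   list of [pressure_waveform()]), `summaries`, `metrics`, and
#'   convergence info.
#' @export
simulate_subject <- function(cardiac, tree, config = sim_config(),
                             sites = c(left_common_carotid = "left_common_carotid",
                                       brachial = "left_brachial")) {
  stopifnot(inherits(cardiac, "cardiac_params"), inherits(tree, "arterial_tree"))
  net <- discretize_tree(tree, config$elem_len_cm, config$min_elements)
  seg <- tree$segments
  site_idx <- match(sites, seg$name)
  if (anyNA(site_idx)) stop_invalid("unknown site segment name")
  rec_nodes <- c(net$root_node, net$seg_end_node[site_idx])
  rec_branches <- net$seg_end_branch[site_idx]

  # Voigt wall resistance per node (capped for very small compliances);
  # the integration step is then shrunk below the nominal 0.1 ms ceiling
  # until the fastest resistive/oscillatory pole of the lumped network
  # sits inside the RK4 stability region.
  node_Rw <- pmin(config$wall_visc_tau / net$node_C, 2.0)
  r_eff <- net$br_R + node_Rw[net$br_from] + node_Rw[net$br_to]
  pole_r <- max(r_eff / net$br_L)                       # resistive poles
  pole_w <- max(1 / sqrt(net$br_L * pmin(net$node_C[net$br_from],
                                         net$node_C[net$br_to])))
  dt_stab <- min(1.0 / pole_r, 1.0 / pole_w)
  dt_use <- min(config$dt_max, dt_stab)
  res <- .simulate_network_cpp(
    net$node_C, node_Rw,
    net$br_from - 1L, net$br_to - 1L, net$br_R, net$br_L,
    net$term_node - 1L, net$term_Z, net$term_R, net$term_C,
    0.0,
    cardiac$E_es, cardiac$E_ed, cardiac$filling_pressure, cardiac$t_maxE,
    cardiac$heart_rate, cardiac$V_d, cardiac$venous_resistance,
    cardiac$valve_resistance, cardiac$valve_inertance, net$root_node - 1L,
    dt_use, config$out_dt, config$max_cycles, config$tol,
    config$min_cycles,
    rec_nodes - 1L, rec_branches - 1L, 80.0)

  if (res$blew_up)
    stop(structure(class = c("dpd_simulation_failure", "error", "condition"),
                   list(message = "simulation blew up (|P| > 400 mmHg)",
                        call = sys.call())))
  if (!res$converged)
    stop(structure(class = c("dpd_simulation_failure", "error", "condition"),
                   list(message = sprintf(
                     "no periodic steady state after %d cycles (residual %.3g mmHg)",
                     res$cycles_run, res$max_cycle_diff), call = sys.call())))

  T <- res$period
  waves <- list(aortic_root = pressure_waveform(
    res$time, res$pressure[, 1], site = "aortic_root", flow = res$q_av,
    period = T))
  for (j in seq_along(sites)) {
    waves[[names(sites)[j]]] <- pressure_waveform(
      res$time, res$pressure[, 1 + j], site = names(sites)[j],
      flow = res$flow[, j], period = T)
  }
  summaries <- lapply(waves, summarize_pressure)

  co <- cycle_mean(res$time, res$q_av, T)                   # mL/s
  sv <- co * T
  map_ao <- summaries$aortic_root$map
  asc <- seg[is.na(seg$parent), ]
  pwv_ao <- compute_local_pwv(asc$distensibility_per_Pa, tree$blood$density)
  car <- seg[seg$name == "left_common_carotid", ]
  pwv_car <- if (nrow(car)) compute_local_pwv(car$distensibility_per_Pa,
                                              tree$blood$density) else NA_real_
  metrics <- list(
    cardiac_output_ml_s = co, cardiac_output_l_min = co * 60 / 1000,
    stroke_volume = sv, tpr = map_ao / co,
    aortic_characteristic_impedance =
      compute_characteristic_impedance(asc$prox_diam_cm, pwv_ao,
                                       tree$blood$density),
    local_pwv = c(aortic = pwv_ao, left_common_carotid = pwv_car))

  structure(list(waveforms = waves, summaries = summaries, metrics = metrics,
                 v_lv = res$v_lv, p_lv = res$p_lv,
                 cycles_run = res$cycles_run, converged = res$converged,
                 max_cycle_diff = res$max_cycle_diff, dt = res$dt),
            class = "subject_simulation")
}

#' @export
print.subject_simulation <- function(x, ...) {
  s <- x$summaries$aortic_root
  cat(sprintf(paste0("<subject_simulation> %d cycles to steady state; aortic ",
                     "%0.0f/%0.0f (MAP %0.0f) mmHg, CO %.2f L/min\n"),
              x$cycles_run, s$sbp, s$dbp, s$map, x$metrics$cardiac_output_l_min))
  invisible(x)
}
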