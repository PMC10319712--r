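# Shared fixtures, built in code. Heavy objects (reference simulation,
# the scaled-down population run) are computed once per test session and
# cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# reference subject: mid-range cardiac parameters, C = 1.14, TPR = 1.0
reference_simulation <- function() {
  cached("ref_sim", {
    tree <- set_vascular_targets(load_arterial_tree(), 1.14, 1.0)
    simulate_subject(cardiac_params(), tree)
  })
}

# the scaled-down experiment used by the acceptance criteria
acceptance_pipeline <- function() {
  cached("accept_run", run_pipeline(run_config(n = 100, seed = 11)))
}

# closed-form exponential window for fit oracles
exp_window <- function(p_inf = 60, amp = 40, rc = 1.5, duration = 0.6,
                       fs = 1000) {
  wave <- generate_exponential_segment(p_inf, p_inf + amp, rc, duration, fs)
  structure(list(time = wave$time, pressure = wave$pressure,
                 t_in = 0, t_end = max(wave$time), window_start = 0,
                 fraction = 1, site = "fixture"),
            class = "diastolic_window")
}
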