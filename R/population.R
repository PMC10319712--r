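#' Parameter ranges for the virtual population
#'
#' Ranged parameters are sampled from a truncated Gaussian with
#' SD = (max - min)/4 (resample-on-reject); fixed parameters are held at
#' their stated values. Gaussian centers default to the range midpoint
#' except for heart rate, total arterial compliance and total peripheral
#' resistance, which are centered on the physiological norms the
#' literature mining was anchored to (73 bpm, 1.14 mL/mmHg,
#' 1.0 mmHg s/mL); centering those at the midpoints would produce an
#' accepted population whose means contradict the norms (e.g. mean heart
#' rate near 80 rather than ~73).
#'
#' @return list of class `parameter_ranges` with `ranged` (named list of
#'   c(min, max)), `center` (named list) and `fixed` (named list).
#' @export
parameter_ranges <- function() {
  ranged <- list(
    E_es = c(1.03, 3.50),                      # mmHg/mL
    E_ed = c(0.05, 0.20),                      # mmHg/mL
    filling_pressure = c(7, 23),               # mmHg
    heart_rate = c(60, 100),                   # bpm
    total_arterial_compliance = c(0.10, 3.80), # mL/mmHg
    total_peripheral_resistance = c(0.5, 2),   # mmHg s/mL
    inlet_diameter = c(1.9, 4),                # cm
    height = c(150, 200)                       # cm
  )
  center <- lapply(ranged, mean)
  center$heart_rate <- 73
  center$total_arterial_compliance <- 1.14
  center$total_peripheral_resistance <- 1.0
  structure(list(
    ranged = ranged, center = center,
    fixed = list(t_maxE = 0.340, V_d = 15, venous_resistance = 0.003,
                 blood_density = 1050, blood_viscosity = 0.004)),
    class = "parameter_ranges")
}

#' Sample virtual-subject parameter draws
#'
#' @param ranges a [parameter_ranges()].
#' @param n number of subjects.
#' @param seed integer seed; identical seeds give identical draws.
#' @return data.frame, one row per subject (`subject_id` first), with one
#'   column per ranged and fixed parameter.
#' @export
sample_parameters <- function(ranges = parameter_ranges(), n, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop_invalid("n must be >= 1")
  for (nm in names(ranges$ranged)) {
    r <- ranges$ranged[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2] || r[1] <= 0)
      stop(structure(class = c("dpd_config_error", "error", "condition"),
                     list(message = paste0("bad range for ", nm), call = sys.call())))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  draws <- lapply(names(ranges$ranged), function(nm) {
    r <- ranges$ranged[[nm]]
    ctr <- if (!is.null(ranges$center[[nm]])) ranges$center[[nm]] else mean(r)
    rtrunc_gauss(n, mean = ctr, sd = diff(r) / 4, lo = r[1], hi = r[2])
  })
  names(draws) <- names(ranges$ranged)
  out <- data.frame(subject_id = seq_len(n), draws)
  for (nm in names(ranges$fixed)) out[[nm]] <- ranges$fixed[[nm]]
  out
}

# truncated Gaussian by resample-on-reject
rtrunc_gauss <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Physiological plausibility filter configuration
#'
#' Reference mean/SD pairs for brachial and aortic SBP, DBP, MAP and PP
#' in a normotensive and a hypertensive reference set. The shipped
#' defaults are editable approximations assembled from published
#' population studies of central and peripheral pressures (they are NOT a
#' reprint of any specific table). A subject is accepted if every
#' variable lies within mean +/- z_threshold * SD of at least one
#' reference set.
#'
#' @param z_threshold acceptance half-width in SD units; the default
#'   2.807 corresponds to a 99.5% normal interval.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(z_threshold = 2.807) {
  check_positive(z_threshold, "z_threshold")
  ref <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE,
                dimnames = list(c("brachial_sbp", "brachial_dbp", "brachial_map",
                                  "brachial_pp", "aortic_sbp", "aortic_dbp",
                                  "aortic_map", "aortic_pp"),
                                c("mean", "sd")))
    as.data.frame(m)
  }
  structure(list(
    z_threshold = z_threshold,
    normotensive = ref(123, 14,  77, 9,  93, 10,  46, 13,
                       113, 14,  78, 9,  93, 10,  35, 12),
    hypertensive = ref(152, 17,  91, 12, 111, 13,  61, 16,
                       141, 17,  92, 12, 108, 13,  49, 15)),
    class = "filter_config")
}

#' Apply the physiological plausibility filter
#'
#' @param summaries data.frame with one row per subject and columns
#'   matching the filter variables (`brachial_sbp`, ..., `aortic_pp`).
#' @param config a [filter_config()].
#' @return data.frame with `accepted` (logical) and `reason` (first
#'   failing variable or NA); attribute `n_accepted`.
#' @export
apply_physiology_filter <- function(summaries, config = filter_config()) {
  vars <- rownames(config$normotensive)
  missing <- setdiff(vars, names(summaries))
  if (length(missing))
    stop(structure(class = c("dpd_config_error", "error", "condition"),
                   list(message = paste0("missing filter variables: ",
                                         paste(missing, collapse = ", ")),
                        call = sys.call())))
  z <- config$z_threshold
  ok <- matrix(TRUE, nrow(summaries), length(vars),
               dimnames = list(NULL, vars))
  for (v in vars) {
    pass_set <- function(ref) {
      abs(summaries[[v]] - ref[v, "mean"]) <= z * ref[v, "sd"]
    }
    ok[, v] <- pass_set(config$normotensive) | pass_set(config$hypertensive)
  }
  accepted <- rowSums(!ok) == 0
  first_fail <- apply(ok, 1, function(row) {
    i <- which(!row)[1]
    if (is.na(i)) NA_character_ else vars[i]
  })
  out <- data.frame(accepted = accepted, reason = first_fail,
                    stringsAsFactors = FALSE)
  attr(out, "n_accepted") <- sum(accepted)
  out
}

#' Generate and simulate a virtual population
#'
#' Samples `n` parameter draws, builds each subject's scaled tree,
#' simulates to periodic steady state, and applies the physiological
#' filter. Subjects whose simulation fails are flagged (not accepted).
#'
#' @param n number of subjects to draw.
#' @param seed integer seed.
#' @param ranges a [parameter_ranges()].
#' @param reference_tree reference `arterial_tree`.
#' @param filter a [filter_config()].
#' @param config a [sim_config()].
#' @param progress print a line every 20 subjects.
#' @return list of class `virtual_population`: `draws` (with summary
#'   columns and verdicts), `simulations` (list, NULL where failed),
#'   `n_accepted`.
#' @export
generate_population <- function(n, seed = 1L, ranges = parameter_ranges(),
                                reference_tree = load_arterial_tree(),
                                filter = filter_config(),
                                config = sim_config(), progress = FALSE) {
  draws <- sample_parameters(ranges, n, seed)
  sims <- vector("list", n)
  cols <- c("brachial_sbp", "brachial_dbp", "brachial_map", "brachial_pp",
            "aortic_sbp", "aortic_dbp", "aortic_map", "aortic_pp")
  for (cn in cols) draws[[cn]] <- NA_real_
  draws$sim_ok <- FALSE
  for (i in seq_len(n)) {
    d <- as.list(draws[i, ])
    sim <- tryCatch({
      tree <- build_scaled_tree(reference_tree, d)
      cardiac <- cardiac_params(E_es = d$E_es, E_ed = d$E_ed,
                                filling_pressure = d$filling_pressure,
                                heart_rate = d$heart_rate, t_maxE = d$t_maxE,
                                V_d = d$V_d,
                                venous_resistance = d$venous_resistance)
      simulate_subject(cardiac, tree, config)
    }, error = function(e) e)
    if (!inherits(sim, "error")) {
      sims[[i]] <- sim
      draws$sim_ok[i] <- TRUE
      sa <- sim$summaries$aortic_root; sb <- sim$summaries$brachial
      draws[i, cols] <- c(sb$sbp, sb$dbp, sb$map, sb$pp,
                          sa$sbp, sa$dbp, sa$map, sa$pp)
    }
    if (progress && i %% 20 == 0)
      message(sprintf("  simulated %d/%d subjects", i, n))
  }
  verdict <- data.frame(accepted = rep(FALSE, n), reason = NA_character_)
  okrows <- which(draws$sim_ok)
  if (length(okrows)) {
    v <- apply_physiology_filter(draws[okrows, ], filter)
    verdict[okrows, ] <- v
  }
  verdict$reason[!draws$sim_ok] <- "simulation_failed"
  draws$accepted <- verdict$accepted
  draws$reason <- verdict$reason
  structure(list(draws = draws, simulations = sims,
                 n_accepted = sum(draws$accepted), seed = seed),
            class = "virtual_population")
}

#' @export
print.virtual_population <- function(x, ...) {
  cat(sprintf("<virtual_population> n = %d drawn, %d simulated, %d accepted (seed %s)\n",
              nrow(x$draws), sum(x$draws$sim_ok), x$n_accepted,
              format(x$seed)))
  invisible(x)
}
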