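#' Run configuration for the full in-silico experiment
#'
#' @param n number of subjects to draw.
#' @param seed root seed; all stage seeds (sampling, per-subject noise)
#'   are derived from it.
#' @param windows diastolic window fractions to evaluate.
#' @param noise_sd additive Gaussian noise SD (mmHg).
#' @param tree_file path to the segment table (default: packaged tree).
#' @param sim a [sim_config()].
#' @param filter a [filter_config()].
#' @param out_dir optional output directory; when given, the resolved
#'   config, subject table, RC table and report are written there.
#' @return list of class `run_config`.
#' @export
run_config <- function(n = 100, seed = 1L, windows = c(1/3, 2/3, 1),
                       noise_sd = 0.3, tree_file = NULL, sim = sim_config(),
                       filter = filter_config(), out_dir = NULL) {
  if (n < 1) stop_invalid("n must be >= 1")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 windows = windows, noise_sd = noise_sd,
                 tree_file = tree_file, sim = sim, filter = filter,
                 out_dir = out_dir),
            class = "run_config")
}

window_label <- function(fraction) {
  c("13", "23", "entire")[match(round(fraction, 3), round(c(1/3, 2/3, 1), 3))]
}

# Per-subject RC extraction across all arms. Returns a long data.frame.
#
# Each site's cycle is re-referenced foot-to-foot so that its diastole
# runs to the next pulse onset. The diastole start is detected once from
# the aortic valve flow (unambiguous in silico); the carotid incisura is
# the same valve-closure event arriving one wave transit later, so in
# foot-referenced phase both sites share the same t_in.
extract_subject_rcs <- function(sim, subject_id, windows, noise_sd, seed) {
  ao0 <- sim$waveforms$aortic_root
  ca0 <- sim$waveforms$left_common_carotid
  br <- sim$summaries$brachial
  cuff <- cuff_reading(br$sbp, br$dbp)

  tin0 <- tryCatch(as.numeric(detect_incisura(ao0)), error = function(e) NA_real_)
  # rotate each cycle to start at its diastolic minimum, so diastole
  # runs uninterrupted to the cycle end (the next onset)
  t_min_ao <- ao0$time[which.min(ao0$pressure)]
  t_min_ca <- ca0$time[which.min(ca0$pressure)]
  ao <- rotate_waveform(ao0, t_min_ao)
  ca <- rotate_waveform(ca0, t_min_ca)
  tin <- (tin0 - t_min_ao) %% ao0$period
  calib <- rescale_to_cuff(minmax_normalize(ca), cuff)

  noise_seed <- seed + 131071L * subject_id
  ca_noisy <- add_gaussian_noise(ca, sd = noise_sd, seed = noise_seed)
  calib_noisy <- add_gaussian_noise(calib, sd = noise_sd, seed = noise_seed + 1L)

  variants <- list(
    aortic = list(wave = ao, t_in = tin, noise = "clean"),
    raw_clean = list(wave = ca, t_in = tin, noise = "clean"),
    raw_noisy = list(wave = ca_noisy, t_in = tin, noise = "noisy"),
    calibrated_clean = list(wave = calib, t_in = tin, noise = "clean"),
    calibrated_noisy = list(wave = calib_noisy, t_in = tin, noise = "noisy"))

  rows <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    for (f in windows) {
      est <- if (is.na(v$t_in)) NULL else
        tryCatch(estimate_rc(v$wave, f, t_in = v$t_in),
                 error = function(e) NULL)
      ok <- !is.null(est) && !isTRUE(est$flagged)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, variant = vn, window = window_label(f),
        rc = if (ok) est$rc else NA_real_,
        p_inf = if (!is.null(est)) est$p_inf else NA_real_,
        flagged = !ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full experiment
#'
#' Sample, scale, simulate, filter, transform, fit, and compare:
#' produces the per-subject RC table and the 12-cell agreement report.
#'
#' @param config a [run_config()].
#' @param progress print progress messages.
#' @return list of class `pipeline_result` with `population`, `rc_table`,
#'   `report`, `config`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tree <- if (is.null(config$tree_file)) load_arterial_tree()
          else load_arterial_tree(config$tree_file)
  pop <- generate_population(config$n, config$seed,
                             reference_tree = tree, filter = config$filter,
                             config = config$sim, progress = progress)
  acc <- which(pop$draws$accepted)
  rc_rows <- lapply(acc, function(i)
    extract_subject_rcs(pop$simulations[[i]], i, config$windows,
                        config$noise_sd, config$seed))
  rc_table <- if (length(rc_rows)) do.call(rbind, rc_rows) else
    data.frame(subject_id = integer(), variant = character(),
               window = character(), rc = numeric(), p_inf = numeric(),
               flagged = logical())

  arms <- list()
  for (f in config$windows) {
    wl <- window_label(f)
    ao <- rc_table[rc_table$variant == "aortic" & rc_table$window == wl, ]
    for (variant in c("raw", "calibrated")) for (noise in c("clean", "noisy")) {
      cmp <- rc_table[rc_table$variant == paste(variant, noise, sep = "_") &
                        rc_table$window == wl, ]
      m <- merge(ao[!ao$flagged, c("subject_id", "rc")],
                 cmp[!cmp$flagged, c("subject_id", "rc")],
                 by = "subject_id", suffixes = c("_ao", "_cmp"))
      arms[[sprintf("w%s_%s_%s", wl, variant, noise)]] <-
        list(aortic = m$rc_ao, comparator = m$rc_cmp)
    }
  }
  report <- build_report(arms, metadata = list(
    n = config$n, seed = config$seed, n_accepted = pop$n_accepted,
    noise_sd = config$noise_sd,
    n_flagged_fits = sum(rc_table$flagged)))

  result <- structure(list(population = pop, rc_table = rc_table,
                           report = report, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$population)
  cat(sprintf("  %d RC fits (%d flagged)\n", nrow(x$rc_table),
              sum(x$rc_table$flagged)))
  print(x$report)
  invisible(x)
}

# Provenance: resolved config + seed, subject table, RC table, report.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  jsonlite::write_json(
    list(n = cfg$n, seed = cfg$seed, windows = cfg$windows,
         noise_sd = cfg$noise_sd,
         tree_file = if (is.null(cfg$tree_file)) "packaged:arterial_tree_24"
                     else cfg$tree_file,
         sim = unclass(cfg$sim), z_threshold = cfg$filter$z_threshold,
         n_accepted = result$population$n_accepted),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  write.csv(result$population$draws, file.path(out_dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(result$rc_table, file.path(out_dir, "rc_table.csv"),
            row.names = FALSE)
  write.csv(report_table(result$report), file.path(out_dir, "report.csv"),
            row.names = FALSE)
  invisible(out_dir)
}
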