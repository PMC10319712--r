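#' Brachial cuff reading
#'
#' Holds the simulated cuff systolic/diastolic pressures and the derived
#' cuff mean pressure MAP = (SBP + 2 DBP) / 3.
#'
#' @param sbp brachial systolic pressure (mmHg).
#' @param dbp brachial diastolic pressure (mmHg).
#' @return list of class `cuff_reading` with `sbp`, `dbp`, `map`.
#' @export
cuff_reading <- function(sbp, dbp) {
  check_positive(sbp, "sbp"); check_positive(dbp, "dbp")
  if (sbp <= dbp) stop_invalid("sbp must exceed dbp")
  structure(list(sbp = sbp, dbp = dbp, map = (sbp + 2 * dbp) / 3),
            class = "cuff_reading")
}

#' Min-max normalization of a waveform
#'
#' Maps the pressure trace affinely onto \[0, 1\].
#'
#' @param wave a [pressure_waveform()].
#' @return a dimensionless [pressure_waveform()] with min 0 and max 1.
#' @export
minmax_normalize <- function(wave) {
  stopifnot(inherits(wave, "pressure_waveform"))
  p <- wave$pressure
  rng <- range(p)
  if (diff(rng) <= 0) stop_invalid("cannot normalize a constant waveform")
  out <- wave
  out$pressure <- (p - rng[1]) / (rng[2] - rng[1])
  out
}

#' Rescale a normalized waveform to cuff pressures
#'
#' Implements the standard tonometry calibration under the assumption
#' that DBP and MAP are constant across the major arteries: the
#' normalized wave w is mapped to p = DBP + k w with k solved so that the
#' time average of p equals the cuff MAP = (SBP + 2 DBP)/3. The minimum
#' of p is therefore the cuff DBP and the peak is an output of the
#' calibration, not an input.
#'
#' @param normalized_wave a waveform in \[0, 1\] (see
#'   [minmax_normalize()]).
#' @param cuff a [cuff_reading()].
#' @return a calibrated [pressure_waveform()].
#' @export
rescale_to_cuff <- function(normalized_wave, cuff) {
  stopifnot(inherits(normalized_wave, "pressure_waveform"),
            inherits(cuff, "cuff_reading"))
  w <- normalized_wave$pressure
  if (min(w) < -1e-9 || max(w) > 1 + 1e-9)
    stop_invalid("wave must be normalized to [0, 1]")
  mw <- cycle_mean(normalized_wave$time, w, normalized_wave$period)
  if (mw <= 0) stop_invalid("normalized wave has zero mean")
  k <- (cuff$map - cuff$dbp) / mw
  out <- normalized_wave
  out$pressure <- cuff$dbp + k * w
  out
}

#' Additive Gaussian noise
#'
#' Corrupts every pressure sample with i.i.d. Gaussian noise
#' (default mu = 0, sigma = 0.3 mmHg). Reproducible via `seed`.
#'
#' @param wave a [pressure_waveform()].
#' @param sd noise standard deviation (mmHg).
#' @param mean noise mean (mmHg).
#' @param seed optional integer seed; the caller's RNG state is
#'   preserved.
#' @return the corrupted waveform.
#' @export
add_gaussian_noise <- function(wave, sd = 0.3, mean = 0, seed = NULL) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (!is.finite(sd) || sd < 0) stop_invalid("sd must be >= 0")
  out <- wave
  if (sd == 0 && mean == 0) return(out)
  noise <- if (is.null(seed)) {
    rnorm(length(wave$pressure), mean, sd)
  } else {
    withr_seed <- function(code) { # preserve global RNG state
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      code
    }
    withr_seed(rnorm(length(wave$pressure), mean, sd))
  }
  out$pressure <- wave$pressure + noise
  out
}
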