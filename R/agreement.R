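#' Agreement statistics for paired time constants
#'
#' Computes, from plain sums, the mean absolute error, Pearson
#' correlation, the ordinary least-squares regression of the comparator
#' on the aortic value (slope, intercept, two-sided Wald t-test p-value
#' for slope = 0), and the Bland-Altman bias and 1.96 SD limits of
#' agreement of d = comparator - aortic (sample SD, n - 1).
#'
#' @param aortic numeric vector of aortic time constants (s).
#' @param comparator numeric vector of comparator (carotid) time
#'   constants (s), same length.
#' @return list of class `agreement_result` with `r`, `mae`, `slope`,
#'   `intercept`, `wald_p`, `bias`, `loa_low`, `loa_high`, `n_pairs`.
#' @export
compute_agreement <- function(aortic, comparator) {
  x <- as.numeric(aortic); y <- as.numeric(comparator)
  if (length(x) != length(y)) stop_invalid("paired vectors must match in length")
  if (anyNA(x) || anyNA(y)) stop_invalid("pairs must not contain missing values")
  n <- length(x)
  if (n < 3) stop_invalid("need at least 3 pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop_invalid("zero variance in predictor")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else 0
  # Wald t-test on the slope (H0: slope = 0)
  rss <- syy - slope * sxy
  se_slope <- sqrt(max(rss, 0) / (n - 2) / sxx)
  tstat <- if (se_slope > 0) slope / se_slope else Inf
  wald_p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  d <- y - x
  bias <- mean(d)
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  structure(list(r = r, mae = mean(abs(d)), slope = slope,
                 intercept = intercept, wald_p = wald_p, bias = bias,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n_pairs = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(paste0("<agreement_result> n = %d  r = %.3f  MAE = %.3f s  ",
                     "slope = %.3f (p = %.2g)  intercept = %.3f s\n",
                     "  Bland-Altman: bias = %.3f s, LoA [%.3f, %.3f] s\n"),
              x$n_pairs, x$r, x$mae, x$slope, x$wald_p, x$intercept,
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Assemble the 12-arm agreement report
#'
#' One cell per experimental arm: window (1/3, 2/3, entire) x carotid
#' variant (raw, calibrated) x noise (noise-free, noisy), each comparing
#' the arm's carotid time constants against the noise-free aortic time
#' constants for the matching window.
#'
#' @param arms named list of 12 lists, each holding `aortic` and
#'   `comparator` numeric vectors; names of the form
#'   `w<window>_<raw|calibrated>_<clean|noisy>` (see
#'   [arm_names()]).
#' @param metadata list recorded alongside (n, seed, ...).
#' @return list of class `agreement_report` with `cells` (named list of
#'   `agreement_result`), `metadata`, `alpha = 0.05`.
#' @export
build_report <- function(arms, metadata = list()) {
  expected <- arm_names()
  missing <- setdiff(expected, names(arms))
  if (length(missing))
    stop(structure(class = c("dpd_report_error", "error", "condition"),
                   list(message = paste0("missing arms: ",
                                         paste(missing, collapse = ", ")),
                        call = sys.call())))
  cells <- lapply(arms[expected], function(a)
    compute_agreement(a$aortic, a$comparator))
  structure(list(cells = cells, metadata = metadata, alpha = 0.05),
            class = "agreement_report")
}

#' Canonical arm labels of the report grid
#'
#' @return character vector of the 12 arm names in report order.
#' @export
arm_names <- function() {
  grid <- expand.grid(noise = c("clean", "noisy"),
                      variant = c("raw", "calibrated"),
                      window = c("13", "23", "entire"),
                      stringsAsFactors = FALSE)
  sprintf("w%s_%s_%s", grid$window, grid$variant, grid$noise)
}

#' Agreement report as a data.frame (Table-3-shaped)
#'
#' @param report an `agreement_report`.
#' @return data.frame with one row per arm and the agreement columns.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  rows <- lapply(names(report$cells), function(nm) {
    c0 <- report$cells[[nm]]
    parts <- strsplit(nm, "_")[[1]]
    data.frame(window = sub("^w", "", parts[1]), variant = parts[2],
               noise = parts[3], r = c0$r, mae = c0$mae, slope = c0$slope,
               wald_p = c0$wald_p, intercept = c0$intercept, bias = c0$bias,
               loa_low = c0$loa_low, loa_high = c0$loa_high,
               n_pairs = c0$n_pairs)
  })
  do.call(rbind, rows)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  print(report_table(x), digits = 3, row.names = FALSE)
  invisible(x)
}
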