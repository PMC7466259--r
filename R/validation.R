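#' Calibration linearity with detection and quantification limits
#'
#' Fits signal on concentration by simple linear least squares and
#' derives the detection and quantification limits from the residual
#' standard error sigma of the line: `LOD = 3.3 sigma / slope`,
#' `LOQ = 10 sigma / slope` (so LOQ/LOD = 10/3.3 always).
#'
#' @param concentrations Analyte concentrations (>= 3 points, >= 2
#'   distinct values).
#' @param signals Corresponding signals (e.g. peak areas).
#' @return A `calibration_fit`: `slope`, `intercept`, `r2`,
#'   `se_residual`, `lod`, `loq`, `n`.
#' @export
calibrate <- function(concentrations, signals) {
  stopifnot(length(concentrations) == length(signals))
  if (length(concentrations) < 3L || length(unique(concentrations)) < 2L) {
    stop("calibrate: need >= 3 points with >= 2 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(signals ~ concentrations)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0 || stats::sd(signals) == 0) {
    stop("calibrate: zero slope; detection limits are undefined", call. = FALSE)
  }
  sm <- summary(fit)
  se <- sm$sigma
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared, se_residual = se,
                 lod = 3.3 * se / abs(slope), loq = 10 * se / abs(slope),
                 n = length(signals)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: y = %.4g x %+.4g  (n = %d)\n", x$slope, x$intercept, x$n))
  cat(sprintf("  R2 = %.4f  sigma = %.4g  LOD = %.4g  LOQ = %.4g\n",
              x$r2, x$se_residual, x$lod, x$loq))
  invisible(x)
}

#' Spike recovery
#'
#' `100 * (measured - baseline) / spiked` percent; values within the
#' 80-110% window are flagged acceptable.
#'
#' @param measured Measurement of the spiked sample.
#' @param baseline Measurement of the unspiked sample.
#' @param spiked Amount spiked (> 0), same units.
#' @return List with `recovery_pct` and `acceptable` (80-110% window).
#' @export
recovery <- function(measured, baseline, spiked) {
  if (!is.numeric(spiked) || any(spiked <= 0)) {
    stop("recovery: spiked amount must be positive", call. = FALSE)
  }
  pct <- 100 * (measured - baseline) / spiked
  list(recovery_pct = pct, acceptable = pct >= 80 & pct <= 110)
}

#' Replicate precision as percent coefficient of variation
#'
#' `CV% = 100 * sd / mean` with the sample (n-1) standard deviation.
#' System-suitability (`sst`) replicates pass at CV < 2%; the general
#' (AOAC-style) acceptance for intraday/interday precision is CV <= 10%.
#'
#' @param values Replicate measurements (n >= 2, positive mean).
#' @param mode One of `"sst"`, `"intraday"`, `"interday"` (label only;
#'   both thresholds are always evaluated).
#' @return A `precision_report`: `cv_pct`, `n`, `mode`, `passes_sst`,
#'   `passes_aoac`.
#' @export
precision <- function(values, mode = c("sst", "intraday", "interday")) {
  mode <- match.arg(mode)
  if (length(values) < 2L) stop("precision: need at least 2 replicates", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("precision: CV undefined for non-positive mean", call. = FALSE)
  cv <- 100 * stats::sd(values) / m
  structure(list(cv_pct = cv, n = length(values), mode = mode,
                 passes_sst = cv < 2, passes_aoac = cv <= 10),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("%s precision: CV = %.2f%% (n = %d); SST %s, AOAC %s\n",
              x$mode, x$cv_pct, x$n,
              if (x$passes_sst) "pass" else "fail",
              if (x$passes_aoac) "pass" else "fail"))
  invisible(x)
}

#' Check an additive concentration against its regulatory limit
#'
#' Compares a measured concentration with the NADFC (Indonesian National
#' Agency of Drug and Food Control) maximum for that additive in
#' powdered drinks. The boundary is inclusive: a concentration equal to
#' the limit is compliant.
#'
#' @param analyte Additive code (one of ACE, BEN, SOR, SAC, TAR, CAF,
#'   SUN, ASP); vectorized.
#' @param concentration Measured concentration, mg/kg.
#' @param limits Named numeric vector of limits; default the built-in
#'   NADFC table.
#' @return Character vector `"compliant"` / `"exceeds"`.
#' @export
check_compliance <- function(analyte, concentration, limits = nadfc_limits()) {
  analyte <- as.character(analyte)
  unknown <- setdiff(analyte, names(limits))
  if (length(unknown)) {
    stop(sprintf("check_compliance: unknown analyte(s) %s; known codes: %s",
                 paste(unknown, collapse = ", "),
                 paste(names(limits), collapse = ", ")), call. = FALSE)
  }
  ifelse(concentration <= limits[analyte], "compliant", "exceeds")
}

#' @rdname check_compliance
#' @export
nadfc_limits <- function() {
  tab <- utils::read.csv(system.file("extdata", "nadfc_limits.csv",
                                     package = "chromrsm"),
                         stringsAsFactors = FALSE)
  stats::setNames(tab$limit_mg_kg, tab$analyte)
}
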