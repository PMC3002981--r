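#' Calibration levels for absolute m7G quantification
#'
#' The external calibration series used for absolute quantification of m7G:
#' seven standard concentrations mixed with a fixed 40 nM spike of the
#' \[15N5\]-dA internal standard.
#'
#' @return List with `concentration_nM` (0, 5, 50, 300, 600, 1000, 2000) and
#'   `is_concentration_nM` (40).
#' @export
default_m7g_levels <- function() {
  list(concentration_nM = c(0, 5, 50, 300, 600, 1000, 2000),
       is_concentration_nM = 40)
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares regression of the analyte/internal-standard area
#' ratio on standard concentration. Unweighted, and not forced through zero:
#' the zero-concentration standard is an ordinary calibration level.
#'
#' @param levels data.frame with `concentration` (nM) and `area_ratio`
#'   (dimensionless analyte/IS).
#' @param analyte analyte label stored with the curve (default `"m7G"`).
#' @param weights optional per-level weights passed to [stats::lm()].
#' @return A `calibration_curve`: list with `analyte`, `levels`, `slope`
#'   (per nM), `intercept`, `r_squared`, and the underlying `fit`.
#' @examples
#' lv <- data.frame(concentration = c(0, 5, 50, 300, 600, 1000, 2000))
#' lv$area_ratio <- 0.002 * lv$concentration
#' fit_calibration(lv)$slope  # 0.002
#' @export
fit_calibration <- function(levels, analyte = "m7G", weights = NULL) {
  stopifnot(is.data.frame(levels),
            all(c("concentration", "area_ratio") %in% names(levels)))
  if (nrow(levels) < 2) stop("need at least 2 calibration levels")
  if (length(unique(levels$concentration)) < 2)
    stop("degenerate calibration design: all concentrations identical")
  if (any(levels$concentration < 0)) stop("negative concentration level")
  fit <- stats::lm(area_ratio ~ concentration, data = levels,
                   weights = weights)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((levels$area_ratio - mean(levels$area_ratio))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(analyte = analyte, levels = levels,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve [%s]: ratio = %.6g + %.6g * conc(nM), r^2 = %.5f (%d levels)\n",
    x$analyte, x$intercept, x$slope, x$r_squared, nrow(x$levels)))
  invisible(x)
}

#' Invert a calibration curve: area ratio to concentration
#'
#' @param curve a `calibration_curve`.
#' @param area_ratio observed analyte/IS area ratio(s).
#' @return data.frame with `area_ratio`, `concentration_nM` (negative
#'   inversions floored at 0) and `flags` (`"below_curve"` where floored).
#' @export
invert_calibration <- function(curve, area_ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero: cannot invert")
  conc <- (area_ratio - curve$intercept) / curve$slope
  flags <- ifelse(conc < 0, "below_curve", "")
  data.frame(area_ratio = area_ratio,
             concentration_nM = pmax(conc, 0),
             flags = flags, stringsAsFactors = FALSE)
}

#' Write / read fitted calibration parameters as JSON
#' @param curve a `calibration_curve`.
#' @param path JSON file path.
#' @return `path` invisibly (`write_calibration`); a list of parameters
#'   (`read_calibration`).
#' @export
write_calibration <- function(curve, path) {
  jsonlite::write_json(
    list(analyte = curve$analyte, slope = curve$slope,
         intercept = curve$intercept, r_squared = curve$r_squared,
         n_levels = nrow(curve$levels)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
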