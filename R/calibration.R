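#' Fit an HPLC calibration line
#'
#' Ordinary least-squares regression of detector peak area on analyte
#' concentration, `area = slope * C + intercept`. The valid range is the span
#' of the calibration concentrations; inverse predictions outside it warn
#' (or fail in strict mode) in [quantify()].
#'
#' @param concentrations Calibration concentrations, mg/L (>= 3 distinct).
#' @param areas Detector peak areas, same length.
#' @param analyte Analyte label carried on the curve.
#' @return An object of class `calibration_curve` with elements `slope`,
#'   `intercept`, `valid_range`, `analyte`, `se_slope`, `n`.
#' @examples
#' cal <- fit_calibration(c(10, 100, 1000),
#'                        3336.8 * c(10, 100, 1000) + 181813, "ASA")
#' quantify(515493, cal)
#' @export
fit_calibration <- function(concentrations, areas, analyte = "analyte") {
  if (length(concentrations) != length(areas))
    stop("concentrations and areas must have equal length")
  if (length(unique(concentrations)) < 3L)
    stop("degenerate calibration design: need >= 3 distinct concentrations")
  fit <- lm.fit(cbind(1, concentrations), areas)
  cf <- unname(fit$coefficients)
  dof <- length(areas) - 2L
  se <- if (dof > 0) {
    s2 <- sum(fit$residuals^2) / dof
    sqrt(s2 / sum((concentrations - mean(concentrations))^2))
  } else NA_real_
  structure(list(slope = cf[2], intercept = cf[1],
                 valid_range = range(concentrations), analyte = analyte,
                 se_slope = se, n = length(areas)),
            class = "calibration_curve")
}

#' Build a calibration curve from known line constants
#'
#' @param slope,intercept Line constants (area per mg/L, area).
#' @param valid_range Concentration range the line was established on, mg/L.
#' @inheritParams fit_calibration
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, valid_range, analyte = "analyte") {
  stopifnot(slope != 0, valid_range[1] < valid_range[2])
  structure(list(slope = slope, intercept = intercept,
                 valid_range = as.numeric(valid_range), analyte = analyte,
                 se_slope = NA_real_, n = NA_integer_),
            class = "calibration_curve")
}

#' Reference HPLC calibration lines for ASA and salicylic acid
#'
#' The established detector responses: `Y = 3336.8 C + 181813` over
#' 10--1000 mg/L for acetylsalicylic acid and `Y = 39158 C + 14652` over
#' 0.5--20 mg/L for salicylic acid (UV detection at 254 nm).
#'
#' @param analyte `"ASA"` or `"SA"`.
#' @return A `calibration_curve`.
#' @export
reference_calibration <- function(analyte = c("ASA", "SA")) {
  analyte <- match.arg(analyte)
  if (analyte == "ASA")
    calibration_curve(3336.8, 181813, c(10, 1000), "ASA")
  else
    calibration_curve(39158, 14652, c(0.5, 20), "SA")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("HPLC calibration (%s): area = %.4g * C + %.6g\n",
              x$analyte, x$slope, x$intercept))
  cat(sprintf("  valid range %g-%g mg/L", x$valid_range[1], x$valid_range[2]))
  if (!is.na(x$se_slope)) cat(sprintf(", slope SE %.3g (n = %d)", x$se_slope, x$n))
  cat("\n")
  invisible(x)
}

#' Inverse-predict a concentration from a peak area
#'
#' `C = dilution_factor * (area - intercept) / slope`, in mg/L. The
#' back-calculated (undiluted-scale) concentration is checked against the
#' curve's valid range; out-of-range values warn by default because assays
#' routinely dilute into range, or fail when `strict = TRUE`.
#'
#' @param area Detector peak area.
#' @param curve A `calibration_curve`.
#' @param dilution_factor Dilution applied before injection (>= 1).
#' @param strict Error (instead of warn) on out-of-range back-calculation.
#' @return Concentration in mg/L.
#' @export
quantify <- function(area, curve, dilution_factor = 1, strict = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"), all(dilution_factor >= 1))
  C_injected <- (area - curve$intercept) / curve$slope
  if (any(C_injected < 0))
    stop("negative back-calculated concentration: area below the intercept")
  out_of_range <- C_injected < curve$valid_range[1] | C_injected > curve$valid_range[2]
  # areas exactly at the intercept (C = 0) are a legitimate blank
  out_of_range <- out_of_range & C_injected > 0
  if (any(out_of_range)) {
    msg <- sprintf("%d value(s) outside the calibrated range %g-%g mg/L",
                   sum(out_of_range), curve$valid_range[1], curve$valid_range[2])
    if (strict) stop(msg) else warning(msg)
  }
  dilution_factor * C_injected
}

#' Convert a mass concentration to molarity
#'
#' @param C_mgL Concentration in mg/L.
#' @param molar_mass Molar mass in g/mol.
#' @return Concentration in mol/L.
#' @export
mgL_to_molar <- function(C_mgL, molar_mass) {
  stopifnot(molar_mass > 0)
  C_mgL / 1000 / molar_mass
}
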