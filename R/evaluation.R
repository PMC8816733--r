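#' Mean relative deviation percent
#'
#' `MRD% = (100 / N) * sum(|calculated - observed| / observed)` on the linear
#' concentration scale.
#'
#' @param calculated,observed Equal-length vectors; `observed` must be
#'   strictly positive.
#' @return MRD in percent.
#' @examples
#' mrd_percent(c(1, 2), c(2, 2))  # 25
#' @export
mrd_percent <- function(calculated, observed) {
  if (length(calculated) != length(observed))
    stop("calculated and observed must have equal length")
  if (length(observed) < 1L) stop("need at least one observation")
  if (any(observed <= 0)) stop("observed values must be positive")
  100 * mean(abs(calculated - observed) / observed)
}

#' Build a prediction report with per-temperature and overall MRD%
#'
#' Aligns calculated and observed solubilities and scores them with the mean
#' relative deviation. The overall deviation is reported both pooled over all
#' points and as the unweighted mean of the per-temperature values (they
#' differ when group sizes differ).
#'
#' @param calculated,observed Aligned positive vectors.
#' @param f1,T Optional composition/temperature labels per point (used for
#'   grouping and the per-point table).
#' @param model Optional model identifier carried in the report.
#' @return An object of class `prediction_report`: list with `points`
#'   (per-point data frame with relative deviations), `mrd_by_T`,
#'   `mrd_overall` (pooled) and `mrd_mean_of_T`.
#' @export
evaluate_predictions <- function(calculated, observed, f1 = NULL, T = NULL,
                                 model = NULL) {
  n <- length(observed)
  if (length(calculated) != n) stop("calculated and observed must align 1:1")
  if (!is.null(f1) && length(f1) != n) stop("f1 labels must align with the points")
  if (!is.null(T) && length(T) != n) stop("T labels must align with the points")
  pts <- data.frame(
    f1 = if (is.null(f1)) NA_real_ else f1,
    T = if (is.null(T)) NA_real_ else T,
    observed = observed, calculated = calculated,
    rel_dev = abs(calculated - observed) / observed)
  by_T <- if (!is.null(T)) {
    v <- vapply(split(pts, pts$T), function(g) 100 * mean(g$rel_dev), numeric(1))
    v[order(as.numeric(names(v)))]
  } else NULL
  structure(list(points = pts, mrd_by_T = by_T,
                 mrd_overall = 100 * mean(pts$rel_dev),
                 mrd_mean_of_T = if (!is.null(by_T)) mean(by_T) else NULL,
                 model = model),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Prediction report", if (!is.null(x$model)) paste0("(", x$model, ")"), "\n")
  if (!is.null(x$mrd_by_T))
    for (tt in names(x$mrd_by_T))
      cat(sprintf("  MRD%% at %s K: %.1f\n", tt, x$mrd_by_T[[tt]]))
  cat(sprintf("  MRD%% overall (pooled over %d points): %.1f\n",
              nrow(x$points), x$mrd_overall))
  if (!is.null(x$mrd_mean_of_T))
    cat(sprintf("  MRD%% mean of temperatures: %.1f\n", x$mrd_mean_of_T))
  invisible(x)
}

#' Write a prediction report to disk
#'
#' Per-point table as CSV plus an MRD summary as JSON.
#'
#' @param report A `prediction_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_prediction_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(report$points, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(model = report$model, mrd_by_T = as.list(report$mrd_by_T),
           mrd_overall = report$mrd_overall,
           mrd_mean_of_T = report$mrd_mean_of_T,
           n_points = nrow(report$points)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Composition of maximum observed solubility
#'
#' The cosolvent fraction(s) at which the measured solubility peaks at a
#' given temperature; all tied fractions are returned.
#'
#' @param dataset A [solubility_dataset()].
#' @param T Temperature, K.
#' @param analyte Which analyte series to use.
#' @return Numeric vector of `f1` value(s) attaining the maximum.
#' @examples
#' solubility_peak(asa_ethanol_water(), 298.15)  # 0.9
#' @export
solubility_peak <- function(dataset, T, analyte = "primary_solute") {
  d <- dataset_subset(dataset, analyte = analyte, T = T)
  if (nrow(d) < 2L) stop("need at least two records at T = ", T, " K")
  d$f1[d$C == max(d$C)]
}

#' Percent crystallinity from diffraction peak areas
#'
#' `100 * crystalline_area / total_area`, where the total is the combined
#' crystalline plus amorphous scattering area.
#'
#' @param crystalline_area Area under the designated crystalline reflections.
#' @param total_area Total diffractogram area (must be >= `crystalline_area`).
#' @return Crystallinity in percent, in `[0, 100]`.
#' @export
crystallinity_percent <- function(crystalline_area, total_area) {
  if (any(total_area <= 0)) stop("total area must be positive")
  if (any(crystalline_area < 0) || any(crystalline_area > total_area))
    stop("crystalline area must lie in [0, total_area]")
  100 * crystalline_area / total_area
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Crystallinity index of a powder diffractogram
#'
#' Integrates the designated crystalline reflections (trapezoidal rule over a
#' window around each peak position, after subtracting the linear baseline
#' spanned by the window edges, which removes the amorphous halo underneath)
#' and divides by the total scattering area of the trace.
#'
#' @param twotheta,intensity Diffractogram trace (2-theta in degrees).
#' @param peaks Crystalline reflection positions, degrees 2-theta; default
#'   the 7.8 and 15.6 degree reflections of crystalline ASA.
#' @param half_width Half-width of each integration window, degrees.
#' @return List with `crystallinity_percent`, `crystalline_area`,
#'   `total_area`.
#' @export
diffractogram_crystallinity <- function(twotheta, intensity,
                                        peaks = c(7.8, 15.6),
                                        half_width = 0.5) {
  stopifnot(length(twotheta) == length(intensity), half_width > 0)
  o <- order(twotheta)
  twotheta <- twotheta[o]; intensity <- intensity[o]
  total <- .trapz(twotheta, pmax(intensity, 0))
  crystalline <- 0
  for (p in peaks) {
    w <- twotheta >= p - half_width & twotheta <= p + half_width
    if (!any(w)) stop("no trace points in the window around ", p, " degrees")
    xt <- twotheta[w]; yt <- intensity[w]
    base <- yt[1] + (yt[length(yt)] - yt[1]) * (xt - xt[1]) / (xt[length(xt)] - xt[1])
    crystalline <- crystalline + .trapz(xt, pmax(yt - base, 0))
  }
  crystalline <- min(crystalline, total)
  list(crystallinity_percent = crystallinity_percent(crystalline, total),
       crystalline_area = crystalline, total_area = total)
}

#' Flag degradation-product concentrations below their saturation solubility
#'
#' Compares a measured concentration series against the saturation
#' (intrinsic) solubility of the same compound in the same mixtures; a flag
#' of `TRUE` means the measured value is strictly undersaturated, i.e. the
#' compound cannot precipitate.
#'
#' @param measured Data frame with columns `f1`, `C`, or a numeric vector.
#' @param saturation_reference Data frame with columns `f1`, `C_sat`, or a
#'   numeric vector aligned with `measured`.
#' @return Logical vector named by `f1` where available.
#' @examples
#' d <- dataset_subset(asa_ethanol_water(), "degradation_product", 298.15)
#' undersaturation_check(data.frame(f1 = d$f1, C = d$C),
#'                       sa_saturation_reference())
#' @export
undersaturation_check <- function(measured, saturation_reference) {
  if (is.data.frame(measured) && is.data.frame(saturation_reference)) {
    if (!setequal(measured$f1, saturation_reference$f1))
      stop("measured and reference series are not aligned on f1")
    m <- measured[order(measured$f1), ]
    r <- saturation_reference[order(saturation_reference$f1), ]
    setNames(m$C < r$C_sat, m$f1)
  } else {
    m <- as.numeric(if (is.data.frame(measured)) measured$C else measured)
    r <- as.numeric(if (is.data.frame(saturation_reference))
      saturation_reference$C_sat else saturation_reference)
    if (length(m) != length(r)) stop("series must have equal length")
    m < r
  }
}
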