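# Seeded generators reproducing the statistical structure of the measured
# inputs: solubility curves with Jouyban-Acree or Wilson structure under
# multiplicative noise, Gaussian-peak diffractograms over an amorphous halo,
# and linear chromatographic responses.

# run code under a seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# evaluate a true cosolvency model on a grid
.truth_predict <- function(truth, f1, T) {
  if (inherits(truth, "cosolv_fit"))
    return(predict(truth, data.frame(f1 = f1, T = T)))
  if (inherits(truth, "ja_params")) {
    an <- .anchor_lookup(truth$anchors, T)
    return(ja_predict(truth, an[, "C1"], an[, "C2"], f1, T))
  }
  if (inherits(truth, "wilson_params")) {
    if (!all(T == truth$T)) stop("Wilson truth is isothermal at T = ", truth$T)
    return(wilson_predict(truth$lambda12, truth$lambda21,
                          truth$anchors[["C1"]], truth$anchors[["C2"]], f1))
  }
  stop("truth must be a cosolv_fit, ja_params or wilson_params object")
}

#' Simulate a solubility dataset from a true cosolvency model
#'
#' Draws `ln C = ln C_model + eps`, `eps ~ N(0, noise_sd^2)`, over a
#' composition/temperature grid (multiplicative noise keeps solubilities
#' positive and matches the relative-deviation error metric). The `sd`
#' column is populated from `n_rep` additional simulated replicate
#' measurements per point. A pure function of its arguments and the seed.
#'
#' @param truth A fitted [cosolv_fit()], a [ja_fit()] result, or a
#'   [wilson_fit()] result (anchors included in all three).
#' @param f1 Composition grid; must include the anchors 0 and 1.
#' @param T Temperature grid, K.
#' @param noise_sd Standard deviation of the ln-scale noise (>= 0).
#' @param seed Integer seed; the caller's RNG state is restored afterwards.
#' @param n_rep Number of replicate draws behind the `sd` column.
#' @return A [solubility_dataset()].
#' @examples
#' fit <- cosolv_fit(asa_ethanol_water(), "jouyban_acree")
#' sim <- simulate_solubility_dataset(fit, seed = 42)
#' @export
simulate_solubility_dataset <- function(truth, f1 = seq(0, 1, by = 0.1),
                                        T = c(298.15, 310.15),
                                        noise_sd = 0.05, seed = 1, n_rep = 3) {
  stopifnot(noise_sd >= 0, all(f1 >= 0 & f1 <= 1), 0 %in% f1, 1 %in% f1)
  grid <- expand.grid(f1 = f1, T = T)
  mu <- log(.truth_predict(truth, grid$f1, grid$T))
  .with_seed(seed, {
    C <- exp(mu + rnorm(length(mu), 0, noise_sd))
    reps <- matrix(exp(mu + rnorm(length(mu) * n_rep, 0, noise_sd)),
                   ncol = n_rep)
    sdC <- if (noise_sd > 0) apply(reps, 1, sd) else rep(0, length(mu))
    solubility_dataset(
      data.frame(f1 = grid$f1, T = grid$T, C = C, sd = sdC,
                 analyte = "primary_solute"),
      solute_name = "synthetic solute")
  })
}

#' Simulate a powder diffractogram
#'
#' Sum of Gaussian crystalline peaks and a broad Gaussian amorphous halo on
#' the 5--50 degree 2-theta grid (0.02 degree steps), plus seeded Gaussian
#' noise. The analytic area of each Gaussian is
#' `height * width * sqrt(2 pi)`, which makes ground-truth crystallinity
#' splits available to tests.
#'
#' @param peaks Data frame with columns `position` (degrees 2-theta),
#'   `height`, `width` (Gaussian SD, degrees); may have zero rows.
#' @param halo Numeric vector `c(center, height, width)` for the amorphous
#'   halo, or `NULL` for none.
#' @param noise_sd SD of additive intensity noise.
#' @param seed Integer seed.
#' @param range 2-theta scan range, degrees.
#' @param step Scan step, degrees.
#' @return Data frame with columns `twotheta`, `intensity`.
#' @examples
#' xr <- simulate_diffractogram(
#'   data.frame(position = c(7.8, 15.6), height = c(200, 150),
#'              width = c(0.1, 0.1)),
#'   halo = c(20, 30, 8), noise_sd = 0, seed = 7)
#' @export
simulate_diffractogram <- function(peaks = data.frame(position = numeric(),
                                                      height = numeric(),
                                                      width = numeric()),
                                   halo = NULL, noise_sd = 0, seed = 1,
                                   range = c(5, 50), step = 0.02) {
  if (nrow(peaks) &&
      (any(peaks$position < range[1]) || any(peaks$position > range[2])))
    stop("crystalline peaks must lie within the scan range")
  x <- seq(range[1], range[2], by = step)
  y <- numeric(length(x))
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks$height[i] * exp(-(x - peaks$position[i])^2 / (2 * peaks$width[i]^2))
  if (!is.null(halo))
    y <- y + halo[2] * exp(-(x - halo[1])^2 / (2 * halo[3]^2))
  if (noise_sd > 0)
    y <- .with_seed(seed, y + rnorm(length(x), 0, noise_sd))
  data.frame(twotheta = x, intensity = y)
}

#' Simulate HPLC peak areas for known concentrations
#'
#' `area = slope * C + intercept + eps`, `eps ~ N(0, noise_sd^2)`, seeded.
#'
#' @param curve A `calibration_curve`.
#' @param concentrations Concentrations, mg/L (>= 0).
#' @param noise_sd SD of additive area noise.
#' @param seed Integer seed.
#' @return Numeric vector of simulated detector areas.
#' @export
simulate_hplc_areas <- function(curve, concentrations, noise_sd = 0, seed = 1) {
  stopifnot(inherits(curve, "calibration_curve"), all(concentrations >= 0))
  mu <- curve$slope * concentrations + curve$intercept
  if (noise_sd == 0) return(mu)
  .with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
}
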