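# Algebraic cosolvency models. All functions work on a single concentration
# scale: whatever scale the anchor (neat-solvent) solubilities are given on
# is the scale of the prediction; the packaged reference data are molar.

#' Solubilization power from neat-solvent solubilities
#'
#' The log-linear model writes `ln Cm = ln C2 + sigma * f1`; at the anchors
#' this forces `sigma = ln(C1 / C2)`.
#'
#' @param C1 Solubility in the neat cosolvent (same scale as `C2`).
#' @param C2 Solubility in neat water.
#' @return The solubilization power sigma (dimensionless).
#' @export
loglinear_sigma <- function(C1, C2) {
  if (any(C1 <= 0) || any(C2 <= 0)) stop("solubilities must be positive")
  log(C1 / C2)
}

#' Solubilization power from the solute's log P
#'
#' Cosolvent-specific linear relation `sigma = M * logP + N`.
#'
#' @param logP Octanol-water partition coefficient (log10) of the solute.
#' @param constants List or vector with elements `M` and `N`; default are the
#'   ethanol constants `M = 2.14`, `N = 0.92`.
#' @return sigma.
#' @examples
#' loglinear_sigma_from_logP(1.18)  # 3.4452
#' @export
loglinear_sigma_from_logP <- function(logP, constants = ethanol_loglinear_constants()) {
  constants$M * logP + constants$N
}

#' @rdname loglinear_sigma_from_logP
#' @export
ethanol_loglinear_constants <- function() list(M = 2.14, N = 0.92)

#' Log-linear solubility prediction
#'
#' @param C2 Neat-water solubility.
#' @param sigma Solubilization power (from [loglinear_sigma()] or
#'   [loglinear_sigma_from_logP()]).
#' @param f1 Cosolvent volume fraction(s) in `[0, 1]`.
#' @return Predicted solubility on the scale of `C2`.
#' @export
loglinear_predict <- function(C2, sigma, f1) {
  stopifnot(all(f1 >= 0 & f1 <= 1), C2 > 0)
  exp(log(C2) + sigma * f1)
}

# mixing-term regressors f1*f2*(f1-f2)^i / T, i = 0..(n_terms-1)
.ja_design <- function(f1, T, n_terms) {
  f2 <- 1 - f1
  sapply(seq_len(n_terms) - 1L, function(i) f1 * f2 * (f1 - f2)^i / T)
}

# neat-solvent anchors per temperature; errors when one is missing
.ja_anchors <- function(f1, T, C) {
  Ts <- sort(unique(T))
  anchors <- lapply(Ts, function(tt) {
    i1 <- which(T == tt & f1 == 1)
    i2 <- which(T == tt & f1 == 0)
    if (!length(i1) || !length(i2))
      stop("missing neat-solvent anchor (f1 = 0 and f1 = 1 required) at T = ", tt, " K")
    c(C1 = C[i1[1]], C2 = C[i2[1]])
  })
  names(anchors) <- as.character(Ts)
  anchors
}

.anchor_lookup <- function(anchors, T) {
  key <- as.character(T)
  miss <- setdiff(unique(key), names(anchors))
  if (length(miss)) stop("no anchors for T = ", paste(miss, collapse = ", "), " K")
  t(vapply(key, function(k) anchors[[k]], numeric(2)))
}

#' Fit the Jouyban-Acree mixing coefficients
#'
#' Intercept-free least squares of the excess term
#' `y = ln Cm - f1 ln C1,T - f2 ln C2,T` on the regressors
#' `f1 f2 / T`, `f1 f2 (f1 - f2) / T`, `f1 f2 (f1 - f2)^2 / T`
#' (the first `n_terms` of them). Neat-solvent rows contribute zero rows and
#' are retained; the anchors themselves are taken from the data, so the model
#' reproduces them exactly.
#'
#' @param dataset A [solubility_dataset()] (its `"primary_solute"` records)
#'   or a data frame with columns `f1`, `T`, `C`, containing `f1 = 0` and
#'   `f1 = 1` records at every temperature.
#' @param n_terms Number of mixing coefficients (1--3).
#' @return An object of class `ja_params`: list with `J` (named coefficient
#'   vector, units K), `n_terms`, `anchors` (neat solubilities per
#'   temperature) and ln-scale `residuals`.
#' @examples
#' fit <- ja_fit(asa_ethanol_water())
#' fit$J
#' @export
ja_fit <- function(dataset, n_terms = 3) {
  stopifnot(n_terms >= 1, n_terms <= 3)
  d <- .model_frame(dataset)
  anchors <- .ja_anchors(d$f1, d$T, d$C)
  an <- .anchor_lookup(anchors, d$T)
  y <- log(d$C) - d$f1 * log(an[, "C1"]) - (1 - d$f1) * log(an[, "C2"])
  X <- .ja_design(d$f1, d$T, n_terms)
  interior <- d$f1 > 0 & d$f1 < 1
  if (sum(interior) < n_terms)
    stop("need at least ", n_terms, " interior mixture points")
  fit <- lm.fit(X, y)
  if (fit$rank < n_terms)
    stop("rank-deficient mixing design: regressors are collinear or all zero")
  J <- unname(fit$coefficients)
  structure(list(J = setNames(J, paste0("J", seq_len(n_terms) - 1L)),
                 n_terms = n_terms, anchors = anchors,
                 residuals = unname(fit$residuals)),
            class = "ja_params")
}

#' @export
print.ja_params <- function(x, ...) {
  cat("Jouyban-Acree mixing coefficients (K):\n")
  print(round(x$J, 3))
  invisible(x)
}

#' Jouyban-Acree solubility prediction
#'
#' `ln Cm = f1 ln C1,T + f2 ln C2,T + (f1 f2 / T) * sum_i J_i (f1 - f2)^i`,
#' exponentiated.
#'
#' @param params A `ja_params` object from [ja_fit()], or a bare numeric
#'   vector of 1--3 coefficients `J0, J1, J2`.
#' @param C1T,C2T Neat cosolvent / water solubilities at `T`.
#' @param f1 Cosolvent volume fraction(s).
#' @param T Absolute temperature(s), K.
#' @return Predicted solubility on the anchor scale.
#' @export
ja_predict <- function(params, C1T, C2T, f1, T) {
  J <- if (inherits(params, "ja_params")) params$J else as.numeric(params)
  stopifnot(length(J) >= 1, length(J) <= 3, all(f1 >= 0 & f1 <= 1), all(T > 0))
  X <- .ja_design(f1, T, length(J))
  exp(f1 * log(C1T) + (1 - f1) * log(C2T) + drop(X %*% J))
}

#' Pre-trained mixture coefficient sets
#'
#' Published trained coefficient sets for the Jouyban-Acree form in
#' ethanol + water: `"two_term"` (J0, J1 trained on a minimal five-point
#' design), `"generic"` (solute-independent three-term ethanol + water
#' coefficients) and `"abraham"` (three coefficient vectors over the Abraham
#' solute descriptors `1, E, S, A, B, V`, one per power of `(f1 - f2)`).
#'
#' @param set Which coefficient set.
#' @return An object of class `ja_trained`: list of per-power coefficient
#'   vectors; scalar for solute-independent sets, length-6 vectors for the
#'   Abraham-extended set.
#' @export
ja_trained_coefficients <- function(set = c("generic", "abraham", "two_term")) {
  set <- match.arg(set)
  co <- switch(set,
    two_term = list(1153.087, 474.742),
    generic = list(1667.856, 1117.347, 447.7262),
    abraham = list(
      c(1286.11, 825.86, 50.69, -812.89, 300.49, -684.22),
      c(105.18, -381.77, -740.53, 1104.24, -943.10, 1906.03),
      c(-1137.24, -786.06, 1994.90, -83.29, 399.36, -1279.27)))
  structure(list(coefficients = co, set = set), class = "ja_trained")
}

#' Predict with a pre-trained mixture model
#'
#' Each power-of-`(f1 - f2)` coefficient is the dot product of its trained
#' vector with `(1, E, S, A, B, V)` (or the scalar itself for
#' solute-independent sets); the resulting coefficients are then used in the
#' Jouyban-Acree form. Solute descriptors are required for the
#' Abraham-extended set. None of the packaged mixture measurements enter
#' these coefficient sets, so this is a genuine prediction from the two
#' neat-solvent solubilities alone.
#'
#' @param coeffs A `ja_trained` object from [ja_trained_coefficients()].
#' @param C1T,C2T Neat-solvent solubility anchors at `T`.
#' @param f1,T Composition and temperature of the prediction.
#' @param descriptors An [abraham_descriptors()] object (required for
#'   `set = "abraham"`).
#' @return Predicted solubility on the anchor scale.
#' @examples
#' ja_trained_predict(ja_trained_coefficients("abraham"), 0.826, 0.0246,
#'                    f1 = 0.5, T = 298.15,
#'                    descriptors = asa_abraham_descriptors())
#' @export
ja_trained_predict <- function(coeffs, C1T, C2T, f1, T, descriptors = NULL) {
  stopifnot(inherits(coeffs, "ja_trained"))
  J <- vapply(coeffs$coefficients, function(v) {
    if (length(v) == 1L) return(v)
    if (is.null(descriptors))
      stop("Abraham solute descriptors required for this coefficient set")
    sum(v * c(1, descriptors$E, descriptors$S, descriptors$A,
              descriptors$B, descriptors$V))
  }, numeric(1))
  ja_predict(J, C1T, C2T, f1, T)
}

#' Modified Wilson solubility prediction
#'
#' Two-constant local-composition model at one temperature:
#' `-ln Cm = 1 - f1 (1 + ln C1) / (f1 + f2 l12) - f2 (1 + ln C2) / (f1 l21 + f2)`
#' with the neat-solvent solubilities on the same concentration scale as
#' `Cm`. Reproduces both anchors exactly at `f1 = 0` and `f1 = 1`.
#'
#' @param lambda12,lambda21 Positive model constants.
#' @param C1,C2 Neat cosolvent / water solubilities at the working
#'   temperature.
#' @param f1 Cosolvent volume fraction(s).
#' @return Predicted solubility.
#' @export
wilson_predict <- function(lambda12, lambda21, C1, C2, f1) {
  stopifnot(lambda12 > 0, lambda21 > 0, all(f1 >= 0 & f1 <= 1))
  f2 <- 1 - f1
  den1 <- f1 + f2 * lambda12
  den2 <- f1 * lambda21 + f2
  if (any(abs(den1) < 1e-12) || any(abs(den2) < 1e-12))
    stop("degenerate Wilson denominator")
  neg_ln <- 1 - f1 * (1 + log(C1)) / den1 - f2 * (1 + log(C2)) / den2
  exp(-neg_ln)
}

#' Fit the modified Wilson constants at one temperature
#'
#' Minimizes the sum of squared ln-scale residuals over
#' `(lambda12, lambda21) > 0` by bounded quasi-Newton optimisation from a
#' 3 x 3 multi-start grid over `[0.1, 5]^2`; the lowest objective wins, ties
#' (< 1e-12) broken by the smaller `lambda12`.
#'
#' @param dataset A [solubility_dataset()] restricted to one temperature, or
#'   a data frame with columns `f1`, `C` (and optionally a constant `T`).
#' @param starts Optional matrix of starting pairs (rows).
#' @return An object of class `wilson_params`: list with `lambda12`,
#'   `lambda21`, `T`, `objective` (ln-scale SSR), `anchors`, `convergence`.
#' @examples
#' d25 <- dataset_subset(asa_ethanol_water(), "primary_solute", 298.15)
#' wilson_fit(d25)
#' @export
wilson_fit <- function(dataset, starts = NULL) {
  d <- .model_frame(dataset)
  if (length(unique(d$T)) > 1L)
    stop("the modified Wilson model is isothermal: supply one temperature")
  anchors <- .ja_anchors(d$f1, d$T, d$C)[[1]]
  interior <- d$f1 > 0 & d$f1 < 1
  if (sum(interior) < 4L)
    stop("underdetermined fit: need >= 4 mixture points plus both anchors")
  C1 <- anchors[["C1"]]; C2 <- anchors[["C2"]]
  obj <- function(p) {
    pr <- tryCatch(wilson_predict(p[1], p[2], C1, C2, d$f1),
                   error = function(e) NULL)
    if (is.null(pr) || any(!is.finite(pr))) return(1e10)
    sum((log(pr) - log(d$C))^2)
  }
  if (is.null(starts))
    starts <- as.matrix(expand.grid(l12 = c(0.1, 1, 5), l21 = c(0.1, 1, 5)))
  best <- NULL
  ok <- FALSE
  for (k in seq_len(nrow(starts))) {
    o <- tryCatch(
      optim(starts[k, ], obj, method = "L-BFGS-B",
            lower = c(1e-6, 1e-6), upper = c(1e3, 1e3),
            control = list(factr = 1, maxit = 1000, ndeps = rep(1e-7, 2))),
      error = function(e) NULL)
    if (is.null(o)) next
    ok <- ok || o$convergence == 0
    if (is.null(best) || o$value < best$value - 1e-12 ||
        (abs(o$value - best$value) < 1e-12 && o$par[1] < best$par[1]))
      best <- o
  }
  if (is.null(best) || !ok)
    stop("Wilson fit failed to converge from every start")
  # derivative-free polish: tightens the optimum well below the quasi-Newton
  # finite-difference resolution
  pol <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
  if (pol$value <= best$value) best <- pol
  structure(list(lambda12 = unname(best$par[1]), lambda21 = unname(best$par[2]),
                 T = d$T[1], objective = best$value,
                 anchors = anchors, convergence = best$convergence),
            class = "wilson_params")
}

#' @export
print.wilson_params <- function(x, ...) {
  cat(sprintf("Modified Wilson constants at %.2f K: lambda12 = %.4f, lambda21 = %.4f\n",
              x$T, x$lambda12, x$lambda21))
  invisible(x)
}

# Accept a solubility_dataset (primary solute) or a plain data frame with
# f1 / T / C columns.
.model_frame <- function(dataset) {
  if (inherits(dataset, "solubility_dataset"))
    dataset <- dataset_subset(dataset, analyte = "primary_solute")
  d <- as.data.frame(dataset)
  if (is.null(d$T)) d$T <- NA_real_
  stopifnot(all(c("f1", "C") %in% names(d)))
  d[, c("f1", "T", "C")]
}
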