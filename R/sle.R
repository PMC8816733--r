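# Solid-liquid equilibrium: ideal solubility from fusion properties plus
# PC-SAFT activity-coefficient iteration.

#' Ideal mole-fraction solubility from fusion properties
#'
#' `x_ideal = exp[(dHm / R) (1/Tm - 1/T)]`: the solubility a crystalline
#' solid would have in an ideal solution (activity coefficient 1), driven by
#' its melting temperature and fusion enthalpy. No heat-capacity correction
#' is applied.
#'
#' @param fusion A [fusion_properties()] object.
#' @param T Absolute temperature(s), K. Temperatures above `Tm` warn (the
#'   subcooled-solid picture no longer applies).
#' @return Ideal mole-fraction solubility.
#' @examples
#' ideal_solubility(asa_fusion_properties(), 298.15)  # ~0.0314
#' @export
ideal_solubility <- function(fusion, T) {
  stopifnot(inherits(fusion, "fusion_properties"), all(T > 0))
  if (any(T > fusion$Tm))
    warning("T above the melting temperature: not a solid-liquid equilibrium")
  exp(fusion$dHm / .Rgas * (1 / fusion$Tm - 1 / T))
}

#' Solute-free solvent mole fractions from a volume fraction
#'
#' Converts the cosolvent volume fraction of a solute-free binary mixture to
#' mole fractions through the pure-liquid densities and molar masses at `T`.
#'
#' @param f1 Cosolvent volume fraction(s) in `[0, 1]`.
#' @param system A [solvent_system()].
#' @param T Temperature, K.
#' @return Matrix with columns `x1` (cosolvent) and `x2` (water), one row per
#'   `f1`.
#' @examples
#' solvent_mole_fractions(0.5)  # x1 ~ 0.236
#' @export
solvent_mole_fractions <- function(f1, system = ethanol_water_system(), T = 298.15) {
  stopifnot(all(f1 >= 0 & f1 <= 1))
  n1 <- f1 * solvent_density(system, T, "cosolvent") * 1000 / system$cosolvent_molar_mass
  n2 <- (1 - f1) * solvent_density(system, T, "water") * 1000 / system$water_molar_mass
  x1 <- n1 / (n1 + n2)
  cbind(x1 = x1, x2 = 1 - x1)
}

#' Solve solid-liquid-equilibrium solubility with PC-SAFT activities
#'
#' Damped fixed-point iteration on the mole-fraction solubility:
#' `x_new = x_ideal / gamma(x)`, where the activity coefficient of the solute
#' comes from the PC-SAFT fugacity-coefficient ratio between the saturated
#' mixture and the pure (hypothetical subcooled liquid) solute at the same
#' temperature and pressure. The solute-free solvent ratio is held fixed
#' while the mixture is renormalized with the solute. Initialized at
#' `x_ideal` (gamma = 1).
#'
#' @param solute A [pcsaft_component()] for the solute.
#' @param fusion [fusion_properties()] of the solute.
#' @param solvents List of two [pcsaft_component()]s (cosolvent, water).
#' @param f1 Cosolvent volume fraction (solute-free).
#' @param T Temperature, K.
#' @param P Pressure, bar.
#' @param system [solvent_system()] used to convert `f1` to solvent mole
#'   fractions.
#' @param kij Optional 3 x 3 binary-interaction matrix (solute, cosolvent,
#'   water); defaults to zeros.
#' @param damping Fixed-point damping factor in (0, 1].
#' @param tol Relative convergence tolerance on x.
#' @param max_iter Iteration cap.
#' @param activity `"pcsaft"`, or `"ideal"` to force gamma = 1 (returns the
#'   closed-form ideal solubility; useful as a consistency reduction).
#' @return An object of class `sle_result`: list with `x` (mole-fraction
#'   solubility), `gamma`, `x_ideal`, `iterations`, `converged`, `residual`
#'   (fixed-point residual `|x - x_ideal/gamma(x)|`), `clipped` and the
#'   iterate `trace`.
#' @examples
#' \donttest{
#' comps <- asa_pcsaft_components()
#' sle_solubility(comps$asa, asa_fusion_properties(),
#'                comps[c("ethanol", "water")], f1 = 1, T = 298.15)
#' }
#' @export
sle_solubility <- function(solute, fusion, solvents, f1, T, P = 1.013,
                           system = ethanol_water_system(), kij = NULL,
                           damping = 0.5, tol = 1e-8, max_iter = 200,
                           activity = c("pcsaft", "ideal")) {
  activity <- match.arg(activity)
  stopifnot(f1 >= 0, f1 <= 1, damping > 0, damping <= 1)
  x_id <- ideal_solubility(fusion, T)
  if (activity == "ideal")
    return(structure(list(x = x_id, gamma = 1, x_ideal = x_id, iterations = 0L,
                          converged = TRUE, residual = 0, clipped = FALSE,
                          trace = x_id, f1 = f1, T = T),
                     class = "sle_result"))
  comps <- c(list(solute), solvents)
  par <- .psx(comps)
  if (is.null(kij)) kij <- matrix(0, 3, 3)
  P_Pa <- P * 1e5
  xs <- solvent_mole_fractions(f1, system, T)[1, ]
  # pure-solute (subcooled liquid) reference, computed once
  par1 <- .psx(comps[1])
  rho1 <- .solve_density_num(par1, T, 1, P_Pa, "liquid", matrix(0, 1, 1))
  lnphi0 <- .lnphi_num(par1, T, 1, rho1, matrix(0, 1, 1))$lnphi
  x <- x_id
  gam <- 1
  clipped <- FALSE
  trace <- numeric(0)
  eta_prev <- NULL
  converged <- FALSE
  md3 <- function(xv) {
    d <- par$sig * (1 - 0.12 * exp(-3 * par$eps / T))
    sum(xv * par$m * d^3)
  }
  for (it in seq_len(max_iter)) {
    xv <- c(x, (1 - x) * xs)
    rho <- .solve_density_num(par, T, xv, P_Pa, "liquid", kij, eta_init = eta_prev)
    eta_prev <- pi / 6 * rho * md3(xv)
    lp <- .lnphi_num(par, T, xv, rho, kij)$lnphi
    gam <- exp(lp[1] - lnphi0)
    target <- x_id / gam
    if (target >= 1) { target <- 1 - 1e-12; clipped <- TRUE }
    x_new <- (1 - damping) * x + damping * target
    trace <- c(trace, x_new)
    if (abs(target - x) <= tol * max(x, .Machine$double.eps)) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged) {
    msg <- paste0("SLE iteration did not converge in ", max_iter,
                  " steps; last iterates: ",
                  paste(signif(tail(trace, 5), 6), collapse = ", "))
    stop(msg)
  }
  if (clipped) warning("solubility iterate clipped to (0, 1)")
  structure(list(x = x, gamma = unname(gam), x_ideal = x_id, iterations = it,
                 converged = converged,
                 residual = abs(x - x_id / gam), clipped = clipped,
                 trace = trace, f1 = f1, T = T),
            class = "sle_result")
}

#' @export
print.sle_result <- function(x, ...) {
  cat(sprintf(
    "SLE solubility at f1 = %.2f, T = %.2f K: x = %.4g (gamma = %.4g, ideal %.4g)\n",
    x$f1, x$T, x$x, x$gamma, x$x_ideal))
  cat(sprintf("  %d iterations, residual %.2g%s\n", x$iterations, x$residual,
              if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Predicted solubility profile over a composition/temperature grid
#'
#' Runs [sle_solubility()] over all combinations of `f1` and `T` and collects
#' the prediction table.
#'
#' @inheritParams sle_solubility
#' @param f1 Vector of cosolvent volume fractions.
#' @param T Vector of temperatures, K.
#' @return Data frame with columns `f1`, `T_C`, `x_pred`, `gamma`,
#'   `converged`, `iterations`.
#' @export
sle_profile <- function(solute, fusion, solvents, f1 = seq(0, 1, 0.1),
                        T = c(298.15, 310.15), P = 1.013,
                        system = ethanol_water_system(), kij = NULL,
                        damping = 0.5, tol = 1e-8, max_iter = 200,
                        activity = c("pcsaft", "ideal")) {
  activity <- match.arg(activity)
  grid <- expand.grid(f1 = f1, T = T)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- sle_solubility(solute, fusion, solvents, grid$f1[i], grid$T[i], P,
                        system, kij, damping, tol, max_iter, activity)
    data.frame(f1 = grid$f1[i], T_C = grid$T[i] - 273.15, x_pred = r$x,
               gamma = r$gamma, converged = r$converged,
               iterations = r$iterations)
  })
  do.call(rbind, rows)
}
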