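# Reference data for acetylsalicylic acid (ASA, aspirin) in ethanol + water.
# Molar solubilities (mol/L) at 298.15 and 310.15 K over 11 cosolvent volume
# fractions, for ASA and for the salicylic acid generated by its hydrolysis.

.asa_f1 <- 0:10 / 10   # exact doubles, so f1 == 0.3 etc. match literals

.asa_C25 <- c(2.46e-2, 3.47e-2, 5.92e-2, 1.28e-1, 2.71e-1, 4.31e-1,
              5.46e-1, 6.82e-1, 7.77e-1, 8.68e-1, 8.26e-1)
.asa_sd25 <- c(0.06e-2, 0.11e-2, 0.25e-2, 0.00e-1, 0.05e-1, 0.02e-1,
               0.14e-1, 0.03e-1, 0.02e-1, 0.52e-1, 0.23e-1)
.asa_C37 <- c(3.08e-2, 5.22e-2, 1.01e-1, 2.04e-1, 4.09e-1, 6.71e-1,
              8.16e-1, 9.95e-1, 1.06, 1.13, 9.88e-1)
.asa_sd37 <- c(0.00e-2, 0.01e-2, 0.00e-1, 0.04e-1, 0.03e-1, 0.08e-1,
               0.92e-1, 0.16e-1, 0.19, 0.08, 0.02e-1)

.sa_C25 <- c(7.26e-4, 8.78e-4, 1.04e-3, 1.95e-3, 1.86e-3, 2.98e-3,
             3.16e-3, 3.67e-3, 3.28e-3, 3.73e-3, 3.38e-3)
.sa_sd25 <- c(0.12e-4, 0.63e-4, 0.09e-3, 0.00e-3, 0.00e-3, 0.00e-3,
              0.00e-3, 0.05e-3, 0.73e-3, 0.00e-3, 0.52e-3)
.sa_C37 <- c(3.20e-3, 4.47e-3, 7.78e-3, 1.84e-2, 3.24e-2, 4.31e-2,
             4.52e-2, 5.33e-2, 5.52e-2, 4.94e-2, 5.24e-2)
.sa_sd37 <- c(0.13e-3, 0.25e-3, 0.60e-3, 0.00e-2, 0.00e-2, 0.00e-2,
              0.00e-2, 0.00e-2, 0.44e-2, 0.01e-2, 0.01e-2)

# Literature saturation solubility of salicylic acid itself in the same
# mixtures at 298.15 K (mol/L), used for the undersaturation check.
.sa_sat25 <- c(1.37e-2, 1.73e-2, 3.24e-2, 8.09e-2, 2.10e-1, 4.81e-1,
               9.62e-1, 1.38, 1.84, 2.21, 2.11)

#' Reference solubility dataset: acetylsalicylic acid in ethanol + water
#'
#' The packaged measurement set for acetylsalicylic acid (ASA) saturated in
#' ethanol + water mixtures at 298.15 K and 310.15 K: 11 cosolvent volume
#' fractions (0.00 to 1.00, step 0.10) per temperature, for the parent drug
#' (`"primary_solute"`) and for the salicylic acid formed by its hydrolysis
#' during the experiment (`"degradation_product"`) -- 44 records in total.
#' All concentrations are molar (mol/L); `sd` holds the standard deviation of
#' triplicate measurements.
#'
#' @return A [solubility_dataset()] with solute metadata (molar mass
#'   180.16 g/mol, log P 1.18).
#' @seealso [sa_saturation_reference()] for the literature saturation
#'   solubility of salicylic acid used in the undersaturation check.
#' @examples
#' d <- asa_ethanol_water()
#' subset(d, analyte == "primary_solute" & T == 298.15)
#' @export
asa_ethanol_water <- function() {
  rec <- data.frame(
    f1 = rep(.asa_f1, 4),
    T = rep(rep(c(.T25, .T37), each = 11), 2),
    C = c(.asa_C25, .asa_C37, .sa_C25, .sa_C37),
    sd = c(.asa_sd25, .asa_sd37, .sa_sd25, .sa_sd37),
    analyte = rep(c("primary_solute", "degradation_product"), each = 22))
  solubility_dataset(rec, system = ethanol_water_system(),
                     solute_name = "acetylsalicylic acid",
                     solute_molar_mass = .MM_ASA, solute_logP = 1.18)
}

#' Literature salicylic acid saturation solubilities at 298.15 K
#'
#' Saturation (intrinsic) molar solubility of salicylic acid in the same
#' ethanol + water mixtures at 298.15 K, from the literature. Serves as the
#' reference series for [undersaturation_check()]: the salicylic acid found in
#' ASA-saturated solutions stays below these values, so it never precipitates.
#'
#' @return Data frame with columns `f1` and `C_sat` (mol/L).
#' @export
sa_saturation_reference <- function() {
  data.frame(f1 = .asa_f1, C_sat = .sa_sat25)
}

#' Fusion properties of acetylsalicylic acid crystals
#'
#' Peak melting temperatures and fusion enthalpies measured by DSC on ASA
#' before ("untreated") and after equilibration with different ethanol + water
#' ratios. The untreated row is the default input for the ideal-solubility
#' term of the solid-liquid-equilibrium solver.
#'
#' @param sample One of `"untreated"`, `"water_25"`, `"water_37"`,
#'   `"50_50_25"`, `"50_50_37"`, `"ethanol_25"`, `"ethanol_37"`.
#' @return A [fusion_properties()] object (Tm in K, dHm in J/mol using the
#'   ASA molar mass 180.16 g/mol).
#' @export
asa_fusion_properties <- function(sample = "untreated") {
  tab <- list( # melting point (C), enthalpy of fusion (J/g)
    untreated = c(145.3, 165.6),
    water_25 = c(142.9, 147.7), water_37 = c(137.8, 130.7),
    "50_50_25" = c(141.3, 139.5), "50_50_37" = c(144.4, 161.0),
    ethanol_25 = c(143.7, 156.2), ethanol_37 = c(144.3, 155.4))
  if (!sample %in% names(tab))
    stop("unknown sample; one of: ", paste(names(tab), collapse = ", "))
  v <- tab[[sample]]
  fusion_properties(Tm = v[1] + 273.15, dHm = v[2] * .MM_ASA)
}

#' Fusion properties driving ideal solubility
#'
#' @param Tm Melting temperature, K.
#' @param dHm Enthalpy of fusion, J/mol.
#' @return An object of class `fusion_properties`.
#' @export
fusion_properties <- function(Tm, dHm) {
  stopifnot(Tm > 0, dHm > 0)
  structure(list(Tm = Tm, dHm = dHm), class = "fusion_properties")
}

#' @export
print.fusion_properties <- function(x, ...) {
  cat(sprintf("Fusion properties: Tm = %.2f K, dHm = %.0f J/mol\n", x$Tm, x$dHm))
  invisible(x)
}

#' Reference crystallinity indices of recovered ASA samples
#'
#' Percent crystallinity (diffraction peak-area ratio at the 7.8 and 15.6
#' degree 2-theta reflections) of original ASA and of the solid recovered
#' after the solubility experiments. Shipped as a reference table only; the
#' raw diffractogram areas behind it are not available.
#'
#' @return Data frame with columns `sample`, `T_C`, `crystallinity_percent`.
#' @export
asa_crystallinity_reference <- function() {
  data.frame(
    sample = rep(c("original", "water", "ethanol", "50_50"), each = 2),
    T_C = rep(c(25, 37), 4),
    crystallinity_percent = c(44.3, 44.3, 32.3, 23.1, 35.5, 40.7, 33.6, 42.8))
}

#' Abraham solute descriptors
#'
#' Linear free-energy-relationship descriptors of a solute: excess molar
#' refraction `E`, dipolarity/polarizability `S`, hydrogen-bond acidity `A`,
#' hydrogen-bond basicity `B` and McGowan volume `V`. Consumed by the
#' Abraham-extended trained mixture model ([ja_trained_predict()]).
#'
#' @param E,S,A,B,V Descriptor values; `V` must be positive.
#' @return An object of class `abraham_descriptors`.
#' @export
abraham_descriptors <- function(E, S, A, B, V) {
  stopifnot(V > 0)
  structure(list(E = E, S = S, A = A, B = B, V = V),
            class = "abraham_descriptors")
}

#' @rdname abraham_descriptors
#' @export
asa_abraham_descriptors <- function() {
  abraham_descriptors(E = 0.84, S = 1.42, A = 0.57, B = 0.77, V = 1.29)
}
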