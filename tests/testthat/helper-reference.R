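# Shared reference quantities used across test files.

ref <- list(
  # printed Jouyban-Acree coefficients for ASA in ethanol + water
  J_printed = c(1426.596, 515.373, -1084.479),
  # printed modified Wilson constants per temperature
  wilson_25 = c(lambda12 = 0.394, lambda21 = 2.537),
  wilson_37 = c(lambda12 = 0.294, lambda21 = 3.405),
  # neat-solvent molar solubilities (mol/L)
  C1_25 = 0.826, C2_25 = 0.0246,
  C1_37 = 0.988, C2_37 = 0.0308,
  # ethanol log-linear cosolvent constants and ASA log P
  M = 2.14, N = 0.92, logP = 1.18)

asa25 <- function() dataset_subset(asa_ethanol_water(), "primary_solute", 298.15)
asa37 <- function() dataset_subset(asa_ethanol_water(), "primary_solute", 310.15)

# a small non-associating + associating test pair reused in EOS tests
toy_components <- function() {
  list(
    plain = pcsaft_component("plain", 2.0, 3.5, 250, 0, 0, "none", 100),
    gated = pcsaft_component("gated", 2.0, 3.5, 250, 0, 2500, "2B", 100),
    assoc = pcsaft_component("assoc", 2.0, 3.5, 250, 0.03, 2500, "2B", 100))
}
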