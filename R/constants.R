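# Physical constants and fixed molar masses (g/mol)
.kB <- 1.380649e-23          # Boltzmann, J/K
.NAvogadro <- 6.02214076e23  # 1/mol
.Rgas <- 8.31446261815324    # J/(mol K)

.MM_ASA <- 180.16
.MM_ETHANOL <- 46.07
.MM_WATER <- 18.015

# Pure-liquid densities (g/cm^3) at 298.15 / 310.15 K, standard literature
# values; used only where volume fractions must be converted to mole
# fractions. User-supplied systems override.
.DENS_WATER <- c("298.15" = 0.99705, "310.15" = 0.99333)
.DENS_ETHANOL <- c("298.15" = 0.78522, "310.15" = 0.77641)

.T25 <- 298.15
.T37 <- 310.15
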