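#' Describe a binary aqueous-cosolvent system
#'
#' Holds the names, pure-liquid densities and molar masses of the cosolvent
#' (solvent 1) and water (solvent 2). Densities are tabulated per temperature
#' and interpolated linearly in between; they are needed only where volume
#' fractions or molarities must be converted to mole fractions.
#'
#' @param cosolvent_name,water_name Solvent labels.
#' @param cosolvent_density,water_density Named numeric vectors of pure-liquid
#'   densities in g/cm^3; names are absolute temperatures in K.
#' @param cosolvent_molar_mass,water_molar_mass Molar masses in g/mol.
#' @return An object of class `solvent_system`.
#' @examples
#' sys <- ethanol_water_system()
#' solvent_density(sys, 298.15)
#' @export
solvent_system <- function(cosolvent_name, water_name = "water",
                           cosolvent_density, water_density,
                           cosolvent_molar_mass, water_molar_mass = .MM_WATER) {
  stopifnot(is.numeric(cosolvent_density), is.numeric(water_density))
  if (any(cosolvent_density <= 0) || any(water_density <= 0))
    stop("densities must be positive")
  if (cosolvent_molar_mass <= 0 || water_molar_mass <= 0)
    stop("molar masses must be positive")
  if (is.null(names(cosolvent_density)) || is.null(names(water_density)))
    stop("density vectors must be named by temperature in K")
  structure(list(
    cosolvent_name = cosolvent_name, water_name = water_name,
    cosolvent_density = cosolvent_density, water_density = water_density,
    cosolvent_molar_mass = cosolvent_molar_mass,
    water_molar_mass = water_molar_mass
  ), class = "solvent_system")
}

#' @rdname solvent_system
#' @export
ethanol_water_system <- function() {
  solvent_system("ethanol", "water",
                 cosolvent_density = .DENS_ETHANOL,
                 water_density = .DENS_WATER,
                 cosolvent_molar_mass = .MM_ETHANOL)
}

#' Pure-liquid density of a system solvent at a temperature
#'
#' @param system A [solvent_system()].
#' @param T Absolute temperature in K.
#' @param which `"cosolvent"` or `"water"`.
#' @return Density in g/cm^3 (linear interpolation/extrapolation on the
#'   tabulated temperatures).
#' @export
solvent_density <- function(system, T, which = c("cosolvent", "water")) {
  which <- match.arg(which)
  tab <- if (which == "cosolvent") system$cosolvent_density else system$water_density
  Ts <- as.numeric(names(tab))
  if (length(tab) == 1L) return(unname(tab))
  o <- order(Ts)
  stats::approx(Ts[o], tab[o], xout = T, rule = 2)$y
}

#' @export
print.solvent_system <- function(x, ...) {
  cat(sprintf("Binary solvent system: %s (1) + %s (2)\n",
              x$cosolvent_name, x$water_name))
  cat(sprintf("  molar masses: %.3f / %.3f g/mol\n",
              x$cosolvent_molar_mass, x$water_molar_mass))
  cat("  densities (g/cm^3):\n")
  Ts <- union(names(x$cosolvent_density), names(x$water_density))
  for (tt in Ts)
    cat(sprintf("    %s K: %s %.5f, %s %.5f\n", tt, x$cosolvent_name,
                x$cosolvent_density[[tt]], x$water_name, x$water_density[[tt]]))
  invisible(x)
}

.valid_analytes <- c("primary_solute", "degradation_product")

#' Construct a validated solubility dataset
#'
#' A solubility dataset is a data frame of saturation measurements of one
#' solute in one binary solvent system, with columns `f1` (solute-free
#' cosolvent volume fraction), `T` (absolute temperature, K), `C` (molar
#' solubility, mol/L), `sd` (standard deviation of replicates, mol/L) and
#' `analyte` (`"primary_solute"` or `"degradation_product"`).
#'
#' @param records Data frame with columns `f1`, `T`, `C`, `sd`, `analyte`
#'   (`sd` may be omitted and defaults to 0; `analyte` defaults to
#'   `"primary_solute"`).
#' @param system A [solvent_system()].
#' @param solute_name Solute label.
#' @param solute_molar_mass Molar mass of the solute, g/mol.
#' @param solute_logP Octanol-water log P of the solute (used by the
#'   predictive log-linear model).
#' @return A data frame of class `solubility_dataset` with the validated
#'   records and the solute/system metadata stored as attributes.
#' @examples
#' d <- solubility_dataset(
#'   data.frame(f1 = c(0, 0.5, 1), T = 298.15, C = c(0.02, 0.4, 0.8)),
#'   solute_name = "demo", solute_molar_mass = 180.16)
#' @export
solubility_dataset <- function(records, system = ethanol_water_system(),
                               solute_name = "solute",
                               solute_molar_mass = NA_real_,
                               solute_logP = NA_real_) {
  records <- as.data.frame(records)
  if (!all(c("f1", "T", "C") %in% names(records)))
    stop("records need columns f1, T, C")
  if (is.null(records$sd)) records$sd <- 0
  if (is.null(records$analyte)) records$analyte <- "primary_solute"
  records <- records[, c("f1", "T", "C", "sd", "analyte")]
  bad <- which(!(records$f1 >= 0 & records$f1 <= 1))
  if (length(bad)) stop("f1 outside [0, 1] in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!(records$C > 0))
  if (length(bad)) stop("C must be > 0 in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!(records$sd >= 0))
  if (length(bad)) stop("sd must be >= 0 in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!(records$T > 0))
  if (length(bad)) stop("T must be > 0 (Kelvin) in row(s) ", paste(bad, collapse = ", "))
  if (!all(records$analyte %in% .valid_analytes))
    stop("analyte must be one of: ", paste(.valid_analytes, collapse = ", "))
  key <- paste(records$f1, records$T, records$analyte)
  if (anyDuplicated(key))
    stop("duplicate (f1, T, analyte) keys: ", paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(records) <- NULL
  structure(records,
            system = system, solute_name = solute_name,
            solute_molar_mass = solute_molar_mass, solute_logP = solute_logP,
            class = c("solubility_dataset", "data.frame"))
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat(sprintf("Solubility dataset: %s in %s + %s\n", attr(x, "solute_name"),
              attr(x, "system")$cosolvent_name, attr(x, "system")$water_name))
  cat(sprintf("  %d records, %d temperature(s): %s K\n", nrow(x),
              length(unique(x$T)), paste(sort(unique(x$T)), collapse = ", ")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Subset a solubility dataset
#'
#' Filter by analyte and/or temperature while keeping metadata attributes.
#'
#' @param dataset A [solubility_dataset()].
#' @param analyte,T Optional filters.
#' @return A `solubility_dataset`.
#' @export
dataset_subset <- function(dataset, analyte = NULL, T = NULL) {
  keep <- rep(TRUE, nrow(dataset))
  if (!is.null(analyte)) keep <- keep & dataset$analyte %in% analyte
  if (!is.null(T)) keep <- keep & dataset$T %in% T
  out <- as.data.frame(dataset)[keep, , drop = FALSE]
  solubility_dataset(out, system = attr(dataset, "system"),
                     solute_name = attr(dataset, "solute_name"),
                     solute_molar_mass = attr(dataset, "solute_molar_mass"),
                     solute_logP = attr(dataset, "solute_logP"))
}

#' Read a solubility dataset from CSV
#'
#' Expected columns (renameable through `schema`): `f1`, `T_C` (temperature in
#' Celsius), `C_molar`, `sd`, `analyte`. Temperatures are converted to Kelvin
#' on load; rows violating the dataset invariants are rejected with an error.
#'
#' @param path CSV file path (comma-separated, `.` decimal, header row).
#' @param schema Named character vector mapping the canonical column names to
#'   the names used in the file.
#' @inheritParams solubility_dataset
#' @return A [solubility_dataset()].
#' @export
read_solubility_csv <- function(path, schema = c(f1 = "f1", T_C = "T_C",
                                                 C_molar = "C_molar", sd = "sd",
                                                 analyte = "analyte"),
                                system = ethanol_water_system(),
                                solute_name = "solute",
                                solute_molar_mass = NA_real_,
                                solute_logP = NA_real_) {
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
                  error = function(e) stop("cannot parse CSV '", path, "': ",
                                           conditionMessage(e)))
  if (nrow(raw) == 0L) stop("empty dataset file: ", path)
  need <- c("f1", "T_C", "C_molar")
  miss <- need[!schema[need] %in% names(raw)]
  if (length(miss)) stop("missing column(s): ", paste(schema[miss], collapse = ", "))
  num <- function(col) {
    v <- raw[[schema[[col]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !(is.na(v) | v == ""))
    if (length(bad)) stop("non-numeric value in column '", schema[[col]],
                          "', row(s) ", paste(bad, collapse = ", "))
    out
  }
  rec <- data.frame(f1 = num("f1"), T = num("T_C") + 273.15, C = num("C_molar"))
  rec$sd <- if (schema[["sd"]] %in% names(raw)) num("sd") else 0
  rec$sd[is.na(rec$sd)] <- 0
  rec$analyte <- if (schema[["analyte"]] %in% names(raw)) raw[[schema[["analyte"]]]] else "primary_solute"
  solubility_dataset(rec, system = system, solute_name = solute_name,
                     solute_molar_mass = solute_molar_mass,
                     solute_logP = solute_logP)
}

#' Write a solubility dataset to CSV
#'
#' Emits the same schema that [read_solubility_csv()] expects, with the
#' temperature column in Celsius. Numeric fields are written with full
#' precision so that a read/write round trip reproduces them bit-identically.
#'
#' @param dataset A [solubility_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_solubility_csv <- function(dataset, path) {
  out <- data.frame(
    f1 = sprintf("%.17g", dataset$f1),
    T_C = sprintf("%.17g", dataset$T - 273.15),
    C_molar = sprintf("%.17g", dataset$C),
    sd = sprintf("%.17g", dataset$sd),
    analyte = dataset$analyte)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert molar solubility to mole-fraction solubility
#'
#' Mass balance over one litre of saturated solution: the solute contributes
#' `C` mol; the remaining mass (from the measured solution density) is split
#' between cosolvent and water according to the solute-free volume fraction
#' `f1` (converted to a solute-free mass ratio with the pure-liquid
#' densities at `T`).
#'
#' @param C Molar solubility, mol/L.
#' @param solution_density Measured saturated-solution density, g/cm^3.
#' @param f1 Solute-free cosolvent volume fraction.
#' @param system A [solvent_system()].
#' @param solute_molar_mass Solute molar mass, g/mol.
#' @param T Temperature in K (for the pure-liquid density split).
#' @return Mole fraction of the solute, in `[0, 1)`.
#' @examples
#' molar_to_mole_fraction(0.0246, 1.0, 0, solute_molar_mass = 180.16)
#' @export
molar_to_mole_fraction <- function(C, solution_density, f1,
                                   system = ethanol_water_system(),
                                   solute_molar_mass, T = 298.15) {
  stopifnot(solution_density > 0, f1 >= 0, f1 <= 1, C >= 0)
  mass_total <- solution_density * 1000            # g in 1 L
  mass_solute <- C * solute_molar_mass
  mass_solvent <- mass_total - mass_solute
  if (any(mass_solvent <= 0))
    stop("solution density implies non-positive solvent mass")
  # solute-free mass split of the solvent from volume fractions
  m1 <- f1 * solvent_density(system, T, "cosolvent")
  m2 <- (1 - f1) * solvent_density(system, T, "water")
  w1 <- m1 / (m1 + m2)
  n1 <- mass_solvent * w1 / system$cosolvent_molar_mass
  n2 <- mass_solvent * (1 - w1) / system$water_molar_mass
  n_solute <- C
  n_solute / (n_solute + n1 + n2)
}
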