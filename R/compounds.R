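# Compound registry: chemical species tracked in the liquid and gas phases,
# their elemental formulas (neutral free-acid convention for carboxylates),
# molar masses, and degree-of-reduction electron equivalents.

.ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, He = 4.0026)

.registry_row <- function(name, C = 0, H = 0, O = 0, N = 0, He = 0,
                          phase = c("liquid", "gas"), role = "product") {
  phase <- match.arg(phase)
  mm <- sum(.ATOMIC_WEIGHTS * c(C, H, O, N, He))
  data.frame(name = name, C = C, H = H, O = O, N = N, He = He,
             molar_mass = mm, phase = phase, role = role,
             stringsAsFactors = FALSE)
}

#' Registry of chemical species
#'
#' Builds the default registry of compounds measured in lactate/acetate
#' chain-elongation fermenters with H2/CO2 gas recirculation: the HPLC-measured
#' carboxylates and alcohols in the liquid phase and the GC-measured species in
#' the gas phase (H2, CO2, CH4, He, O2, N2, ethylene). Carboxylates are
#' registered as neutral free acids, so g/L and mM interconvert on the free-acid
#' molar mass. Biomass uses the generic composition CH1.8O0.5N0.2 per C-mol.
#'
#' @return A data frame with one row per compound: element counts (C, H, O, N,
#'   He), `molar_mass` (g/mol, from standard atomic weights), `phase`
#'   (`"liquid"` or `"gas"`) and `role` (substrate, product, tracer, inhibitor,
#'   contaminant, or solvent).
#' @examples
#' reg <- compound_registry()
#' reg[reg$name == "lactate", "molar_mass"]
#' @export
compound_registry <- function() {
  rows <- list(
    .registry_row("formate",      1,  2, 2, phase = "liquid"),
    .registry_row("acetate",      2,  4, 2, phase = "liquid", role = "substrate"),
    .registry_row("ethanol",      2,  6, 1, phase = "liquid"),
    .registry_row("lactate",      3,  6, 3, phase = "liquid", role = "substrate"),
    .registry_row("propionate",   3,  6, 2, phase = "liquid"),
    .registry_row("n-propanol",   3,  8, 1, phase = "liquid"),
    .registry_row("n-butyrate",   4,  8, 2, phase = "liquid"),
    .registry_row("i-butyrate",   4,  8, 2, phase = "liquid"),
    .registry_row("n-butanol",    4, 10, 1, phase = "liquid"),
    .registry_row("n-valerate",   5, 10, 2, phase = "liquid"),
    .registry_row("i-valerate",   5, 10, 2, phase = "liquid"),
    .registry_row("n-pentanol",   5, 12, 1, phase = "liquid"),
    .registry_row("n-caproate",   6, 12, 2, phase = "liquid"),
    .registry_row("i-caproate",   6, 12, 2, phase = "liquid"),
    .registry_row("n-hexanol",    6, 14, 1, phase = "liquid"),
    .registry_row("n-heptanoate", 7, 14, 2, phase = "liquid"),
    .registry_row("n-caprylate",  8, 16, 2, phase = "liquid"),
    .registry_row("water",        0,  2, 1, phase = "liquid", role = "solvent"),
    .registry_row("biomass",      1, 1.8, 0.5, 0.2, phase = "liquid"),
    .registry_row("h2",           0,  2, 0, phase = "gas", role = "substrate"),
    .registry_row("co2",          1,  0, 2, phase = "gas", role = "substrate"),
    .registry_row("ch4",          1,  4, 0, phase = "gas"),
    .registry_row("he",           He = 1, phase = "gas", role = "tracer"),
    .registry_row("o2",           0,  0, 2, phase = "gas", role = "contaminant"),
    .registry_row("n2",           0,  0, 0, 2, phase = "gas", role = "contaminant"),
    .registry_row("ethylene",     2,  4, 0, phase = "gas", role = "inhibitor")
  )
  reg <- do.call(rbind, rows)
  rownames(reg) <- reg$name
  reg
}

.default_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- compound_registry()
    cache
  }
})

#' Look up one compound
#'
#' @param name Canonical lowercase compound name (e.g. `"n-caproate"`, `"h2"`).
#' @param registry Registry data frame; defaults to [compound_registry()].
#' @return The single registry row for that compound.
#' @export
compound <- function(name, registry = NULL) {
  if (is.null(registry)) registry <- .default_registry()
  hit <- registry[registry$name == name, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("unknown compound: '", name, "'", call. = FALSE)
  hit
}

#' Degree of reduction (electron equivalents per mole)
#'
#' Available electron equivalents per mole of compound under the convention
#' gamma = 4C + H - 2O - 3N on the neutral free-acid formula (ammonia as the
#' reference nitrogen state). CO2, H2O and He carry zero; O2 is negative (it is
#' an electron acceptor with capacity 4 e-/mol).
#'
#' @param x Compound name or a registry row.
#' @param registry Registry data frame.
#' @return Electron equivalents per mol (dimensionless, possibly negative).
#' @examples
#' degree_of_reduction("lactate")  # 12
#' degree_of_reduction("o2")       # -4
#' @export
degree_of_reduction <- function(x, registry = NULL) {
  row <- if (is.character(x)) compound(x, registry) else x
  unname(4 * row$C + row$H - 2 * row$O - 3 * row$N)
}

#' Convert a mass concentration to a molar concentration
#'
#' @param conc Concentration in g/L (non-negative).
#' @param name Compound name.
#' @param registry Registry data frame.
#' @return Concentration in mM (`1000 * conc / molar_mass`).
#' @examples
#' mass_to_molar(12, "lactate")  # ~133 mM
#' @export
mass_to_molar <- function(conc, name, registry = NULL) {
  stopifnot(all(conc >= 0))
  conc * 1000 / compound(name, registry)$molar_mass
}

#' @rdname mass_to_molar
#' @param conc_mM Concentration in mM.
#' @return `molar_to_mass()`: concentration in g/L.
#' @export
molar_to_mass <- function(conc_mM, name, registry = NULL) {
  conc_mM * compound(name, registry)$molar_mass / 1000
}

#' Write or read a compound registry as JSON
#'
#' @param registry Registry data frame.
#' @param path File path.
#' @return `read_registry_json()` returns the registry data frame.
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(registry, path, digits = NA)
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  reg <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  rownames(reg) <- reg$name
  reg
}
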