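#' Temperature-dependent Debye-Huckel solvent parameters
#'
#' Computes the A and B coefficients of the extended Debye-Huckel equation
#' from the density and static dielectric constant of pure water at 1 bar.
#' The dielectric constant follows the Malmberg-Maryott polynomial and the
#' density the Kell equation, both valid over 0-100 degrees C, which covers
#' any habitable spring water.
#'
#' @param temperature_C water temperature in degrees Celsius.
#' @return named numeric vector with elements `A` (kg^1/2 mol^-1/2) and
#'   `B` (kg^1/2 mol^-1/2 per Angstrom). At 25 C these evaluate to
#'   approximately 0.511 and 0.329.
#' @export
#' @examples
#' debye_huckel_AB(25)
debye_huckel_AB <- function(temperature_C) {
  stopifnot(is.numeric(temperature_C), temperature_C >= 0, temperature_C <= 100)
  t <- temperature_C
  TK <- t + 273.15
  eps <- 87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
  rho <- (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
            46.170461e-6 * t^3 + 105.56302e-9 * t^4 -
            280.54253e-12 * t^5) / (1 + 16.87985e-3 * t) / 1000
  c(A = 1.824829238e6 * sqrt(rho) / (eps * TK)^1.5,
    B = 50.29158649 * sqrt(rho) / sqrt(eps * TK))
}

#' Ion size parameters for the extended Debye-Huckel equation
#'
#' Effective ion diameters (Kielland convention, Angstroms) for the species
#' handled by [speciate()]. Neutral species are assigned size 0 and unit
#' activity coefficient.
#'
#' @return named numeric vector of ion sizes in Angstroms.
#' @export
ion_size_params <- function() {
  c("H+" = 9, "OH-" = 3.5,
    "Na+" = 4, "K+" = 3, "Li+" = 6, "NH4+" = 2.5,
    "Mg+2" = 8, "Ca+2" = 6, "Fe+2" = 6,
    "Cl-" = 3, "F-" = 3.5, "Br-" = 3, "NO3-" = 3,
    "SO4-2" = 4, "HSO4-" = 4,
    "HCO3-" = 4, "CO3-2" = 4.5,
    "CH3COO-" = 4.5, "HCOO-" = 3.5,
    "CO2(aq)" = 0, "CH3COOH" = 0, "HCOOH" = 0, "HF" = 0, "NH3" = 0)
}

#' Acid-base couples recognised by the speciation routines
#'
#' Reference dissociation constants at 25 C with a van 't Hoff enthalpy
#' proxy for temperature correction. The first carbonate dissociation is a
#' special case handled by an empirical temperature polynomial (see
#' [pKa_at_temperature()]), so its `dH` is not used.
#'
#' @param overrides optional named list replacing individual entries, e.g.
#'   `list(acetate = list(pKa_25 = 4.76))`.
#' @return a list of couples; each couple is a list with fields `name`,
#'   `acid`, `base`, `z_acid`, `z_base`, `pKa_25`, `dH` (kJ/mol).
#' @export
acid_base_couples <- function(overrides = NULL) {
  couples <- list(
    sulfate  = list(name = "sulfate",  acid = "HSO4-",   base = "SO4-2",
                    z_acid = -1L, z_base = -2L, pKa_25 = 1.99,  dH = -22.4),
    acetate  = list(name = "acetate",  acid = "CH3COOH", base = "CH3COO-",
                    z_acid = 0L,  z_base = -1L, pKa_25 = 4.756, dH = -0.41),
    formate  = list(name = "formate",  acid = "HCOOH",   base = "HCOO-",
                    z_acid = 0L,  z_base = -1L, pKa_25 = 3.745, dH = -0.05),
    ammonium = list(name = "ammonium", acid = "NH4+",    base = "NH3",
                    z_acid = 1L,  z_base = 0L,  pKa_25 = 9.25,  dH = 51.9),
    fluoride = list(name = "fluoride", acid = "HF",      base = "F-",
                    z_acid = 0L,  z_base = -1L, pKa_25 = 3.17,  dH = -13.3),
    carbonate_1 = list(name = "carbonate_1", acid = "CO2(aq)", base = "HCO3-",
                       z_acid = 0L, z_base = -1L, pKa_25 = 6.35, dH = 9.15,
                       empirical = "carbonate_1"),
    carbonate_2 = list(name = "carbonate_2", acid = "HCO3-", base = "CO3-2",
                       z_acid = -1L, z_base = -2L, pKa_25 = 10.33, dH = 14.9,
                       empirical = "carbonate_2")
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), all(names(overrides) %in% names(couples)))
    for (nm in names(overrides)) {
      couples[[nm]] <- modifyList(couples[[nm]], overrides[[nm]])
    }
  }
  couples
}

# Empirical log10 K polynomials for the carbonate system (freshwater scale,
# fitted over 0-50+ C; T in kelvin).
.log10_K1_carbonate <- function(TK) {
  -356.3094 - 0.06091964 * TK + 21834.37 / TK +
    126.8339 * log10(TK) - 1684915 / TK^2
}
.log10_K2_carbonate <- function(TK) {
  -107.8871 - 0.03252849 * TK + 5151.79 / TK +
    38.92561 * log10(TK) - 563713.9 / TK^2
}

#' Dissociation constant of an acid-base couple at temperature
#'
#' Applies a van 't Hoff correction to the 25 C reference pKa using the
#' couple's enthalpy proxy `dH`. The two carbonate dissociations instead use
#' empirical temperature polynomials, which are considerably more accurate
#' for CO2(aq) over 0-50 C than a constant-enthalpy extrapolation.
#'
#' @param couple a couple from [acid_base_couples()].
#' @param temperature_C temperature in degrees Celsius, within 0-100.
#' @return pKa (dimensionless, -log10 of the dissociation constant).
#' @export
#' @examples
#' pKa_at_temperature(acid_base_couples()$carbonate_1, 35.4)
pKa_at_temperature <- function(couple, temperature_C) {
  stopifnot(is.list(couple), !is.null(couple$pKa_25))
  if (!is.numeric(temperature_C) || temperature_C < 0 || temperature_C > 100) {
    stop("temperature must be within 0-100 degrees C", call. = FALSE)
  }
  TK <- temperature_C + 273.15
  emp <- couple$empirical
  if (!is.null(emp) && emp == "carbonate_1") {
    return(-.log10_K1_carbonate(TK))
  }
  if (!is.null(emp) && emp == "carbonate_2") {
    return(-.log10_K2_carbonate(TK))
  }
  dH <- if (is.null(couple$dH)) 0 else couple$dH
  R <- 8.31446e-3 # kJ mol-1 K-1
  couple$pKa_25 - dH / (R * log(10)) * (1 / 298.15 - 1 / TK)
}

# Ion product of water, -log10 Kw (Harned & Owen form).
.pKw <- function(temperature_C) {
  TK <- temperature_C + 273.15
  4470.99 / TK - 6.0875 + 0.01706 * TK
}
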