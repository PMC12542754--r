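#' Ionic strength of a solution
#'
#' I = 1/2 * sum(m_i * z_i^2) over all charged species.
#'
#' @param molality numeric vector of species molalities (mol/kg).
#' @param charge integer vector of species charges, same length.
#' @return ionic strength in mol/kg.
#' @export
#' @examples
#' ionic_strength(c(0.01, 0.01), c(1, -1)) # 10 mM NaCl -> 0.01
ionic_strength <- function(molality, charge) {
  stopifnot(length(molality) == length(charge))
  0.5 * sum(molality * charge^2)
}

#' Single-ion activity coefficient by the extended Debye-Huckel equation
#'
#' log10(gamma) = -A z^2 sqrt(I) / (1 + B a sqrt(I)), with temperature
#' dependent solvent coefficients A and B from [debye_huckel_AB()] and a
#' per-ion size parameter a in Angstroms. Neutral species are assigned
#' gamma = 1. Valid to ionic strengths of about 0.1 mol/kg, well above
#' those of the dilute spring waters this package targets (I < 0.02).
#'
#' @param z integer charge of the species.
#' @param I ionic strength in mol/kg (>= 0).
#' @param temperature_C temperature in degrees Celsius.
#' @param ion_size effective ion diameter in Angstroms.
#' @return the dimensionless activity coefficient gamma.
#' @export
#' @examples
#' activity_coefficient(1, 0.005, 25, 4) # Na+ in a 5 mM 1:1 solution
activity_coefficient <- function(z, I, temperature_C = 25, ion_size = 4) {
  stopifnot(I >= 0)
  if (z == 0 || I == 0) return(1)
  AB <- debye_huckel_AB(temperature_C)
  sqI <- sqrt(I)
  10^(-AB[["A"]] * z^2 * sqI / (1 + AB[["B"]] * ion_size * sqI))
}

#' Fraction of an acid-base couple present as the protonated (acid) form
#'
#' The ideal-solution form is f = 1 / (1 + 10^(pH - pKa)). When activity
#' coefficients for the conjugate pair are supplied the mass-action ratio
#' base/acid = Ka * gamma_acid / (gamma_base * aH+) is used instead, i.e.
#' the 10-power term is multiplied by gamma_acid / gamma_base.
#'
#' @param pH the pH (-log10 hydrogen-ion activity).
#' @param pKa the couple's pKa at the relevant temperature.
#' @param gamma_acid,gamma_base activity coefficients of the acid and base
#'   species (default 1, the ideal case).
#' @return fraction in (0, 1) of the total present as the acid form.
#' @export
#' @examples
#' fraction_protonated(5.6, 4.756)  # acetic acid in mildly acidic medium
#' fraction_protonated(4.756, 4.756) # half-titration -> 0.5
fraction_protonated <- function(pH, pKa, gamma_acid = 1, gamma_base = 1) {
  ratio <- 10^(pH - pKa) * gamma_acid / gamma_base
  1 / (1 + ratio)
}

#' Construct a water composition
#'
#' Bundles the measured bulk chemistry of a spring-water sample: temperature,
#' optionally the field pH, and total (all species summed) concentrations of
#' the major components in mol/L. Molality and molarity are treated as equal,
#' appropriate for these dilute waters (ionic strength < 0.02 mol/kg).
#'
#' @param totals named numeric vector of component totals in mol/L. Known
#'   components: Na, K, Li, Mg, Ca, NH4, Fe2, Cl, F, Br, NO3, SO4, DIC,
#'   acetate, formate. Unknown names are rejected.
#' @param temperature_C sample temperature in degrees Celsius.
#' @param field_pH pH measured on site (optional).
#' @param sample_id optional identifier carried through to reports.
#' @param extras optional named list of additional measurements (isotope
#'   ratios, weight percents, ...) carried through untouched.
#' @return an object of class `water_composition`.
#' @export
water_composition <- function(totals, temperature_C, field_pH = NA_real_,
                              sample_id = NULL, extras = list()) {
  known <- c("Na", "K", "Li", "Mg", "Ca", "NH4", "Fe2",
             "Cl", "F", "Br", "NO3", "SO4", "DIC", "acetate", "formate")
  stopifnot(is.numeric(totals), !is.null(names(totals)))
  bad <- setdiff(names(totals), known)
  if (length(bad)) {
    stop("unknown components: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(totals < 0)) stop("component totals must be >= 0", call. = FALSE)
  if (temperature_C < 0 || temperature_C > 100) {
    stop("temperature must be within 0-100 degrees C", call. = FALSE)
  }
  full <- setNames(numeric(length(known)), known)
  full[names(totals)] <- totals
  structure(list(totals = full, temperature_C = temperature_C,
                 field_pH = field_pH, sample_id = sample_id, extras = extras),
            class = "water_composition")
}

#' @export
print.water_composition <- function(x, ...) {
  cat("Water composition", if (!is.null(x$sample_id)) paste0("'", x$sample_id, "'"),
      "\n")
  cat(sprintf("  temperature: %.1f C   field pH: %s\n", x$temperature_C,
              ifelse(is.na(x$field_pH), "not measured", format(x$field_pH))))
  nz <- x$totals[x$totals > 0]
  for (nm in names(nz)) {
    cat(sprintf("  %-8s %.4g mol/L\n", nm, nz[[nm]]))
  }
  invisible(x)
}

# Fixed-charge (non-protolytic) components and their single species.
.fixed_species <- data.frame(
  component = c("Na", "K", "Li", "Mg", "Ca", "Cl", "Br", "NO3"),
  species   = c("Na+", "K+", "Li+", "Mg+2", "Ca+2", "Cl-", "Br-", "NO3-"),
  charge    = c(1L, 1L, 1L, 2L, 2L, -1L, -1L, -1L),
  stringsAsFactors = FALSE
)
# Fe2 is kept as the free ferrous ion (no redox speciation).
.fixed_species <- rbind(.fixed_species,
                        data.frame(component = "Fe2", species = "Fe+2",
                                   charge = 2L, stringsAsFactors = FALSE))

# Map component -> the acid_base_couples() entries governing it.
.couple_map <- list(SO4 = "sulfate", acetate = "acetate", formate = "formate",
                    NH4 = "ammonium", F = "fluoride",
                    DIC = c("carbonate_1", "carbonate_2"))

.gamma_of <- function(species, I, temperature_C, sizes) {
  zmap <- c("H+" = 1, "OH-" = -1, "Na+" = 1, "K+" = 1, "Li+" = 1,
            "NH4+" = 1, "Mg+2" = 2, "Ca+2" = 2, "Fe+2" = 2, "Cl-" = -1,
            "F-" = -1, "Br-" = -1, "NO3-" = -1, "SO4-2" = -2, "HSO4-" = -1,
            "HCO3-" = -1, "CO3-2" = -2, "CH3COO-" = -1, "HCOO-" = -1,
            "CO2(aq)" = 0, "CH3COOH" = 0, "HCOOH" = 0, "HF" = 0, "NH3" = 0)
  vapply(species, function(s) {
    activity_coefficient(zmap[[s]], I, temperature_C,
                         ion_size = if (s %in% names(sizes)) sizes[[s]] else 4)
  }, numeric(1))
}

#' Speciate a water composition at a given pH
#'
#' Distributes each measured component total over its chemical species using
#' mass-action equilibria with temperature-corrected dissociation constants
#' ([pKa_at_temperature()]) and extended Debye-Huckel activity coefficients.
#' Because the activity coefficients depend on the ionic strength, which in
#' turn depends on the speciation, the two are iterated to a fixed point
#' (relative tolerance 1e-10 on ionic strength, at most 100 iterations).
#'
#' pH is interpreted as -log10 of the hydrogen-ion *activity*; the H+ and
#' OH- concentrations entering the ionic strength and charge balance are
#' activity / gamma.
#'
#' Deliberately outside scope: redox speciation, ion-pair complexes
#' (e.g. CaSO4(0)), mineral saturation, and dissolved sulfide (negligible
#' charge below pH 6).
#'
#' @param composition a [water_composition()].
#' @param pH the pH at which to speciate; defaults to the composition's
#'   field pH.
#' @param couples acid-base constants, from [acid_base_couples()].
#' @param max_iter,tol fixed-point iteration controls.
#' @return an object of class `speciation`: a species table (component,
#'   species, charge, molality, activity coefficient, fraction of its
#'   component), the ionic strength, the charge imbalance in percent of
#'   mean charge, and the pH and temperature used.
#' @export
#' @examples
#' w <- water_composition(c(DIC = 11e-3, SO4 = 1e-3, Na = 0.97e-3),
#'                        temperature_C = 35.4, field_pH = 3.76)
#' sp <- speciate(w, pH = 3.77)
#' subset(sp$species, component == "DIC")
speciate <- function(composition, pH = composition$field_pH,
                     couples = acid_base_couples(),
                     max_iter = 100, tol = 1e-10) {
  stopifnot(inherits(composition, "water_composition"))
  if (is.na(pH)) stop("pH must be supplied or present in the composition",
                      call. = FALSE)
  TC <- composition$temperature_C
  totals <- composition$totals
  sizes <- ion_size_params()
  aH <- 10^(-pH)
  aOH <- 10^(-(.pKw(TC) - pH))

  # Assemble the species skeleton once.
  tab <- .fixed_species
  tab$molality <- totals[tab$component]
  couple_rows <- function(comp) {
    cps <- .couple_map[[comp]]
    sp <- unique(unlist(lapply(couples[cps], function(cp) c(cp$acid, cp$base))))
    zs <- vapply(sp, function(s) {
      for (cp in couples[cps]) {
        if (cp$acid == s) return(cp$z_acid)
        if (cp$base == s) return(cp$z_base)
      }
    }, integer(1))
    data.frame(component = comp, species = sp, charge = zs,
               molality = 0, stringsAsFactors = FALSE, row.names = NULL)
  }
  for (comp in names(.couple_map)) tab <- rbind(tab, couple_rows(comp))
  tab <- rbind(tab, data.frame(component = c("water", "water"),
                               species = c("H+", "OH-"), charge = c(1L, -1L),
                               molality = c(aH, aOH), stringsAsFactors = FALSE))

  pKas <- lapply(couples, pKa_at_temperature, temperature_C = TC)

  distribute <- function(gam) {
    m <- setNames(tab$molality, tab$species)
    g <- function(s) gam[[s]]
    for (comp in names(.couple_map)) {
      tot <- totals[[comp]]
      cps <- .couple_map[[comp]]
      if (length(cps) == 1) {
        cp <- couples[[cps]]
        K <- 10^(-pKas[[cps]])
        ratio <- K * g(cp$acid) / (g(cp$base) * aH) # [base]/[acid]
        f_acid <- 1 / (1 + ratio)
        m[cp$acid] <- tot * f_acid
        m[cp$base] <- tot * (1 - f_acid)
      } else { # diprotic carbonate
        cp1 <- couples[[cps[1]]]; cp2 <- couples[[cps[2]]]
        K1 <- 10^(-pKas[[cps[1]]]); K2 <- 10^(-pKas[[cps[2]]])
        r1 <- K1 * g(cp1$acid) / (g(cp1$base) * aH) # [HCO3]/[CO2]
        r2 <- K2 * g(cp2$acid) / (g(cp2$base) * aH) # [CO3]/[HCO3]
        denom <- 1 + r1 + r1 * r2
        m[cp1$acid] <- tot / denom
        m[cp1$base] <- tot * r1 / denom
        m[cp2$base] <- tot * r1 * r2 / denom
      }
    }
    m["H+"] <- aH / g("H+")
    m["OH-"] <- aOH / g("OH-")
    m
  }

  gam <- setNames(rep(1, nrow(tab)), tab$species)
  I <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- distribute(gam)
    I_new <- ionic_strength(m, tab$charge[match(names(m), tab$species)])
    gam <- .gamma_of(tab$species, I_new, TC, sizes)
    if (abs(I_new - I) <= tol * max(I_new, .Machine$double.eps)) {
      converged <- TRUE
      I <- I_new
      break
    }
    I <- I_new
  }
  if (!converged) {
    stop(sprintf(
      "activity-coefficient iteration did not converge in %d iterations (last relative residual %.3e)",
      max_iter, abs(I_new - I) / max(I_new, .Machine$double.eps)), call. = FALSE)
  }
  m <- distribute(gam)
  tab$molality <- unname(m[tab$species])
  tab$gamma <- unname(gam[tab$species])
  comp_tot <- ifelse(tab$component == "water", NA_real_, totals[tab$component])
  tab$fraction <- ifelse(is.na(comp_tot) | comp_tot == 0, NA_real_,
                         tab$molality / comp_tot)

  res <- structure(list(species = tab, ionic_strength = I, pH = pH,
                        temperature_C = TC, iterations = it,
                        sample_id = composition$sample_id),
                   class = "speciation")
  res$charge_imbalance_pct <- charge_imbalance(res)
  res
}

#' @export
print.speciation <- function(x, digits = 4, ...) {
  cat("Aqueous speciation",
      if (!is.null(x$sample_id)) paste0("of '", x$sample_id, "'"), "\n")
  cat(sprintf("  pH %.3f at %.1f C; ionic strength %.4g mol/kg (%d iterations)\n",
              x$pH, x$temperature_C, x$ionic_strength, x$iterations))
  cat(sprintf("  charge imbalance: %+.2f%% of mean charge\n",
              x$charge_imbalance_pct))
  tab <- x$species[x$species$molality > 0, ]
  tab$molality <- signif(tab$molality, digits)
  tab$gamma <- signif(tab$gamma, digits)
  tab$fraction <- signif(tab$fraction, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Charge imbalance as percent of mean charge
#'
#' CI% = 100 * (sum of cation equivalents - sum of anion equivalents) /
#' (mean of the two sums). H+ and OH- are included via the speciation's pH
#' (concentration = activity / gamma). A perfectly analysed and speciated
#' water balances to zero.
#'
#' @param result a `speciation` object from [speciate()].
#' @return the signed charge imbalance in percent.
#' @export
charge_imbalance <- function(result) {
  stopifnot(inherits(result, "speciation"))
  tab <- result$species
  eq <- tab$molality * tab$charge
  cat_eq <- sum(eq[eq > 0])
  an_eq <- -sum(eq[eq < 0])
  if (cat_eq + an_eq == 0) {
    stop("composition carries no charge; imbalance undefined", call. = FALSE)
  }
  100 * (cat_eq - an_eq) / (0.5 * (cat_eq + an_eq))
}

#' Solve for the pH of zero charge imbalance
#'
#' Finds the pH at which the speciated composition balances exactly, by
#' bisection on pH in [0, 12] with re-speciation at every trial pH. The
#' charge imbalance is strictly decreasing in pH (H+ falls, deprotonated
#' anions rise), so a sign change in the bracket guarantees a unique root.
#' Convergence: |CI| < 1e-6 percent (with a machine-precision bracket
#' width as the safety stop), so re-speciating at the returned pH
#' balances to well below 1e-4 percent.
#'
#' A composition whose imbalance does not change sign over the bracket
#' cannot be balanced by pH alone (a missing or erroneous analysis); this
#' is reported as an error quoting the endpoint imbalances.
#'
#' @param composition a [water_composition()].
#' @param couples acid-base constants, from [acid_base_couples()].
#' @param lower,upper pH bracket (default 0-12).
#' @return the charge-balance pH (numeric scalar), with the converged
#'   `speciation` attached as attribute `"speciation"`.
#' @export
solve_ph_charge_balance <- function(composition, couples = acid_base_couples(),
                                    lower = 0, upper = 12) {
  ci <- function(p) charge_imbalance(speciate(composition, pH = p,
                                              couples = couples))
  lo <- lower; hi <- upper
  ci_lo <- ci(lo); ci_hi <- ci(hi)
  if (is.nan(ci_lo) || is.nan(ci_hi) || sign(ci_lo) == sign(ci_hi)) {
    stop(sprintf(
      "composition cannot be charge-balanced in pH [%g, %g]: imbalance %.3g%% to %.3g%%",
      lo, hi, ci_lo, ci_hi), call. = FALSE)
  }
  repeat {
    mid <- (lo + hi) / 2
    ci_mid <- ci(mid)
    if (abs(ci_mid) < 1e-6 || (hi - lo) / 2 < 1e-13) break
    if (sign(ci_mid) == sign(ci_lo)) {
      lo <- mid; ci_lo <- ci_mid
    } else {
      hi <- mid
    }
  }
  structure(mid, speciation = speciate(composition, pH = mid, couples = couples))
}
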