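#' Fraction of the headspace sampled for dissimilation counting
#'
#' Oxidation of labelled substrate to CO2 is assayed by acidifying the
#' microcosm, letting the CO2 partition into the headspace, and drawing a
#' syringe volume of headspace into a CO2 absorbent for counting. The
#' sealed-bottle volume is obtained gravimetrically (mass of the
#' water-filled bottle minus the empty bottle, over the water density);
#' the headspace is that volume minus the liquids/solids added, and the
#' sampled fraction is the syringe volume over the expanded headspace
#' (headspace + syringe), per the expansion-into-the-syringe geometry.
#'
#' @param bottle_full_mass,bottle_empty_mass bottle masses (g) filled with
#'   water and empty; alternatively supply `bottle_volume` directly.
#' @param water_density density of water at lab temperature (g/mL).
#' @param liquid_solid_volume total volume of liquids and solids in the
#'   assay vial (mL).
#' @param syringe_volume headspace volume drawn (mL).
#' @param bottle_volume sealed bottle volume (mL); overrides the masses.
#' @return the sampled fraction F_s in (0, 1].
#' @export
#' @examples
#' headspace_fraction(bottle_volume = 26.3, liquid_solid_volume = 11.3,
#'                    syringe_volume = 5) # 0.25
headspace_fraction <- function(bottle_full_mass = NULL, bottle_empty_mass = NULL,
                               water_density = 0.9982,
                               liquid_solid_volume, syringe_volume,
                               bottle_volume = NULL) {
  if (is.null(bottle_volume)) {
    if (is.null(bottle_full_mass) || is.null(bottle_empty_mass)) {
      stop("supply either bottle_volume or both bottle masses", call. = FALSE)
    }
    if (bottle_full_mass <= bottle_empty_mass) {
      stop("full bottle must outweigh empty bottle", call. = FALSE)
    }
    bottle_volume <- (bottle_full_mass - bottle_empty_mass) / water_density
  }
  headspace <- bottle_volume - liquid_solid_volume
  if (headspace <= 0) {
    stop("liquids/solids exceed the bottle volume: non-positive headspace",
         call. = FALSE)
  }
  syringe_volume / (headspace + syringe_volume)
}

#' Total substrate in a microcosm: native pool plus tracer spike
#'
#' The rate equation scales the fraction of label converted to the total
#' (labelled + native) substrate pool. The native amount is concentration
#' times the liquid volume that carries it (spring water plus slurry
#' liquid, assumed at spring concentration); the labelled amount follows
#' from the spike activity and its specific activity.
#'
#' @param native_concentration native substrate concentration (mol/L).
#' @param native_volume liquid volume carrying native substrate (mL).
#' @param activity_uCi spike activity added (microcuries).
#' @param specific_activity spike specific activity (mCi per mmol of
#'   compound).
#' @param native_concentration_sd standard error of the concentration
#'   (mol/L), propagated to the total.
#' @return named numeric vector: `mmol` (total substrate, mmol of
#'   molecules) and `sd` (its standard error).
#' @export
#' @examples
#' # trace acetate amendment: the spike carries 40% of the pool
#' total_substrate_mmol(0.83e-6, 11, 0.71, 110)
total_substrate_mmol <- function(native_concentration, native_volume,
                                 activity_uCi, specific_activity,
                                 native_concentration_sd = 0) {
  if (native_concentration < 0 || native_volume < 0 || activity_uCi < 0) {
    stop("concentrations, volumes and activities must be >= 0", call. = FALSE)
  }
  if (activity_uCi > 0 && specific_activity <= 0) {
    stop("specific activity must be positive", call. = FALSE)
  }
  native <- native_concentration * native_volume # mol/L * mL = mmol
  spike <- if (activity_uCi > 0) activity_uCi * 1e-3 / specific_activity else 0
  c(mmol = native + spike,
    sd = native_concentration_sd * native_volume)
}

#' Assemble the inputs of the substrate-conversion rate equation
#'
#' One object holding every symbol of the zero-order rate equation with its
#' uncertainty: treatment and killed-control mean DPM (with standard errors
#' of the mean over replicates), the total substrate pool, the molar mass of
#' carbon, carbons per substrate molecule, the isotopic discrimination
#' factor, the activity added, the dry mass and carbon content of the solid
#' phase, the incubation duration, and the fraction sampled.
#'
#' @param dpm_T mean DPM of the live treatment; `dpm_T_sd` its standard
#'   error (replicate variation, typically the dominant uncertainty).
#' @param dpm_K mean DPM of the killed control; `dpm_K_sd` its standard
#'   error.
#' @param mmol_substrate total substrate pool (mmol of molecules) and
#'   `mmol_substrate_sd` its error.
#' @param dpm_added radioactivity added per vial (DPM); `dpm_added_sd` its
#'   error.
#' @param gdw dry mass of mat material per vial (g); `gdw_sd` its error.
#' @param wt_pct_C carbon content of the solid phase (percent of dry
#'   mass); `wt_pct_C_sd` its error.
#' @param t_hours assay duration (hours).
#' @param F_s fraction of the converted label sampled for counting (1 for
#'   assimilation onto filters, typically 0.25 for headspace capture).
#' @param nu_C moles of carbon per mole of substrate (1 for bicarbonate,
#'   2 for acetate).
#' @param alpha isotopic discrimination factor correcting for slower
#'   uptake of 14C than 12C (default 1.05).
#' @param M_C molar mass of carbon (g/mol).
#' @return an object of class `rate_inputs`.
#' @export
rate_inputs <- function(dpm_T, dpm_K, mmol_substrate, dpm_added, gdw,
                        wt_pct_C, t_hours, F_s = 1, nu_C = 1, alpha = 1.05,
                        M_C = .MC,
                        dpm_T_sd = 0, dpm_K_sd = 0, mmol_substrate_sd = 0,
                        dpm_added_sd = 0, gdw_sd = 0, wt_pct_C_sd = 0) {
  if (t_hours <= 0) stop("assay duration must be positive", call. = FALSE)
  if (F_s <= 0 || F_s > 1) stop("F_s must lie in (0, 1]", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (!nu_C %in% c(1L, 2L)) stop("nu_C must be 1 or 2", call. = FALSE)
  for (nm in c("dpm_added", "gdw", "wt_pct_C", "mmol_substrate")) {
    if (get(nm) <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  sds <- c(dpm_T_sd, dpm_K_sd, mmol_substrate_sd, dpm_added_sd, gdw_sd,
           wt_pct_C_sd)
  if (any(sds < 0)) stop("uncertainties must be >= 0", call. = FALSE)
  structure(list(dpm_T = dpm_T, dpm_K = dpm_K,
                 mmol_substrate = mmol_substrate, dpm_added = dpm_added,
                 gdw = gdw, wt_pct_C = wt_pct_C, t_hours = t_hours,
                 F_s = F_s, nu_C = nu_C, alpha = alpha, M_C = M_C,
                 dpm_T_sd = dpm_T_sd, dpm_K_sd = dpm_K_sd,
                 mmol_substrate_sd = mmol_substrate_sd,
                 dpm_added_sd = dpm_added_sd, gdw_sd = gdw_sd,
                 wt_pct_C_sd = wt_pct_C_sd),
            class = "rate_inputs")
}

# Shared core of the assimilation and dissimilation estimators.
.rate_core <- function(x, conf_level = 0.95) {
  net <- x$dpm_T - x$dpm_K
  scale <- x$mmol_substrate * x$M_C * x$nu_C * x$alpha /
    (x$dpm_added * x$gdw * (x$wt_pct_C / 100) * x$t_hours * x$F_s)
  rate <- net * scale
  # First-order propagation: absolute term for the DPM difference, relative
  # terms for the multiplicative factors.
  var_net <- x$dpm_T_sd^2 + x$dpm_K_sd^2
  rel2 <- (x$mmol_substrate_sd / x$mmol_substrate)^2 +
    (x$dpm_added_sd / x$dpm_added)^2 +
    (x$gdw_sd / x$gdw)^2 +
    (x$wt_pct_C_sd / x$wt_pct_C)^2
  se <- sqrt(scale^2 * var_net + rate^2 * rel2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(rate = rate, se = se, net_dpm = net,
                 distinguishable_from_zero = net > 0 && abs(rate) > z * se,
                 conf_level = conf_level, inputs = x),
            class = "rate_result")
}

#' Carbon assimilation rate from a radiotracer microcosm assay
#'
#' The zero-order substrate conversion rate, in mg C per g of solid-phase
#' C per hour:
#'
#' rate = (DPM_T - DPM_K) * mmol * M_C * nu_C * alpha /
#'        (DPM_added * gdw * (wt%C / 100) * t * F_s)
#'
#' i.e. the fraction of added label converted (net of abiotic retention in
#' the killed control), scaled to the total substrate pool, corrected for
#' isotopic discrimination, and normalised to assay duration and to the
#' mat carbon as a biomass proxy. Uncertainty is first-order propagation
#' over all uncertain inputs; with replicate means, the replicate standard
#' error is typically the dominant term. A negative net DPM yields a
#' negative rate, reported as-is (not clipped) and flagged as not
#' distinguishable from zero.
#'
#' @param inputs a [rate_inputs()] object.
#' @param conf_level confidence level for the distinguishable-from-zero
#'   flag (default 0.95).
#' @return an object of class `rate_result` with elements `rate`, `se`,
#'   `net_dpm` and `distinguishable_from_zero`.
#' @export
assimilation_rate <- function(inputs, conf_level = 0.95) {
  stopifnot(inherits(inputs, "rate_inputs"))
  .rate_core(inputs, conf_level)
}

#' Carbon dissimilation rate from headspace CO2 capture
#'
#' Identical estimator to [assimilation_rate()]; only the provenance of the
#' DPM differs (label respired to CO2, captured from the acidified
#' headspace into an absorbent), so the fraction sampled F_s is that of the
#' headspace draw (typically 0.25) rather than 1.
#'
#' @inheritParams assimilation_rate
#' @return an object of class `rate_result`.
#' @export
dissimilation_rate <- function(inputs, conf_level = 0.95) {
  stopifnot(inherits(inputs, "rate_inputs"))
  .rate_core(inputs, conf_level)
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("rate: %.3g +/- %.2g mg C (g C)^-1 h^-1  [net %.4g DPM; %s]\n",
              x$rate, x$se, x$net_dpm,
              if (x$distinguishable_from_zero) {
                sprintf("distinguishable from zero at %g%%", 100 * x$conf_level)
              } else "not distinguishable from zero"))
  invisible(x)
}

#' Light-driven rate: light minus dark
#'
#' The rate attributable to phototrophy is the difference between the rate
#' in microcosms exposed to light and the rate in microcosms excluded from
#' light, with the two errors combined in quadrature. A dark rate exceeding
#' the light rate yields a negative value, reported as-is.
#'
#' @param light,dark `rate_result` objects for the light and dark
#'   treatments of the same substrate and assay mode.
#' @return named numeric vector: `rate` and `se`.
#' @export
light_driven_rate <- function(light, dark) {
  stopifnot(inherits(light, "rate_result"), inherits(dark, "rate_result"))
  for (nm in c("mmol_substrate", "nu_C", "F_s")) {
    if (!isTRUE(all.equal(light$inputs[[nm]], dark$inputs[[nm]]))) {
      stop("light and dark results come from different assays (", nm,
           " differs)", call. = FALSE)
    }
  }
  c(rate = light$rate - dark$rate, se = sqrt(light$se^2 + dark$se^2))
}

#' One-sided Welch test of a higher rate in the light
#'
#' Tests whether per-replicate rates in the light exceed those in the dark
#' using Welch's unequal-variance t-test, one-sided (light > dark). With
#' degenerate zero-variance groups the test statistic is undefined; the
#' p-value is then 0.5 for equal means and 0 or 1 according to the sign of
#' the difference.
#'
#' @param light_rates,dark_rates numeric vectors of per-replicate rates
#'   (at least 2 each).
#' @param alpha_level significance level (default 0.05).
#' @return list with `p`, `significant`, `estimate` (mean difference).
#' @export
compare_treatments <- function(light_rates, dark_rates, alpha_level = 0.05) {
  if (length(light_rates) < 2 || length(dark_rates) < 2) {
    stop("at least two replicates per treatment are required", call. = FALSE)
  }
  diff_means <- mean(light_rates) - mean(dark_rates)
  if (sd(light_rates) == 0 && sd(dark_rates) == 0) {
    p <- if (diff_means > 0) 0 else if (diff_means < 0) 1 else 0.5
  } else {
    p <- t.test(light_rates, dark_rates, alternative = "greater",
                var.equal = FALSE)$p.value
  }
  list(p = p, significant = p < alpha_level, estimate = diff_means)
}
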