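#' Configuration for a synthetic microcosm experiment
#'
#' Defines the ground truth and the noise model for a simulated radiotracer
#' incubation. Defaults reproduce the field design the package targets: a
#' triplicate light/dark/killed bicarbonate assay in an 11 mM DIC spring
#' water (10 mL water + 1 mL slurry + 0.2 mL spike + 0.1 mL amendment),
#' spiked to 5.3 uCi at 54 mCi/mmol, incubated 60 minutes, with ~20 mg dry
#' mat per vial at 9.11 wt% C.
#'
#' Noise model: observed gross counts are Poisson (physical for
#' scintillation counting) on (DPM * efficiency + background) * counting
#' time; vial-to-vial biological variability multiplies the true rate by a
#' mean-one log-normal factor with coefficient of variation `bio_cv`.
#' Killed controls retain `killed_adsorption_dpm` of label abiotically;
#' live vials retain it in addition to their biological signal, so the
#' killed subtraction is unbiased.
#'
#' @param substrate `"DIC"` or `"acetate"`.
#' @param true_light_rate,true_dark_rate ground-truth rates, mg C per g C
#'   per hour (>= 0).
#' @param n_replicates vials per treatment (>= 1).
#' @param activity_uCi,specific_activity,nu_C tracer spike: activity per
#'   vial (uCi), specific activity (mCi/mmol), carbons per molecule.
#' @param native_concentration native substrate concentration (mol/L);
#'   `native_concentration_sd` its analytical error.
#' @param water_volume,slurry_volume,spike_volume,amendment_volume per-vial
#'   liquid volumes (mL). Native substrate is carried by water + slurry.
#' @param gdw,gdw_sd dry mat mass per vial (g) and its uncertainty
#'   (slurry aliquot heterogeneity).
#' @param wt_pct_C,wt_pct_C_sd solid-phase carbon content (percent).
#' @param t_hours incubation duration (hours).
#' @param F_s fraction sampled (1 assimilation, 0.25 headspace capture).
#' @param assay_mode `"assimilation"` or `"dissimilation"`.
#' @param counting_time scintillation counting time (minutes).
#' @param counting_efficiency instrument efficiency at the vials' quench.
#' @param background_cpm instrument background (counts per minute).
#' @param killed_adsorption_dpm abiotic label retention (DPM).
#' @param bio_cv vial-to-vial biological coefficient of variation.
#' @param alpha isotopic discrimination factor.
#' @param dpm_added_sd relative error assigned to the spike activity.
#' @return an object of class `microcosm_config`.
#' @export
microcosm_config <- function(substrate = "DIC",
                             true_light_rate = 7, true_dark_rate = 0.5,
                             n_replicates = 3,
                             activity_uCi = 5.3, specific_activity = 54,
                             nu_C = 1L,
                             native_concentration = 11e-3,
                             native_concentration_sd = 0.05 * native_concentration,
                             water_volume = 10, slurry_volume = 1,
                             spike_volume = 0.2, amendment_volume = 0.1,
                             gdw = 0.020, gdw_sd = 0.002,
                             wt_pct_C = 9.11, wt_pct_C_sd = 0.07,
                             t_hours = 1, F_s = 1,
                             assay_mode = c("assimilation", "dissimilation"),
                             counting_time = 10, counting_efficiency = 0.90,
                             background_cpm = 30, killed_adsorption_dpm = 500,
                             bio_cv = 0.15, alpha = 1.05,
                             dpm_added_sd = 0.01) {
  assay_mode <- match.arg(assay_mode)
  substrate <- match.arg(substrate, c("DIC", "acetate"))
  stopifnot(true_light_rate >= 0, true_dark_rate >= 0, n_replicates >= 1,
            activity_uCi > 0, specific_activity > 0, nu_C %in% c(1L, 2L),
            counting_efficiency > 0, counting_efficiency <= 1,
            bio_cv >= 0, F_s > 0, F_s <= 1)
  structure(as.list(environment()), class = "microcosm_config")
}

# Expected biomass-associated (or headspace-captured) DPM for a true rate,
# i.e. the rate equation inverted for net DPM.
.expected_net_dpm <- function(rate, config) {
  mmol <- total_substrate_mmol(config$native_concentration,
                               config$water_volume + config$slurry_volume,
                               config$activity_uCi,
                               config$specific_activity)[["mmol"]]
  dpm_added <- config$activity_uCi * .DPM_PER_UCI
  rate * config$gdw * (config$wt_pct_C / 100) * config$t_hours * config$F_s *
    dpm_added / (mmol * .MC * config$nu_C * config$alpha)
}

#' Simulate a complete microcosm experiment
#'
#' Generates one vial table (light, dark, killed treatments) from a
#' [microcosm_config()]: per-vial expected DPM from the inverted rate
#' equation, log-normal biological variability, abiotic adsorption, and
#' Poisson counting noise, reported as CPM exactly as a scintillation
#' counter would. Deterministic given the seed.
#'
#' @param config a [microcosm_config()].
#' @param seed integer seed fixing the whole random stream.
#' @return a data.frame with one row per vial: vial_id, substrate,
#'   treatment, assay_mode, volumes, cpm, and the true per-vial rate
#'   (ground truth, for validation only).
#' @export
#' @examples
#' vials <- simulate_microcosms(microcosm_config(), seed = 1)
#' aggregate(cpm ~ treatment, vials, mean)
simulate_microcosms <- function(config, seed = 1) {
  stopifnot(inherits(config, "microcosm_config"))
  set.seed(seed)
  treatments <- c("light", "dark", "killed")
  true_rates <- c(light = config$true_light_rate,
                  dark = config$true_dark_rate, killed = 0)
  dpm_added <- config$activity_uCi * .DPM_PER_UCI
  rows <- list()
  for (tr in treatments) {
    for (i in seq_len(config$n_replicates)) {
      r <- true_rates[[tr]]
      if (r > 0 && config$bio_cv > 0) {
        sdlog <- sqrt(log(1 + config$bio_cv^2))
        r <- r * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      net <- .expected_net_dpm(r, config)
      if (net > dpm_added) {
        stop("configuration implies converting more label than was added; ",
             "lower the true rate or raise the substrate pool", call. = FALSE)
      }
      dpm <- net + config$killed_adsorption_dpm
      lambda <- (dpm * config$counting_efficiency + config$background_cpm) *
        config$counting_time
      cpm <- rpois(1, lambda) / config$counting_time
      rows[[length(rows) + 1]] <- data.frame(
        vial_id = sprintf("%s_%s_%d", config$substrate, tr, i),
        substrate = config$substrate, treatment = tr,
        assay_mode = config$assay_mode,
        water_volume = config$water_volume,
        slurry_volume = config$slurry_volume,
        spike_volume = config$spike_volume,
        amendment_volume = config$amendment_volume +
          if (tr == "killed") 0.1 else 0,
        cpm = cpm, true_rate = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Recover rates from a simulated (or real) vial table
#'
#' Runs the full estimation pipeline — CPM to DPM conversion, replicate
#' aggregation, killed-control subtraction, the rate equation with error
#' propagation, the light-minus-dark contrast and its Welch test — using
#' the nuisance parameters of the configuration, and returns the fitted
#' object. This is the parameter-recovery closure of the simulator: with
#' `vials` from [simulate_microcosms()] the recovered light-driven rate
#' estimates the configured truth.
#'
#' @param vials a vial data.frame as produced by [simulate_microcosms()]
#'   (or read from disk with the same columns).
#' @param config the [microcosm_config()] supplying nuisance parameters
#'   (spike, volumes, biomass, counting efficiency, background).
#' @return a [fit_rates()] object of class `rate_fit`.
#' @export
recover_rates <- function(vials, config) {
  stopifnot(inherits(config, "microcosm_config"))
  fit_rates(vials,
            spike = list(activity_uCi = config$activity_uCi,
                         specific_activity = config$specific_activity,
                         nu_C = config$nu_C),
            biomass = list(gdw = config$gdw, gdw_sd = config$gdw_sd,
                           wt_pct_C = config$wt_pct_C,
                           wt_pct_C_sd = config$wt_pct_C_sd),
            native_concentration = config$native_concentration,
            native_concentration_sd = config$native_concentration_sd,
            t_hours = config$t_hours, F_s = config$F_s,
            efficiency = config$counting_efficiency,
            background_cpm = config$background_cpm,
            alpha = config$alpha,
            dpm_added_sd = config$dpm_added_sd)
}

#' Perturb a water composition log-normally
#'
#' Multiplies every component total by an independent mean-one log-normal
#' factor — a fixture generator for property tests of the speciation and
#' charge-balance routines.
#'
#' @param template a [water_composition()].
#' @param perturbation coefficient of variation of the multipliers
#'   (0 returns the template unchanged).
#' @param seed integer seed.
#' @return a perturbed `water_composition`.
#' @export
simulate_water <- function(template, perturbation = 0.1, seed = 1) {
  stopifnot(inherits(template, "water_composition"), perturbation >= 0)
  if (perturbation == 0) return(template)
  set.seed(seed)
  sdlog <- sqrt(log(1 + perturbation^2))
  mult <- rlnorm(length(template$totals), meanlog = -sdlog^2 / 2,
                 sdlog = sdlog)
  out <- template
  out$totals <- template$totals * mult
  out
}
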