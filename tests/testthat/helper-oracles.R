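# Independent oracles used across the suite.

# Brute-force evaluation of the zero-order rate equation, written as a
# log-domain product so it shares no code path with .rate_core().
oracle_rate <- function(dpm_T, dpm_K, mmol_substrate, dpm_added, gdw,
                        wt_pct_C, t_hours, F_s = 1, nu_C = 1, alpha = 1.05,
                        M_C = 12.011) {
  net <- dpm_T - dpm_K
  mag <- exp(log(abs(net)) + log(mmol_substrate) + log(M_C) + log(nu_C) +
               log(alpha) -
               log(dpm_added) - log(gdw) - log(wt_pct_C / 100) -
               log(t_hours) - log(F_s))
  sign(net) * mag
}

# Monte-Carlo standard deviation of the rate under normally perturbed
# inputs; the reference for the first-order propagated error.
oracle_mc_rate_sd <- function(inp, n = 1e5, seed = 42) {
  set.seed(seed)
  draws <- oracle_rate(
    rnorm(n, inp$dpm_T, inp$dpm_T_sd), rnorm(n, inp$dpm_K, inp$dpm_K_sd),
    rnorm(n, inp$mmol_substrate, inp$mmol_substrate_sd),
    rnorm(n, inp$dpm_added, inp$dpm_added_sd),
    rnorm(n, inp$gdw, inp$gdw_sd), rnorm(n, inp$wt_pct_C, inp$wt_pct_C_sd),
    inp$t_hours, inp$F_s, inp$nu_C, inp$alpha)
  sd(draws)
}

# Brute-force solution of the coupled mass-action / ionic-strength system
# for a toy water: bisection on each couple's mass-action residual (never
# the closed-form fraction) nested in a uniroot on the ionic strength.
oracle_toy_speciation <- function(totals, pH, temperature_C,
                                  couples = acid_base_couples()) {
  sizes <- ion_size_params()
  aH <- 10^(-pH)
  pKw <- 4470.99 / (temperature_C + 273.15) - 6.0875 +
    0.01706 * (temperature_C + 273.15)
  aOH <- 10^(-(pKw - pH))
  couple_for <- list(SO4 = "sulfate", acetate = "acetate",
                     formate = "formate", NH4 = "ammonium", F = "fluoride")
  fixed_z <- c(Na = 1, K = 1, Cl = -1)

  species_at <- function(I) {
    g <- function(sp, z) activity_coefficient(z, I, temperature_C,
                                              sizes[sp])
    m <- c("H+" = aH / g("H+", 1), "OH-" = aOH / g("OH-", -1))
    z <- c(1, -1)
    for (comp in names(totals)) {
      tot <- totals[[comp]]
      if (comp %in% names(fixed_z)) {
        m <- c(m, tot); z <- c(z, fixed_z[[comp]])
      } else {
        cp <- couples[[couple_for[[comp]]]]
        K <- 10^(-pKa_at_temperature(cp, temperature_C))
        ga <- g(cp$acid, cp$z_acid); gb <- g(cp$base, cp$z_base)
        # mass-action residual in the acid concentration
        resid <- function(acid) K * ga * acid - aH * gb * (tot - acid)
        acid <- uniroot(resid, c(0, tot), tol = 1e-16)$root
        m <- c(m, acid, tot - acid)
        z <- c(z, cp$z_acid, cp$z_base)
      }
    }
    list(m = m, z = z)
  }
  I_res <- function(I) {
    sp <- species_at(I)
    ionic_strength(sp$m, sp$z) - I
  }
  I <- uniroot(I_res, c(0, 1), tol = 1e-14)$root
  c(species_at(I), I = I)
}

# A small quench curve shared by several tests.
toy_quench_curve <- function() {
  quench_curve(indicator = c(20, 60, 100, 140),
               efficiency = c(0.95, 0.90, 0.82, 0.70))
}
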