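#' Fit carbon transformation rates to a microcosm vial table
#'
#' The central estimator of the package. Takes one vial table from a
#' radiotracer incubation experiment (triplicate light/dark/killed bottles,
#' one row per vial with measured CPM or DPM), converts counts to
#' disintegrations via a quench curve or a fixed efficiency, aggregates
#' replicates, subtracts the killed control, applies the zero-order rate
#' equation with first-order uncertainty propagation, and contrasts light
#' against dark with a one-sided Welch test.
#'
#' @param vials data.frame with columns `vial_id`, `substrate`,
#'   `treatment` (light/dark/killed), `assay_mode`
#'   (assimilation/dissimilation), `water_volume`, `slurry_volume`,
#'   `spike_volume`, optionally `amendment_volume`, and either `dpm` or
#'   `cpm` (plus `quench_indicator` when a quench curve is used).
#' @param spike list with `activity_uCi`, `specific_activity`
#'   (mCi/mmol) and `nu_C` (carbons per molecule).
#' @param biomass list with `gdw`, `gdw_sd` (g dry mass per vial) and
#'   `wt_pct_C`, `wt_pct_C_sd` (percent).
#' @param native_concentration native substrate concentration in the
#'   spring water (mol/L); `native_concentration_sd` its error.
#' @param t_hours incubation duration (hours).
#' @param F_s fraction sampled; `NULL` (default) resolves to 1 for
#'   assimilation and 0.25 for dissimilation assays.
#' @param quench optional [quench_curve()]; vials then need a
#'   `quench_indicator` column.
#' @param efficiency fixed counting efficiency used when no curve is
#'   supplied.
#' @param background_cpm instrument background (counts per minute).
#' @param alpha isotopic discrimination factor (default 1.05).
#' @param dpm_added_sd relative error on the activity added.
#' @param sig_level significance level of the light-vs-dark test.
#' @param conf_level confidence level for flags and intervals.
#' @return an object of class `rate_fit` with components `treatments`
#'   (per-treatment rates and errors), `contrasts` (light minus dark with
#'   Welch p-value), `per_vial` (per-replicate DPM and rates) and
#'   `warnings`. Supports `print()`, `summary()`, `coef()` and
#'   `confint()`.
#' @export
#' @examples
#' cfg <- microcosm_config()
#' fit <- fit_rates(simulate_microcosms(cfg, seed = 7),
#'                  spike = list(activity_uCi = 5.3, specific_activity = 54,
#'                               nu_C = 1),
#'                  biomass = list(gdw = 0.020, gdw_sd = 0.002,
#'                                 wt_pct_C = 9.11, wt_pct_C_sd = 0.07),
#'                  native_concentration = 11e-3, t_hours = 1,
#'                  efficiency = 0.9, background_cpm = 30)
#' fit
fit_rates <- function(vials, spike, biomass, native_concentration,
                      native_concentration_sd = 0, t_hours, F_s = NULL,
                      quench = NULL, efficiency = 1, background_cpm = 0,
                      alpha = 1.05, dpm_added_sd = 0,
                      sig_level = 0.05, conf_level = 0.95) {
  vv <- validate_vial_table(vials)
  vials <- vv$table
  warns <- vv$warnings

  if (!"dpm" %in% names(vials)) {
    qi <- if (!is.null(quench)) vials$quench_indicator else NULL
    vials$dpm <- dpm_from_cpm(vials$cpm, background_cpm, curve = quench,
                              quench_indicator = qi, efficiency = efficiency)
  }

  dpm_added <- spike$activity_uCi * .DPM_PER_UCI
  groups <- unique(vials[c("substrate", "assay_mode")])
  treatments <- list(); contrasts <- list(); per_vial <- list()

  for (g in seq_len(nrow(groups))) {
    sub <- groups$substrate[g]; mode <- groups$assay_mode[g]
    gv <- vials[vials$substrate == sub & vials$assay_mode == mode, ]
    fs <- if (!is.null(F_s)) F_s else if (mode == "dissimilation") 0.25 else 1
    native_volume <- mean(gv$water_volume + gv$slurry_volume)
    pool <- total_substrate_mmol(native_concentration, native_volume,
                                 spike$activity_uCi, spike$specific_activity,
                                 native_concentration_sd)

    kv <- gv[gv$treatment == "killed", ]
    if (nrow(kv) == 0) {
      warns <- c(warns, sprintf(
        "no killed controls for %s %s: abiotic retention taken as 0 DPM",
        sub, mode))
      dpm_K <- 0; dpm_K_sd <- 0; n_K <- 0L
    } else {
      dpm_K <- mean(kv$dpm)
      dpm_K_sd <- if (nrow(kv) > 1) sd(kv$dpm) / sqrt(nrow(kv)) else 0
      n_K <- nrow(kv)
    }

    rate_of <- function(dpm_T, dpm_T_sd) {
      inp <- rate_inputs(
        dpm_T = dpm_T, dpm_K = dpm_K,
        mmol_substrate = pool[["mmol"]],
        mmol_substrate_sd = pool[["sd"]],
        dpm_added = dpm_added, dpm_added_sd = dpm_added_sd * dpm_added,
        gdw = biomass$gdw, gdw_sd = biomass$gdw_sd %||% 0,
        wt_pct_C = biomass$wt_pct_C, wt_pct_C_sd = biomass$wt_pct_C_sd %||% 0,
        t_hours = t_hours, F_s = fs, nu_C = spike$nu_C, alpha = alpha)
      if (mode == "dissimilation") dissimilation_rate(inp, conf_level)
      else assimilation_rate(inp, conf_level)
    }

    live <- setdiff(unique(gv$treatment), "killed")
    res_by_tr <- list()
    for (tr in live) {
      tv <- gv[gv$treatment == tr, ]
      dpm_T <- mean(tv$dpm)
      dpm_T_sd <- if (nrow(tv) > 1) sd(tv$dpm) / sqrt(nrow(tv)) else 0
      rr <- rate_of(dpm_T, dpm_T_sd)
      res_by_tr[[tr]] <- rr
      treatments[[length(treatments) + 1]] <- data.frame(
        substrate = sub, assay_mode = mode, treatment = tr, n = nrow(tv),
        dpm_mean = dpm_T, dpm_se = dpm_T_sd, net_dpm = rr$net_dpm,
        rate = rr$rate, se = rr$se,
        distinguishable = rr$distinguishable_from_zero,
        stringsAsFactors = FALSE)
      # Per-replicate rates (against the mean killed control) for the
      # treatment contrast test.
      vial_rates <- vapply(tv$dpm, function(d) rate_of(d, 0)$rate, numeric(1))
      per_vial[[length(per_vial) + 1]] <- data.frame(
        vial_id = tv$vial_id, substrate = sub, assay_mode = mode,
        treatment = tr, dpm = tv$dpm, rate = vial_rates,
        stringsAsFactors = FALSE)
    }

    if (all(c("light", "dark") %in% names(res_by_tr))) {
      ld <- light_driven_rate(res_by_tr$light, res_by_tr$dark)
      pv <- do.call(rbind, per_vial)
      lr <- pv$rate[pv$substrate == sub & pv$assay_mode == mode &
                      pv$treatment == "light"]
      dr <- pv$rate[pv$substrate == sub & pv$assay_mode == mode &
                      pv$treatment == "dark"]
      test <- if (length(lr) >= 2 && length(dr) >= 2) {
        compare_treatments(lr, dr, sig_level)
      } else {
        warns <- c(warns, sprintf(
          "fewer than 2 replicates for %s %s: significance unavailable",
          sub, mode))
        list(p = NA_real_, significant = NA)
      }
      contrasts[[length(contrasts) + 1]] <- data.frame(
        substrate = sub, assay_mode = mode, contrast = "light - dark",
        rate = ld[["rate"]], se = ld[["se"]], p_value = test$p,
        significant = test$significant, stringsAsFactors = FALSE)
    }
  }

  for (w in warns) warning(w, call. = FALSE)
  structure(list(
    treatments = do.call(rbind, treatments),
    contrasts = if (length(contrasts)) do.call(rbind, contrasts) else NULL,
    per_vial = do.call(rbind, per_vial),
    warnings = warns, sig_level = sig_level, conf_level = conf_level,
    t_hours = t_hours, call = match.call()),
    class = "rate_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rate_fit <- function(x, digits = 3, ...) {
  cat("Radiotracer carbon transformation rates (mg C (g C)^-1 h^-1)\n\n")
  tr <- x$treatments
  tr$rate <- signif(tr$rate, digits); tr$se <- signif(tr$se, 2)
  tr$dpm_mean <- signif(tr$dpm_mean, 4); tr$dpm_se <- signif(tr$dpm_se, 3)
  tr$net_dpm <- signif(tr$net_dpm, 4)
  print(tr, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nLight-driven (light minus dark) rates:\n")
    ct <- x$contrasts
    ct$rate <- signif(ct$rate, digits); ct$se <- signif(ct$se, 2)
    ct$p_value <- signif(ct$p_value, 3)
    print(ct, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.rate_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rate_fit")
}

#' @export
print.summary.rate_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\n%d vials; incubation %g h; Welch one-sided test at alpha = %g\n",
              nrow(x$fit$per_vial) +
                sum(x$fit$treatments$n[x$fit$treatments$treatment == "killed"],
                    na.rm = TRUE),
              x$fit$t_hours, x$fit$sig_level))
  if (length(x$fit$warnings)) {
    cat("Warnings:\n")
    for (w in x$fit$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  tr <- object$treatments
  out <- setNames(tr$rate, paste(tr$substrate, tr$assay_mode, tr$treatment,
                                 sep = "."))
  if (!is.null(object$contrasts)) {
    ct <- object$contrasts
    out <- c(out, setNames(ct$rate, paste(ct$substrate, ct$assay_mode,
                                          "light_driven", sep = ".")))
  }
  out
}

#' @export
confint.rate_fit <- function(object, parm, level = 0.95, ...) {
  tr <- object$treatments
  est <- coef(object)
  ses <- tr$se
  if (!is.null(object$contrasts)) ses <- c(ses, object$contrasts$se)
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(est - z * ses, est + z * ses)
  dimnames(out) <- list(names(est),
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}
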