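# Analyte vocabulary: maps table analyte names to speciation components.
.analyte_components <- c(
  sodium = "Na", potassium = "K", lithium = "Li", magnesium = "Mg",
  calcium = "Ca", ammonium = "NH4", ferrous_iron = "Fe2",
  chloride = "Cl", fluoride = "F", bromide = "Br", nitrate = "NO3",
  sulfate = "SO4", DIC = "DIC", acetate = "acetate", formate = "formate")

# Concentration unit -> mol/L multiplier. Non-concentration units pass
# through unchanged.
.unit_to_molar <- c("M" = 1, "mol/L" = 1, "mM" = 1e-3, "mmol/L" = 1e-3,
                    "uM" = 1e-6, "umol/L" = 1e-6, "nM" = 1e-9)
.passthrough_units <- c("degC", "pH", "permil", "wt_pct", "uS_cm", "")

.normalise_value <- function(value, unit, analyte) {
  if (unit %in% names(.unit_to_molar)) {
    value * .unit_to_molar[[unit]]
  } else if (unit %in% .passthrough_units || is.na(unit)) {
    value
  } else {
    stop(sprintf("malformed unit '%s' for analyte '%s'", unit, analyte),
         call. = FALSE)
  }
}

#' Read a long-format water chemistry table
#'
#' Expects a CSV with columns `sample_id`, `analyte`, `value`, `unit` and
#' optionally `error`. Concentration units (M, mM, uM, nM and the mol/L
#' spellings) are normalised to mol/L; `degC`, `pH`, `permil`, `wt_pct`
#' and `uS_cm` rows pass through unchanged; any other unit is an error
#' naming the offending row. Analytes that map to speciation components
#' populate the composition's totals; everything else (sulfide, silica,
#' isotope ratios, weight percents, ...) is carried in `extras` with its
#' error.
#'
#' @param path path to the CSV file.
#' @return a named list of [water_composition()] objects, one per sample.
#' @export
read_water_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "analyte", "value", "unit")
  if (!all(need %in% names(tab))) {
    stop("water table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"error" %in% names(tab)) tab$error <- NA_real_
  out <- list()
  for (sid in unique(tab$sample_id)) {
    st <- tab[tab$sample_id == sid, ]
    totals <- numeric(0)
    extras <- list()
    temperature <- NA_real_; field_pH <- NA_real_
    for (i in seq_len(nrow(st))) {
      an <- st$analyte[i]
      val <- .normalise_value(st$value[i], st$unit[i], an)
      if (an == "temperature") {
        temperature <- val
      } else if (an == "pH") {
        field_pH <- val
      } else if (an %in% names(.analyte_components)) {
        if (val < 0) stop("negative concentration for ", an, call. = FALSE)
        totals[.analyte_components[[an]]] <- val
      } else {
        err <- st$error[i]
        if (!is.na(err) && st$unit[i] %in% names(.unit_to_molar)) {
          err <- err * .unit_to_molar[[st$unit[i]]]
        }
        extras[[an]] <- c(value = val, error = err)
      }
    }
    if (is.na(temperature)) {
      stop("sample '", sid, "' has no temperature row", call. = FALSE)
    }
    out[[sid]] <- water_composition(totals, temperature_C = temperature,
                                    field_pH = field_pH, sample_id = sid,
                                    extras = extras)
  }
  out
}

#' Write water compositions back to a long-format CSV
#'
#' Inverse of [read_water_table()]: component totals are written in mol/L
#' and extras with their original values, so a write/read cycle preserves
#' every number exactly (values are never rounded on write).
#'
#' @param samples a named list of [water_composition()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_water_table <- function(samples, path) {
  rows <- list()
  add <- function(sid, analyte, value, unit, error = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sid, analyte = analyte, value = value, unit = unit,
      error = error, stringsAsFactors = FALSE)
  }
  comp_names <- setNames(names(.analyte_components), .analyte_components)
  for (w in samples) {
    sid <- w$sample_id %||% "sample"
    add(sid, "temperature", w$temperature_C, "degC")
    if (!is.na(w$field_pH)) add(sid, "pH", w$field_pH, "pH")
    for (comp in names(w$totals)) {
      if (w$totals[[comp]] > 0) {
        add(sid, comp_names[[comp]], w$totals[[comp]], "mol/L")
      }
    }
    for (an in names(w$extras)) {
      x <- w$extras[[an]]
      add(sid, an, x[["value"]], "", x[["error"]])
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a wide (column-per-sample) water chemistry table
#'
#' Mirrors the field-notebook layout: one `analyte` column, one `unit`
#' column, then one column per sample. Cells may carry "value +/- error".
#'
#' @param path path to the CSV file.
#' @return a named list of [water_composition()] objects.
#' @export
read_water_wide <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("analyte", "unit") %in% names(tab))) {
    stop("wide water table must have 'analyte' and 'unit' columns",
         call. = FALSE)
  }
  samples <- setdiff(names(tab), c("analyte", "unit"))
  long <- list()
  for (sid in samples) {
    for (i in seq_len(nrow(tab))) {
      cell <- as.character(tab[[sid]][i])
      if (is.na(cell) || cell == "" || cell == "NA") next
      parts <- strsplit(cell, "\\s*(±|\\+/-)\\s*")[[1]]
      long[[length(long) + 1]] <- data.frame(
        sample_id = sid, analyte = tab$analyte[i],
        value = as.numeric(parts[1]), unit = tab$unit[i],
        error = if (length(parts) > 1) as.numeric(parts[2]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(do.call(rbind, long), tmp, row.names = FALSE)
  read_water_table(tmp)
}

#' Bundled spring-water field measurements
#'
#' Physicochemical field data for two warm acidic springs in the
#' Yellowstone region that host mats of the acidophilic purple nonsulfur
#' bacterium *Rhodopila globiformis* (one sampled in two different years),
#' plus the minimally thermal creek receiving one spring's outflow: major
#' ions, dissolved gases, carbon pools, and stable isotope ratios of water,
#' DIC, DOC and mat biomass.
#'
#' @return a named list of [water_composition()] objects with elements
#'   `Amphitheater_2017`, `Amphitheater_2014`, `Lemonade_Creek` and
#'   `Hot_Spring_Basin`.
#' @export
#' @examples
#' w <- spring_waters()$Amphitheater_2017
#' w$temperature_C
spring_waters <- function() {
  read_water_table(system.file("extdata", "spring_water.csv",
                               package = "springcarb", mustWork = TRUE))
}

#' Validate a microcosm vial table
#'
#' Enforces the structural invariants of a vial table before fitting:
#' required columns present, unique vial ids, non-negative volumes and
#' counts, one substrate per vial row, recognised treatment and assay-mode
#' labels. Missing killed controls are a warning (rates are then computed
#' against zero abiotic retention, flagged); structural violations are
#' errors.
#'
#' @param vials a data.frame of vials.
#' @return list with `table` (the validated table) and `warnings`
#'   (character vector).
#' @export
validate_vial_table <- function(vials) {
  need <- c("vial_id", "substrate", "treatment", "assay_mode")
  miss <- setdiff(need, names(vials))
  if (length(miss)) {
    stop("vial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!any(c("cpm", "dpm") %in% names(vials))) {
    stop("vial table needs a 'cpm' or 'dpm' column", call. = FALSE)
  }
  if (anyDuplicated(vials$vial_id)) {
    stop("duplicate vial_id: ",
         paste(unique(vials$vial_id[duplicated(vials$vial_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(vials$treatment %in% c("light", "dark", "killed"))) {
    stop("treatment must be one of light, dark, killed", call. = FALSE)
  }
  if (!all(vials$assay_mode %in% c("assimilation", "dissimilation"))) {
    stop("assay_mode must be assimilation or dissimilation", call. = FALSE)
  }
  volcols <- intersect(c("water_volume", "slurry_volume", "spike_volume",
                         "amendment_volume"), names(vials))
  for (vc in volcols) {
    if (any(vials[[vc]] < 0, na.rm = TRUE)) {
      stop("negative ", vc, call. = FALSE)
    }
  }
  for (cc in intersect(c("cpm", "dpm"), names(vials))) {
    if (any(vials[[cc]] < 0, na.rm = TRUE)) stop("negative ", cc, call. = FALSE)
  }
  warnings <- character(0)
  for (g in split(vials, paste(vials$substrate, vials$assay_mode))) {
    if (!"killed" %in% g$treatment) {
      warnings <- c(warnings, sprintf(
        "no killed controls for %s %s", g$substrate[1], g$assay_mode[1]))
    }
  }
  list(table = vials, warnings = warnings)
}

#' Write fitted rates to CSV
#'
#' @param fit a [fit_rates()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(fit, path) {
  stopifnot(inherits(fit, "rate_fit"))
  tr <- fit$treatments
  tr$p_value <- NA_real_; tr$significant <- NA
  out <- tr
  if (!is.null(fit$contrasts)) {
    ct <- fit$contrasts
    ct2 <- data.frame(substrate = ct$substrate, assay_mode = ct$assay_mode,
                      treatment = ct$contrast, n = NA_integer_,
                      dpm_mean = NA_real_, dpm_se = NA_real_,
                      net_dpm = NA_real_, rate = ct$rate, se = ct$se,
                      distinguishable = NA, p_value = ct$p_value,
                      significant = ct$significant, stringsAsFactors = FALSE)
    out <- rbind(out, ct2)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.fmt_pm <- function(value, error, digits = 1) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), value,
          signif(error, 2))
}

#' Render a derived-quantities report for a water sample
#'
#' Produces the text block of derived quantities a field campaign reports
#' alongside its raw chemistry: biomass-DIC carbon isotope fractionation,
#' molar C:N of the mat, the charge imbalance of the analysis at field pH,
#' the charge-balance (calculated) pH, and the speciation of the DIC at
#' that pH. Optionally followed by a rates block from a [fit_rates()]
#' object. Regeneration is byte-identical for identical inputs.
#'
#' @param water a [water_composition()], e.g. from [spring_waters()].
#' @param fit optional `rate_fit` whose rates are appended.
#' @param pH pH at which DIC speciation is reported; defaults to the
#'   charge-balance pH.
#' @return the report as a character vector of lines, invisibly; the
#'   report is also printed.
#' @export
render_report <- function(water, fit = NULL, pH = NULL) {
  stopifnot(inherits(water, "water_composition"))
  lines <- c(sprintf("Derived quantities for '%s'",
                     water$sample_id %||% "sample"),
             strrep("-", 48))
  ex <- water$extras
  has <- function(nm) nm %in% names(ex)
  if (has("d13C_mat") && has("d13C_DIC")) {
    dd <- capital_delta_13C(ex$d13C_mat[["value"]], ex$d13C_DIC[["value"]],
                            ex$d13C_mat[["error"]], ex$d13C_DIC[["error"]])
    lines <- c(lines, sprintf("Delta13C (mat - DIC), permil: %s",
                              .fmt_pm(dd[["estimate"]], dd[["se"]])))
  }
  if (has("mat_C_wt_pct") && has("mat_N_wt_pct")) {
    cn <- cn_molar_ratio(ex$mat_C_wt_pct[["value"]], ex$mat_N_wt_pct[["value"]],
                         ex$mat_C_wt_pct[["error"]], ex$mat_N_wt_pct[["error"]])
    lines <- c(lines, sprintf("Mat C:N, mol:mol: %s",
                              .fmt_pm(cn[["estimate"]], cn[["se"]], 2)))
  }
  if (!is.na(water$field_pH)) {
    ci <- charge_imbalance(speciate(water, pH = water$field_pH))
    lines <- c(lines, sprintf("Charge imbalance at field pH %.2f: %+.2f%%",
                              water$field_pH, ci))
  }
  ph_cb <- tryCatch(as.numeric(solve_ph_charge_balance(water)),
                    error = function(e) NA_real_)
  if (!is.na(ph_cb)) {
    lines <- c(lines, sprintf("Charge-balance pH: %.2f", ph_cb))
  } else {
    lines <- c(lines, "Charge-balance pH: not attainable for this analysis")
  }
  rep_ph <- pH %||% ph_cb
  if (!is.na(rep_ph) && water$totals[["DIC"]] > 0) {
    sp <- speciate(water, pH = rep_ph)
    f <- sp$species$fraction[sp$species$species == "CO2(aq)"]
    lines <- c(lines, sprintf("CO2(aq) fraction of DIC at pH %.2f: %.1f%%",
                              rep_ph, 100 * f))
  }
  if (!is.null(fit)) {
    lines <- c(lines, "", "Rates, mg C (g C)^-1 h^-1:")
    tr <- fit$treatments
    for (i in seq_len(nrow(tr))) {
      lines <- c(lines, sprintf("  %s %s (%s): %s", tr$substrate[i],
                                tr$assay_mode[i], tr$treatment[i],
                                .fmt_pm(tr$rate[i], tr$se[i])))
    }
    if (!is.null(fit$contrasts)) {
      ct <- fit$contrasts
      for (i in seq_len(nrow(ct))) {
        lines <- c(lines, sprintf(
          "  %s %s (light-driven): %s  [one-sided Welch p = %.3g]",
          ct$substrate[i], ct$assay_mode[i], .fmt_pm(ct$rate[i], ct$se[i]),
          ct$p_value[i]))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
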