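#' Construct a quench calibration curve
#'
#' Liquid scintillation counting efficiency degrades with sample quench
#' (colour/chemical interference); instruments report a quench indicator
#' per vial, and a calibration series of known-activity standards relates
#' the indicator to counting efficiency. The curve is interpolated
#' piecewise-linearly between calibration points and clipped to the
#' calibrated range outside it.
#'
#' @param indicator numeric vector of quench-indicator values, strictly
#'   increasing.
#' @param efficiency counting efficiencies in (0, 1], same length,
#'   at least two points.
#' @return an object of class `quench_curve`.
#' @export
#' @examples
#' qc <- quench_curve(c(50, 100, 150), c(0.95, 0.90, 0.80))
#' counting_efficiency(qc, 125)
quench_curve <- function(indicator, efficiency) {
  if (length(indicator) < 2) {
    stop("a quench curve needs at least two calibration points", call. = FALSE)
  }
  stopifnot(length(indicator) == length(efficiency))
  if (any(diff(indicator) <= 0)) {
    stop("quench-indicator values must be strictly increasing", call. = FALSE)
  }
  if (any(efficiency <= 0) || any(efficiency > 1)) {
    stop("counting efficiencies must lie in (0, 1]", call. = FALSE)
  }
  structure(list(indicator = as.numeric(indicator),
                 efficiency = as.numeric(efficiency)),
            class = "quench_curve")
}

#' @export
print.quench_curve <- function(x, ...) {
  cat("Quench curve with", length(x$indicator), "calibration points\n")
  print(data.frame(indicator = x$indicator, efficiency = x$efficiency),
        row.names = FALSE)
  invisible(x)
}

#' Counting efficiency at a quench-indicator value
#'
#' @param curve a [quench_curve()].
#' @param quench_indicator quench-indicator value(s); values outside the
#'   calibrated range are clipped to its ends.
#' @return counting efficiency (fraction).
#' @export
counting_efficiency <- function(curve, quench_indicator) {
  stopifnot(inherits(curve, "quench_curve"))
  approx(curve$indicator, curve$efficiency, xout = quench_indicator,
         rule = 2)$y
}

#' Convert counts per minute to disintegrations per minute
#'
#' DPM = max(CPM - background, 0) / efficiency, with the efficiency taken
#' from a quench curve at the vial's quench indicator, or supplied directly.
#'
#' @param cpm measured counts per minute (>= 0), vectorised.
#' @param background_cpm instrument background in counts per minute.
#' @param curve optional [quench_curve()].
#' @param quench_indicator per-vial quench indicator (required with `curve`).
#' @param efficiency counting efficiency used when no curve is given
#'   (default 1, i.e. CPM taken as DPM after background subtraction).
#' @return disintegrations per minute.
#' @export
#' @examples
#' dpm_from_cpm(930, 30, efficiency = 0.9) # 1000 DPM
dpm_from_cpm <- function(cpm, background_cpm = 0, curve = NULL,
                         quench_indicator = NULL, efficiency = 1) {
  if (any(cpm < 0)) stop("cpm must be >= 0", call. = FALSE)
  if (!is.null(curve)) {
    if (is.null(quench_indicator)) {
      stop("quench_indicator is required when a quench curve is supplied",
           call. = FALSE)
    }
    efficiency <- counting_efficiency(curve, quench_indicator)
  }
  if (any(efficiency <= 0)) {
    stop("counting efficiency must be positive", call. = FALSE)
  }
  pmax(cpm - background_cpm, 0) / efficiency
}
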