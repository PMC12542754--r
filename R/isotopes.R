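#' Carbon isotope fractionation between biomass and DIC
#'
#' The capital-delta difference Delta13C = delta13C(biomass) -
#' delta13C(DIC), in per mil vs VPDB, with the two measurement errors
#' combined in quadrature. This simple delta difference (rather than the
#' exact epsilon = 1000*(alpha - 1)) is the convention used when reporting
#' biomass-DIC offsets at these magnitudes; values near -22 per mil are
#' diagnostic of carbon fixation via the Calvin cycle.
#'
#' @param d13C_mat delta13C of the mat biomass (per mil vs VPDB).
#' @param d13C_DIC delta13C of the dissolved inorganic carbon.
#' @param d13C_mat_sd,d13C_DIC_sd measurement errors (per mil).
#' @return named numeric vector: `estimate` (per mil) and `se`.
#' @export
#' @examples
#' capital_delta_13C(-26.4, -3.5, 0.1, 0.2)
capital_delta_13C <- function(d13C_mat, d13C_DIC,
                              d13C_mat_sd = 0, d13C_DIC_sd = 0) {
  if (missing(d13C_mat) || missing(d13C_DIC) ||
      is.na(d13C_mat) || is.na(d13C_DIC)) {
    stop("both delta13C values are required", call. = FALSE)
  }
  if (d13C_mat_sd < 0 || d13C_DIC_sd < 0) {
    stop("errors must be >= 0", call. = FALSE)
  }
  c(estimate = d13C_mat - d13C_DIC,
    se = sqrt(d13C_mat_sd^2 + d13C_DIC_sd^2))
}

#' Molar C:N ratio from weight percents
#'
#' (wt%C / 12.011) / (wt%N / 14.007), with relative errors combined in
#' quadrature.
#'
#' @param wt_pct_C,wt_pct_N carbon and nitrogen content (percent of dry
#'   mass).
#' @param wt_pct_C_sd,wt_pct_N_sd their errors.
#' @return named numeric vector: `estimate` (mol:mol) and `se`.
#' @export
#' @examples
#' cn_molar_ratio(9.11, 1.315, 0.07, 0.007)
cn_molar_ratio <- function(wt_pct_C, wt_pct_N,
                           wt_pct_C_sd = 0, wt_pct_N_sd = 0) {
  if (wt_pct_N <= 0) stop("wt%N must be positive", call. = FALSE)
  if (wt_pct_C < 0 || wt_pct_C > 100 || wt_pct_N > 100) {
    stop("weight percents must lie in [0, 100]", call. = FALSE)
  }
  est <- (wt_pct_C / .MC) / (wt_pct_N / .MN)
  rel <- sqrt((wt_pct_C_sd / wt_pct_C)^2 + (wt_pct_N_sd / wt_pct_N)^2)
  c(estimate = est, se = est * rel)
}
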