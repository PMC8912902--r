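#' Amplification efficiency from a standard dilution series
#'
#' Fits the standard curve Cq ~ log10(relative concentration) by ordinary
#' least squares and converts the slope to the per-cycle amplification
#' efficiency E = 10^(-1/slope). A perfect assay doubles the template every
#' cycle (E = 2, slope -3.3219). The primer pair passes QC when
#' 1.9 <= E <= 2.1 (95--105% efficiency) and the determination coefficient
#' R^2 is at least 0.99.
#'
#' When the most dilute point falls outside the instrument's detection range
#' it can be excluded by the caller via `use`; the fit itself never drops
#' points silently.
#'
#' @param dilution_factors Relative template concentrations, e.g.
#'   `c(1, 0.1, 0.01, 0.001)` for a 10-fold series. Strictly positive.
#' @param cq_means Mean Cq at each dilution point.
#' @param use Optional logical mask selecting the points entering the fit.
#' @return An object of class `efficiency_result`: list with `slope` (Cq per
#'   log10 concentration), `e_value`, `r_squared`, `pass_qc`, `n_points`.
#'   A zero or positive slope yields `e_value = NA` and `pass_qc = FALSE`.
#' @examples
#' eff <- efficiency_from_standard_curve(c(1, 0.1, 0.01),
#'                                       c(20.0000, 23.3219, 26.6439))
#' eff$e_value    # ~2.000
#' eff$pass_qc
#' @export
efficiency_from_standard_curve <- function(dilution_factors, cq_means,
                                           use = NULL) {
  if (!is.null(use)) {
    dilution_factors <- dilution_factors[use]
    cq_means <- cq_means[use]
  }
  if (length(dilution_factors) != length(cq_means))
    stop_refstab("dilution_factors and cq_means must have equal length",
                 class = "refstab_validation_error")
  if (length(cq_means) < 3L)
    stop_refstab("a standard curve needs at least 3 dilution points",
                 class = "refstab_validation_error")
  if (any(dilution_factors <= 0))
    stop_refstab("dilution factors must be strictly positive",
                 class = "refstab_validation_error")
  lc <- log10(dilution_factors)
  if (stats::var(lc) == 0)
    stop_refstab("all dilution points have the same concentration",
                 class = "refstab_degenerate_design_error")
  fit <- stats::lm(cq_means ~ lc)
  slope <- unname(stats::coef(fit)[2L])
  # a perfect dilution series is routine; avoid summary.lm's perfect-fit warning
  tss <- sum((cq_means - mean(cq_means))^2)
  r2 <- if (tss == 0) NaN else 1 - sum(stats::residuals(fit)^2) / tss
  e_value <- if (is.finite(slope) && slope < 0) 10^(-1 / slope) else NA_real_
  pass <- !is.na(e_value) && e_value >= 1.9 && e_value <= 2.1 && r2 >= 0.99
  structure(list(slope = slope, e_value = e_value, r_squared = r2,
                 pass_qc = pass, n_points = length(cq_means)),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Standard curve (%d points): slope %.4f, E = %s, R^2 = %.4f -> %s\n",
              x$n_points, x$slope,
              if (is.na(x$e_value)) "undefined" else sprintf("%.3f", x$e_value),
              x$r_squared, if (x$pass_qc) "PASS" else "FAIL"))
  invisible(x)
}
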