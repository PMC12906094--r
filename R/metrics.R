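#' Select diodes in the high-gradient dose band
#'
#' Indices of diodes whose planned dose lies between 60\% and 85\%
#' (inclusive) of the maximum planned diode dose; these sit in the field's
#' dose gradient and show the largest dose change under motion.
#'
#' @param planned_dose vector of planned doses at the diode positions, Gy.
#' @param lower,upper band bounds as fractions of the maximum.
#' @return Integer index vector (possibly empty, with a warning when the
#'   input is all zero).
#' @export
select_diodes <- function(planned_dose, lower = 0.60, upper = 0.85) {
  if (length(planned_dose) == 0) stop("empty diode dose vector")
  mx <- max(planned_dose)
  if (mx <= 0) {
    warning("all planned diode doses are zero; empty selection")
    return(integer(0))
  }
  which(planned_dose >= lower * mx & planned_dose <= upper * mx)
}

#' Deviation statistics between measured and reference doses
#'
#' The standard deviation (sample, n-1 denominator) and the mean absolute
#' value of the differences \code{measured - reference} over the selected
#' indices. A constant offset is invisible to the standard deviation but
#' not to the mean absolute difference, which is why both are reported.
#'
#' @param measured,reference equal-length dose vectors, Gy.
#' @param selection indices to evaluate (at least 2).
#' @return \code{c(sigma = ..., mad = ...)} in Gy.
#' @export
deviation_stats <- function(measured, reference,
                            selection = seq_along(measured)) {
  if (length(measured) != length(reference))
    stop("`measured` and `reference` differ in length")
  if (length(selection) < 2)
    stop("need at least two selected diodes for a standard deviation")
  d <- measured[selection] - reference[selection]
  c(sigma = stats::sd(d), mad = mean(abs(d)))
}

#' Deviation series versus delivered MU
#'
#' At each evaluation point the statistics are computed on the cumulative
#' doses up to that point: sigma/MAD of measured-minus-planned
#' (\code{sigma_p}, \code{mad_p}) and measured-minus-calculated
#' (\code{sigma_c}, \code{mad_c}).
#'
#' @param measured,planned,calculated matrices of cumulative diode doses,
#'   one row per evaluation point, one column per diode, aligned on
#'   \code{mu}.
#' @param mu delivered MU at each evaluation point (non-decreasing).
#' @param selection diode indices (e.g. from \code{\link{select_diodes}}).
#' @return A data frame \code{mu, sigma_p, mad_p, sigma_c, mad_c} (Gy).
#' @export
deviation_series <- function(measured, planned, calculated, mu,
                             selection) {
  dims <- list(dim(measured), dim(planned), dim(calculated))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])) ||
      nrow(measured) != length(mu))
    stop("misaligned deviation series inputs")
  if (any(diff(mu) < -1e-9)) stop("`mu` must be non-decreasing")
  out <- lapply(seq_along(mu), function(i) {
    p <- deviation_stats(measured[i, ], planned[i, ], selection)
    cc <- deviation_stats(measured[i, ], calculated[i, ], selection)
    data.frame(mu = mu[i], sigma_p = p[["sigma"]], mad_p = p[["mad"]],
               sigma_c = cc[["sigma"]], mad_c = cc[["mad"]])
  })
  do.call(rbind, out)
}

#' Dose-volume coverage V(threshold)
#'
#' Percentage of the masked volume receiving at least
#' \code{fraction * prescription_gy}; with the default fraction this is
#' the V95\% coverage metric.
#'
#' @param dose a \code{dose_grid} (or \code{voxel_grid}) of dose, Gy.
#' @param mask binary \code{voxel_grid} on the same grid (non-empty).
#' @param prescription_gy prescription dose, Gy.
#' @param fraction threshold as a fraction of the prescription.
#' @return Coverage in percent, \code{[0, 100]}.
#' @export
v_threshold <- function(dose, mask, prescription_gy, fraction = 0.95) {
  stop_if_grid_mismatch(dose, mask)
  inmask <- mask$values != 0
  if (!any(inmask)) stop("empty mask")
  100 * mean(dose$values[inmask] >= fraction * prescription_gy)
}

#' Gamma analysis of two dose distributions
#'
#' Global-normalization gamma index: for each reference point above the
#' low-dose threshold,
#' \deqn{\gamma(r) = \min_{r'} \sqrt{\frac{|r - r'|^2}{\delta_{dta}^2} +
#'   \frac{(D_e(r') - D_r(r))^2}{(\delta_{dd} \cdot \max D_r)^2}}}
#' searched exhaustively over a ball of radius \code{3 * dta_mm} on a
#' sub-voxel lattice with trilinear interpolation of the evaluated
#' distribution. A point passes when \eqn{\gamma \le 1}.
#'
#' @param reference,evaluated dose distributions on the same grid: either
#'   \code{dose_grid}s/\code{voxel_grid}s, or plain matrices (2D planes,
#'   e.g. film) with \code{spacing_mm} giving the pixel spacing.
#' @param dd_percent dose-difference criterion, percent of the maximum
#'   reference dose (global normalization).
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param low_threshold evaluate only where the reference dose is at least
#'   this fraction of its maximum.
#' @param step_mm search lattice step (default \code{dta_mm / 10}).
#' @param spacing_mm pixel spacing when matrices are supplied.
#' @return An object of class \code{gamma_result}: \code{gamma} (map with
#'   NA below threshold), \code{pass_rate} (percent of evaluated points
#'   with gamma <= 1), \code{n_evaluated}, and the criteria.
#' @export
gamma_index <- function(reference, evaluated, dd_percent = 2, dta_mm = 2,
                        low_threshold = 0.05, step_mm = dta_mm / 10,
                        spacing_mm = NULL) {
  if (is.matrix(reference) && !inherits(reference, "voxel_grid")) {
    if (is.null(spacing_mm)) stop("`spacing_mm` required for matrix input")
    sp <- rep_len(spacing_mm, 2)
    reference <- voxel_grid(array(reference, c(dim(reference), 1)),
                            spacing = c(sp, 1))
    evaluated <- voxel_grid(array(evaluated, c(dim(evaluated), 1)),
                            spacing = c(sp, 1))
  }
  stop_if_grid_mismatch(reference, evaluated)
  mx <- max(reference$values)
  cutoff <- low_threshold * mx
  if (mx <= 0 || all(reference$values < cutoff))
    stop("all reference points below the low-dose threshold")
  g <- cpp_gamma(as.numeric(reference$values), as.numeric(evaluated$values),
                 dim(reference$values), reference$spacing, reference$origin,
                 dd_percent / 100 * mx, dta_mm, cutoff, step_mm)
  g <- array(g, dim(reference$values))
  n_eval <- sum(!is.na(g))
  # a point passes at gamma <= 1; a small numerical slack keeps exact
  # boundary cases (dose deviation equal to the criterion) passing
  structure(list(gamma = grid_like(reference, g),
                 pass_rate = 100 * sum(g <= 1 + 1e-9, na.rm = TRUE) / n_eval,
                 n_evaluated = n_eval, max_gamma = max(g, na.rm = TRUE),
                 dd_percent = dd_percent, dta_mm = dta_mm,
                 low_threshold = low_threshold),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (global, %g%% threshold): pass rate %.1f%% over %d points\n",
              x$dd_percent, x$dta_mm, 100 * x$low_threshold, x$pass_rate,
              x$n_evaluated))
  invisible(x)
}

#' Express a dose value as a percentage of the fraction dose
#'
#' @param value_gy dose value, Gy.
#' @param fraction_dose_gy fraction dose, Gy (> 0).
#' @return Percentage, reported at one decimal.
#' @export
gy_to_percent <- function(value_gy, fraction_dose_gy) {
  if (fraction_dose_gy <= 0) stop("`fraction_dose_gy` must be > 0")
  round(100 * value_gy / fraction_dose_gy, 1)
}
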