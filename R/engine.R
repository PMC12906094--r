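#' Analytic primary-beam model
#'
#' A toy dose calculator standing in for a clinical Monte Carlo engine:
#' divergent primary beam with exponential attenuation along the
#' radiological depth, Gaussian aperture penumbra, inverse-square falloff,
#' and an optional Monte-Carlo-like multiplicative noise term with a fixed
#' relative standard deviation per calculation.
#'
#' @param sad_mm source-axis distance, mm.
#' @param mu_water_per_cm linear attenuation coefficient of water, 1/cm.
#' @param penumbra_sigma_mm Gaussian penumbra width at isocenter, mm.
#' @param output_gy_per_mu dose per MU at zero radiological depth on the
#'   central axis at the isocenter distance, Gy/MU.
#' @param noise_rel_sd relative standard deviation of the per-voxel noise
#'   applied to each dose calculation, in \code{[0, 0.2]} (0 disables it).
#' @return An object of class \code{beam_model}.
#' @export
beam_model <- function(sad_mm = 1435, mu_water_per_cm = 0.05,
                       penumbra_sigma_mm = 5, output_gy_per_mu = 0.016,
                       noise_rel_sd = 0.05) {
  if (sad_mm <= 0 || mu_water_per_cm <= 0 || penumbra_sigma_mm <= 0 ||
      output_gy_per_mu <= 0)
    stop("beam model parameters must be positive")
  if (noise_rel_sd < 0 || noise_rel_sd > 0.2)
    stop("`noise_rel_sd` must be in [0, 0.2]")
  structure(list(sad_mm = sad_mm, mu_water_per_cm = mu_water_per_cm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 output_gy_per_mu = output_gy_per_mu,
                 noise_rel_sd = noise_rel_sd),
            class = "beam_model")
}

# beam geometry for a gantry angle: unit vectors of the machine frame.
# Gantry rotates about the CC (z) axis; at 0 deg the source sits on +y.
beam_frame <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  list(e_src = c(sin(g), cos(g), 0),      # isocenter -> source
       e_u = c(cos(g), -sin(g), 0),       # leaf-travel axis in the BEV
       e_v = c(0, 0, 1))                  # leaf-stacking axis (CC)
}

as_aperture <- function(x) {
  if (inherits(x, "aperture")) return(x)
  if (!is.null(x$aperture)) return(x$aperture)
  aperture(x$gantry_deg, x$jaws_cm, x$mlc_cm,
           if (is.null(x$leaf_width_cm)) 0.7 else x$leaf_width_cm)
}

phantom_density <- function(x) {
  if (inherits(x, "voxel_grid")) return(x)
  if (!is.null(x$density)) return(x$density)
  stop("cannot find a density grid in `phantom`")
}

#' Radiological depth along a source-target ray
#'
#' Line integral of density along the ray via exact voxel traversal,
#' returned as cm of water-equivalent path (g/cm^2).
#'
#' @param grid a density \code{voxel_grid} (g/cm^3).
#' @param source,target world coordinates, mm.
#' @return Water-equivalent depth in cm (0 for a zero-length ray or a ray
#'   missing the grid).
#' @export
radiological_depth <- function(grid, source, target) {
  grid <- phantom_density(grid)
  tgt <- matrix(as.numeric(target), ncol = 3)
  as.numeric(cpp_raydepth(as.numeric(grid$values), dim(grid$values),
                          grid$spacing, grid$origin,
                          as.numeric(source), tgt))
}

#' Aperture fluence map at the isocenter plane
#'
#' Intersection of the jaw rectangle with the MLC opening, convolved with
#' the Gaussian penumbra. With \code{penumbra_sigma_mm = 0} the indicator
#' of the open area is returned.
#'
#' @param ap an \code{\link{aperture}} (or a segment carrying one).
#' @param u_mm,v_mm beam's-eye-view coordinates (mm at isocenter) at which
#'   to evaluate; the map is returned on their outer grid.
#' @param penumbra_sigma_mm Gaussian penumbra sigma, mm.
#' @return A \code{length(u_mm)} by \code{length(v_mm)} matrix with values
#'   in \code{[0, 1]}.
#' @export
aperture_fluence <- function(ap, u_mm, v_mm, penumbra_sigma_mm = 5) {
  ap <- as_aperture(ap)
  uu <- rep(u_mm, times = length(v_mm))
  vv <- rep(v_mm, each = length(u_mm))
  f <- cpp_fluence(uu, vv, ap$mlc_cm * 10, leaf_v_edges_cm(ap) * 10,
                   ap$jaws_cm * 10, penumbra_sigma_mm)
  matrix(f, nrow = length(u_mm))
}

# core: primary dose at arbitrary world points, optionally with a
# precomputed radiological depth vector for those points. Points whose
# beam's-eye-view projection falls more than `margin_sigma` penumbra sigmas
# outside the aperture bounding box carry a fluence below ~1e-7 of an open
# field and are set to zero without tracing rays.
dose_core <- function(dens, ap, delta_mu, model, points,
                      beam_offset = c(0, 0, 0), depth_cm = NULL,
                      margin_sigma = 5) {
  frame <- beam_frame(ap$gantry_deg)
  src <- beam_offset + model$sad_mm * frame$e_src
  q1 <- points[, 1] - src[1]
  q2 <- points[, 2] - src[2]
  q3 <- points[, 3] - src[3]
  # distance along the beam axis (source -> isocenter direction)
  a <- -(q1 * frame$e_src[1] + q2 * frame$e_src[2] + q3 * frame$e_src[3])
  r2 <- q1^2 + q2^2 + q3^2
  scale <- ifelse(a > 1e-6, model$sad_mm / a, NA_real_)
  u <- (q1 * frame$e_u[1] + q2 * frame$e_u[2]) * scale
  v <- q3 * scale
  mgn <- margin_sigma * model$penumbra_sigma_mm
  lve <- leaf_v_edges_cm(ap) * 10
  ubox <- c(max(min(ap$mlc_cm[1, ]), ap$jaws_cm[1]),
            min(max(ap$mlc_cm[2, ]), ap$jaws_cm[2])) * c(10, 10)
  vbox <- c(max(lve[1], ap$jaws_cm[3] * 10),
            min(lve[length(lve)], ap$jaws_cm[4] * 10))
  ok <- !is.na(u) & u >= ubox[1] - mgn & u <= ubox[2] + mgn &
    v >= vbox[1] - mgn & v <= vbox[2] + mgn
  d <- numeric(nrow(points))
  if (!any(ok)) return(d)
  fl <- cpp_fluence(u[ok], v[ok], ap$mlc_cm * 10, lve, ap$jaws_cm * 10,
                    model$penumbra_sigma_mm)
  dep <- if (is.null(depth_cm)) {
    cpp_raydepth(as.numeric(dens$values), dim(dens$values),
                 dens$spacing, dens$origin, src,
                 points[ok, , drop = FALSE])
  } else depth_cm[ok]
  d[ok] <- delta_mu * model$output_gy_per_mu * fl *
    (model$sad_mm^2 / r2[ok]) * exp(-model$mu_water_per_cm * dep)
  d
}

#' Dose of one beam segment at arbitrary points
#'
#' Evaluates the analytic beam model exactly at the given world points
#' (no grid resampling); used for virtual diode and film readouts.
#'
#' @param phantom a density \code{voxel_grid} or a phantom object with a
#'   \code{$density} grid.
#' @param ap an \code{\link{aperture}} or beam segment.
#' @param delta_mu monitor units delivered through the segment.
#' @param model a \code{\link{beam_model}}.
#' @param points n-by-3 matrix of world coordinates (mm).
#' @param beam_offset rigid offset of the whole beam geometry (source and
#'   isocenter), mm; computing the dose with the beam shifted by \code{-t}
#'   is exactly equivalent to translating the anatomy by \code{t} and
#'   resampling the dose back.
#' @param noise_seed integer seed for the multiplicative noise term; NULL
#'   draws from the current RNG stream (noise is skipped entirely when the
#'   model's \code{noise_rel_sd} is 0).
#' @return Numeric vector of dose values, Gy.
#' @export
dose_at_points <- function(phantom, ap, delta_mu, model, points,
                           beam_offset = c(0, 0, 0), noise_seed = NULL) {
  if (delta_mu < 0) stop("`delta_mu` must be >= 0")
  dens <- phantom_density(phantom)
  ap <- as_aperture(ap)
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dose_core(dens, ap, delta_mu, model, points, beam_offset)
  apply_engine_noise(d, model, noise_seed)
}

apply_engine_noise <- function(d, model, noise_seed) {
  if (model$noise_rel_sd <= 0) return(d)
  eps <- if (is.null(noise_seed)) {
    stats::rnorm(length(d), 0, model$noise_rel_sd)
  } else {
    with_local_seed(noise_seed, stats::rnorm(length(d), 0, model$noise_rel_sd))
  }
  pmax(d * (1 + eps), 0)
}

with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

#' Radiological depth of every voxel for one beam direction
#'
#' Precomputes the per-voxel water-equivalent depth for a gantry angle so
#' that segments sharing a beam direction and anatomy can reuse it.
#'
#' @inheritParams dose_at_points
#' @param gantry_deg gantry angle, degrees.
#' @return Numeric vector of depths (cm), one per voxel in array order.
#' @export
segment_depth <- function(phantom, gantry_deg, model,
                          beam_offset = c(0, 0, 0)) {
  dens <- phantom_density(phantom)
  src <- beam_offset + model$sad_mm * beam_frame(gantry_deg)$e_src
  cpp_raydepth(as.numeric(dens$values), dim(dens$values), dens$spacing,
               dens$origin, src, grid_points(dens))
}

#' Dose distribution of one beam segment
#'
#' Computes \eqn{D(v) = \Delta MU \cdot output \cdot fluence(u, v)
#' \cdot (SAD/r)^2 \cdot e^{-\mu d_{rad}(v)}}{D = dMU * output * fluence *
#' (SAD/r)^2 * exp(-mu * depth)} on the phantom grid, optionally followed
#' by the per-voxel multiplicative noise term.
#'
#' @inheritParams dose_at_points
#' @param depth_cm optional precomputed per-voxel radiological depth from
#'   \code{\link{segment_depth}} (must match the same anatomy and beam).
#' @return A \code{dose_grid} on the phantom grid.
#' @export
compute_segment_dose <- function(phantom, ap, delta_mu, model,
                                 noise_seed = NULL, beam_offset = c(0, 0, 0),
                                 depth_cm = NULL) {
  if (delta_mu < 0) stop("`delta_mu` must be >= 0")
  dens <- phantom_density(phantom)
  ap <- as_aperture(ap)
  d <- dose_core(dens, ap, delta_mu, model, grid_points(dens),
                 beam_offset, depth_cm)
  d <- apply_engine_noise(d, model, noise_seed)
  dose_grid(array(d, dim = dim(dens$values)), dens$spacing, dens$origin)
}

#' Calibrate the engine output to a plan prescription
#'
#' Plan commissioning for the toy engine: scales the output factor
#' (Gy/MU) so that the mean planned CTV dose equals
#' \code{target_fraction * prescription_gy}, the usual normalization of a
#' clinical plan to its prescription (by default the CTV mean sits at
#' 102\% so the 95\% isodose covers the target).
#'
#' @param plan a \code{treatment_plan}.
#' @param phantom a phantom with a \code{ctv} mask.
#' @param model a \code{\link{beam_model}}.
#' @param target_fraction CTV mean dose as a fraction of the prescription.
#' @return The model with the rescaled \code{output_gy_per_mu}.
#' @export
calibrate_output <- function(plan, phantom, model, target_fraction = 1.02) {
  nf <- model; nf$noise_rel_sd <- 0
  pd <- planned_dose_at_mu(plan, phantom, plan$total_mu, nf)
  ctv_mean <- mean(pd$values[phantom$masks$ctv$values != 0])
  if (ctv_mean <= 0) stop("plan delivers no dose to the CTV")
  model$output_gy_per_mu <- model$output_gy_per_mu *
    target_fraction * plan$prescription_gy / ctv_mean
  model
}

#' Combined statistical uncertainty of accumulated segments
#'
#' The relative standard deviation of a mean of \code{n} independent
#' calculations, each with relative standard deviation
#' \code{rel_sd_per_segment}: \code{rel_sd_per_segment / sqrt(n)}.
#'
#' @param rel_sd_per_segment relative sd of a single calculation (e.g. 0.05).
#' @param n_segments number of accumulated calculations (>= 1).
#' @return The combined relative standard deviation.
#' @export
combined_uncertainty <- function(rel_sd_per_segment, n_segments) {
  if (n_segments < 1) stop("`n_segments` must be >= 1")
  rel_sd_per_segment / sqrt(n_segments)
}
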