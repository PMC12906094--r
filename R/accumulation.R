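#' Anatomy state at a time point
#'
#' The transform relating the current anatomy to the reference frame at a
#' timestamp: exactly one of a rigid translation or a dense displacement
#' field.
#'
#' @param timestamp seconds.
#' @param translation length-3 rigid translation (LR, AP, CC), mm.
#' @param u a \code{\link{dvf}}.
#' @param dvf_inv optional precomputed inverse of \code{u} (reused across
#'   the segments of an imaging window).
#' @param provenance \code{"motion"} (translation stream) or
#'   \code{"registration"}.
#' @param id state identifier used in the accumulation ledger.
#' @return An object of class \code{anatomy_state}.
#' @export
anatomy_state <- function(timestamp, translation = NULL, u = NULL,
                          dvf_inv = NULL,
                          provenance = if (is.null(u)) "motion" else "registration",
                          id = NA_integer_) {
  if (is.null(translation) == is.null(u))
    stop("exactly one of `translation` or `u` must be given")
  if (!is.null(translation) && any(!is.finite(translation)))
    stop("translation must be finite")
  structure(list(timestamp = timestamp, translation = translation, u = u,
                 dvf_inv = dvf_inv, provenance = provenance, id = id),
            class = "anatomy_state")
}

is_identity_state <- function(state) {
  (!is.null(state$translation) && all(state$translation == 0)) ||
    (!is.null(state$u) && max(abs(state$u$d)) == 0)
}

#' Reconstruct the delivered dose of one segment on the reference frame
#'
#' Rigid states: the dose is computed on the anatomy translated by \code{t}
#' and counter-translated back to the reference frame; both steps are
#' carried out jointly and exactly by computing the dose with the whole
#' beam geometry shifted by \code{-t} (the two formulations are
#' analytically identical for a rigid translation, and the joint form
#' avoids resampling). Deformable states: the reference density is warped
#' by the DVF, the dose is computed on the deformed anatomy, and mapped
#' back through the inverse DVF.
#'
#' @param phantom reference phantom (or density \code{voxel_grid}).
#' @param state an \code{\link{anatomy_state}}.
#' @param segment a beam segment from \code{\link{make_segments}} (or any
#'   list with an aperture and \code{delta_mu}).
#' @param model a \code{\link{beam_model}}.
#' @param noise_seed per-segment noise seed (NULL: current RNG stream).
#' @param current_density optional precomputed deformed density grid for
#'   the state (deformable mode).
#' @return A \code{dose_grid} on the reference grid.
#' @export
reconstruct_segment <- function(phantom, state, segment, model,
                                noise_seed = NULL, current_density = NULL) {
  ap <- as_aperture(segment)
  if (!is.null(state$translation)) {
    compute_segment_dose(phantom, ap, segment$delta_mu, model,
                         noise_seed = noise_seed,
                         beam_offset = -as.numeric(state$translation))
  } else {
    if (is_identity_state(state))
      return(compute_segment_dose(phantom, ap, segment$delta_mu, model,
                                  noise_seed = noise_seed))
    dens_cur <- if (is.null(current_density))
      warp_volume(phantom_density(phantom), state$u,
                  fill = min(phantom_density(phantom)$values))
    else current_density
    dose_cur <- compute_segment_dose(dens_cur, ap, segment$delta_mu, model,
                                     noise_seed = noise_seed)
    inv <- if (is.null(state$dvf_inv)) invert_dvf(state$u) else state$dvf_inv
    w <- warp_volume(dose_cur, inv, fill = 0)
    dose_grid(pmax(w$values, 0), w$spacing, w$origin)
  }
}

#' Running accumulated dose with its MU ledger
#'
#' @param grid a \code{voxel_grid} defining the reference geometry.
#' @return An empty \code{accumulated_dose}: zero dose, zero MU, empty
#'   ledger.
#' @export
new_accumulated <- function(grid) {
  grid <- phantom_density(grid)
  structure(list(dose = dose_grid(array(0, dim(grid$values)), grid$spacing,
                                  grid$origin),
                 delivered_mu = 0,
                 ledger = data.frame(delta_mu = numeric(0),
                                     state_id = integer(0),
                                     seed = integer(0))),
            class = "accumulated_dose")
}

#' Add one reconstructed segment dose to the accumulation
#'
#' Element-wise sum with the ledger appended and \code{delivered_mu}
#' incremented; the ledger MU sum always equals \code{delivered_mu}.
#'
#' @param acc an \code{accumulated_dose}.
#' @param segment_dose a \code{dose_grid} on the same grid.
#' @param delta_mu MU of the segment (> 0).
#' @param state_id,seed ledger bookkeeping.
#' @return The updated \code{accumulated_dose}.
#' @export
accumulate <- function(acc, segment_dose, delta_mu, state_id = NA_integer_,
                       seed = NA_integer_) {
  stop_if_grid_mismatch(acc$dose, segment_dose)
  if (delta_mu <= 0) stop("`delta_mu` must be > 0")
  acc$dose$values <- acc$dose$values + segment_dose$values
  acc$delivered_mu <- acc$delivered_mu + delta_mu
  acc$ledger <- rbind(acc$ledger,
                      data.frame(delta_mu = delta_mu,
                                 state_id = as.integer(state_id),
                                 seed = as.integer(seed)))
  acc
}

#' @export
print.accumulated_dose <- function(x, ...) {
  cat(sprintf("<accumulated_dose> %.2f MU over %d segments, max %.3f Gy\n",
              x$delivered_mu, nrow(x$ledger), max(x$dose$values)))
  invisible(x)
}

#' Per-segment planned dose distributions
#'
#' Noise-free dose of each plan segment on the unmoved reference anatomy;
#' reusable for any planned-to-MU cut because the partial segment dose is
#' linear in MU under the step-and-shoot assumption.
#'
#' @param plan a \code{\link{treatment_plan}}.
#' @param phantom reference phantom.
#' @param model a \code{\link{beam_model}}.
#' @return List of \code{dose_grid}s, one per plan segment.
#' @export
plan_segment_doses <- function(plan, phantom, model) {
  nf <- model; nf$noise_rel_sd <- 0
  lapply(seq_along(plan$segments), function(i)
    compute_segment_dose(phantom, plan_aperture(plan, i),
                         plan$segments[[i]]$mu, nf))
}

#' Planned dose up to a given delivered MU
#'
#' Sum of the full segment doses before the cut plus the straddled
#' segment's dose scaled linearly by its residual MU fraction, on the
#' unmoved reference anatomy, noise-free.
#'
#' @inheritParams plan_segment_doses
#' @param mu delivered MU in \code{[0, total_mu]}.
#' @param seg_doses optional precomputed \code{\link{plan_segment_doses}}.
#' @return A \code{dose_grid}.
#' @export
planned_dose_at_mu <- function(plan, phantom, mu, model, seg_doses = NULL) {
  if (mu < -1e-9 || mu > plan$total_mu + 1e-9)
    stop("`mu` outside [0, total MU]")
  if (is.null(seg_doses)) seg_doses <- plan_segment_doses(plan, phantom, model)
  smu <- vapply(plan$segments, `[[`, numeric(1), "mu")
  cum <- c(0, cumsum(smu))
  w <- pmin(pmax((mu - cum[-length(cum)]) / smu, 0), 1)
  g <- seg_doses[[1]]
  vals <- array(0, dim(g$values))
  for (i in seq_along(seg_doses))
    if (w[i] > 0) vals <- vals + w[i] * seg_doses[[i]]$values
  dose_grid(vals, g$spacing, g$origin)
}

#' Forecast the end-of-fraction dose and coverage
#'
#' The delivered dose so far plus the remainder of the plan computed on
#' the anatomy frozen at the latest state, mapped to the reference frame
#' (noise-free), with the CTV V95\% of the summed distribution.
#'
#' @param acc the current \code{accumulated_dose}.
#' @param plan a \code{\link{treatment_plan}}.
#' @param state the latest \code{\link{anatomy_state}}.
#' @param phantom the reference phantom.
#' @param model a \code{\link{beam_model}}.
#' @param ctv_mask binary \code{voxel_grid} of the CTV (rigid runs use the
#'   planning CTV; deformable runs may pass a warped mask).
#' @return An object of class \code{forecast_result}: \code{dose},
#'   \code{mu_at_forecast}, \code{v95}, \code{n_remaining}.
#' @export
forecast_dose <- function(acc, plan, state, phantom, model, ctv_mask) {
  if (acc$delivered_mu > plan$total_mu + 1e-9)
    stop("delivered MU exceeds the plan total")
  rem <- plan_remaining(plan, acc$delivered_mu)
  nf <- model; nf$noise_rel_sd <- 0
  vals <- acc$dose$values
  if (length(rem)) {
    if (!is.null(state$translation)) {
      off <- -as.numeric(state$translation)
      for (s in rem)
        vals <- vals + compute_segment_dose(phantom, as_aperture(s), s$mu,
                                            nf, beam_offset = off)$values
    } else if (is_identity_state(state)) {
      for (s in rem)
        vals <- vals + compute_segment_dose(phantom, as_aperture(s), s$mu,
                                            nf)$values
    } else {
      dens_cur <- warp_volume(phantom_density(phantom), state$u,
                              fill = min(phantom_density(phantom)$values))
      rsum <- array(0, dim(vals))
      for (s in rem)
        rsum <- rsum + compute_segment_dose(dens_cur, as_aperture(s), s$mu,
                                            nf)$values
      inv <- if (is.null(state$dvf_inv)) invert_dvf(state$u) else state$dvf_inv
      g <- phantom_density(phantom)
      rsum <- warp_volume(dose_grid(rsum, g$spacing, g$origin), inv,
                          fill = 0)$values
      vals <- vals + pmax(rsum, 0)
    }
  }
  g <- acc$dose
  fdose <- dose_grid(vals, g$spacing, g$origin)
  v95 <- v_threshold(fdose, ctv_mask, plan$prescription_gy)
  structure(list(dose = fdose, mu_at_forecast = acc$delivered_mu,
                 v95 = v95, n_remaining = length(rem)),
            class = "forecast_result")
}
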