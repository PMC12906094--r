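#' Generate a step-and-shoot plan
#'
#' A prostate-like IMRT plan: \code{n_segments} step-and-shoot segments at
#' gantry angles spread evenly over a full rotation, each with a
#' rectangular-ish MLC aperture (per-leaf jitter of the field edges) and a
#' randomized MU weight normalized so the segment MU sum equals
#' \code{total_mu} exactly. With \code{n_segments = 1} and zero jitter this
#' reduces to a single open field.
#'
#' @param n_segments number of segments (>= 1).
#' @param field_size_cm nominal field size along the leaf-travel axis, cm.
#' @param field_v_cm field extent along the leaf-stacking (cranial-caudal)
#'   axis, cm; the default leaves a 10 mm margin around a 25 mm-radius
#'   central target.
#' @param prescription_gy prescription dose per fraction, Gy.
#' @param seed integer seed; the plan is byte-identical for a given seed.
#' @param total_mu total plan MU (default 80 per segment).
#' @param mlc_jitter_cm half-range of the uniform per-leaf edge jitter, cm
#'   (0 gives exactly rectangular apertures).
#' @param n_leaves number of MLC leaf pairs.
#' @param leaf_width_cm leaf width at isocenter, cm.
#' @return A \code{\link{treatment_plan}}.
#' @export
make_plan <- function(n_segments = 9, field_size_cm = 8, prescription_gy = 7.5,
                      seed = 1, total_mu = 80 * n_segments,
                      field_v_cm = 7,
                      mlc_jitter_cm = if (n_segments > 1) 0.8 else 0,
                      n_leaves = 20, leaf_width_cm = 0.7) {
  if (n_segments < 1) stop("`n_segments` must be >= 1")
  if (field_size_cm <= 0) stop("`field_size_cm` must be > 0")
  with_local_seed(seed, {
    gantry <- seq(0, 360, length.out = n_segments + 1)[seq_len(n_segments)]
    w <- stats::runif(n_segments, 0.7, 1.3)
    mus <- w / sum(w) * total_mu
    hf <- field_size_cm / 2
    segments <- lapply(seq_len(n_segments), function(i) {
      a <- rep(-hf, n_leaves)
      b <- rep(hf, n_leaves)
      if (mlc_jitter_cm > 0) {
        a <- a - stats::runif(n_leaves, 0, mlc_jitter_cm)
        b <- b + stats::runif(n_leaves, 0, mlc_jitter_cm)
      }
      list(gantry_deg = gantry[i],
           jaws_cm = c(-hf - mlc_jitter_cm, hf + mlc_jitter_cm,
                       -field_v_cm / 2, field_v_cm / 2),
           mlc_cm = rbind(a, b), leaf_width_cm = leaf_width_cm,
           mu = mus[i])
    })
    treatment_plan(segments, prescription_gy)
  })
}

#' Simulate the streamed linac control points for a plan
#'
#' Delivers the plan MU at a constant dose rate while the beam is on,
#' emitting one state message per tick. Segment changeovers insert a short
#' beam hold (MLC repositioning), and MU is clamped at plan-segment
#' boundaries so that every control-point pair lies within a single plan
#' segment. Additional beam holds (e.g. treatment pauses) suppress delivery
#' over the given time windows.
#'
#' @param plan a \code{\link{treatment_plan}}.
#' @param dose_rate_mu_per_min dose rate while the beam is on (default and
#'   maximum 420 MU/min).
#' @param msg_rate_hz message rate, Hz (default 5).
#' @param beam_holds list of \code{c(start_s, end_s)} windows with the beam
#'   held off.
#' @param segment_gap_s beam-off time inserted between plan segments, s.
#' @return A \code{linac_stream}.
#' @export
gen_stream <- function(plan, dose_rate_mu_per_min = 420, msg_rate_hz = 5,
                       beam_holds = NULL, segment_gap_s = 0.4) {
  if (dose_rate_mu_per_min < 0 || dose_rate_mu_per_min > 420)
    stop("`dose_rate_mu_per_min` must be in (0, 420]")
  dt <- 1 / msg_rate_hz
  rate_s <- dose_rate_mu_per_min / 60
  seg_end <- cumsum(vapply(plan$segments, `[[`, numeric(1), "mu"))
  n_seg <- length(seg_end)
  in_hold <- function(t0, t1) {
    if (is.null(beam_holds)) return(FALSE)
    any(vapply(beam_holds, function(h) t0 < h[2] && t1 > h[1], logical(1)))
  }
  t <- 0; mu <- 0; seg_i <- 1L; gap_until <- -Inf
  ts <- numeric(0); mus <- numeric(0); ons <- logical(0); aps <- list()
  if (rate_s <= 0) {
    ts <- seq(0, 2, by = dt); mus <- rep(0, length(ts))
    ons <- rep(FALSE, length(ts))
    aps <- rep(list(plan_aperture(plan, 1L)), length(ts))
  } else {
    max_steps <- ceiling((plan$total_mu / rate_s +
                            n_seg * segment_gap_s + 3600) / dt)
    for (step in seq_len(max_steps)) {
      ap <- plan_aperture(plan, seg_i)
      dmu <- 0
      if (!in_hold(t, t + dt) && t >= gap_until) {
        dmu <- min(rate_s * dt, seg_end[seg_i] - mu)
      }
      ts <- c(ts, t); mus <- c(mus, mu); ons <- c(ons, dmu > 1e-12)
      aps[[length(aps) + 1L]] <- ap
      mu <- mu + dmu
      if (mu >= seg_end[seg_i] - 1e-9 && seg_i < n_seg) {
        seg_i <- seg_i + 1L
        gap_until <- t + dt + segment_gap_s
      }
      t <- t + dt
      if (mu >= plan$total_mu - 1e-9) break
    }
    ts <- c(ts, t); mus <- c(mus, mu); ons <- c(ons, FALSE)
    aps[[length(aps) + 1L]] <- plan_aperture(plan, seg_i)
  }
  linac_stream(ts, mus, ons, aps)
}

# piecewise-linear interpolation of a motion trace at arbitrary times,
# holding the end values beyond the trace
interp_motion <- function(motion, t) {
  sapply(c("dx_mm", "dy_mm", "dz_mm"), function(cn)
    stats::approx(motion$t, motion[[cn]], xout = t, rule = 2)$y)
}

#' Virtual time-resolved measurement
#'
#' Ground-truth "measurement" of a delivery: the noise-free analytic engine
#' evaluated on the true anatomy, independent of the reconstruction pipeline
#' under test. For the diode phantom, the per-segment dose increments are
#' evaluated exactly at the diode positions with the true motion
#' interpolated at each segment midpoint (the diodes ride on the motion
#' platform, so the dose a diode absorbs equals the rest-frame dose with
#' the beam counter-shifted). For the film phantom, increments are
#' evaluated on the true deformed anatomy at the deformed film positions.
#'
#' @param phantom a \code{\link{build_phantom}} object carrying a diode
#'   array or a film plane.
#' @param msgs the delivered \code{linac_stream}.
#' @param model a \code{\link{beam_model}} (noise is disabled internally).
#' @param motion true motion trace (rigid mode).
#' @param dvf_schedule list of phases \code{list(t_start, t_end, dvf,
#'   density)} (deformable mode); \code{density} is the true deformed
#'   density grid for the phase.
#' @param noise_sd_gy additive measurement noise per readout sample, Gy.
#' @param seed seed for the measurement noise.
#' @return Rigid mode: list with \code{times} (readout instants at the
#'   diode readout rate), \code{readout} (times x diodes cumulative Gy),
#'   \code{final} and the per-segment cumulative matrix \code{cum_segments}.
#'   Deformable mode: list with \code{film} (film-plane cumulative dose
#'   matrix, x by z) and \code{final} (vector over film points).
#' @export
virtual_measurement <- function(phantom, msgs, model, motion = NULL,
                                dvf_schedule = NULL, noise_sd_gy = 0,
                                seed = 1) {
  nf <- model; nf$noise_rel_sd <- 0
  segs <- make_segments(msgs)
  if (!is.null(motion)) {
    if (is.null(phantom$diodes)) stop("phantom has no diode array")
    pts <- as.matrix(phantom$diodes[, c("x_mm", "y_mm", "z_mm")])
    nd <- nrow(pts)
    cum <- matrix(0, length(segs) + 1L, nd)
    tknots <- numeric(length(segs) + 1L)
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      tr <- interp_motion(motion, (s$t_start + s$t_end) / 2)
      inc <- dose_at_points(phantom, s$aperture, s$delta_mu, nf, pts,
                            beam_offset = -as.numeric(tr))
      cum[i + 1L, ] <- cum[i, ] + inc
      tknots[i + 1L] <- s$t_end
    }
    tknots[1] <- if (length(segs)) segs[[1]]$t_start else 0
    t_end <- msgs[[length(msgs)]]$t
    times <- seq_len(ceiling(t_end * phantom$readout_hz)) / phantom$readout_hz
    readout <- apply(cum, 2, function(cc)
      stats::approx(tknots, cc, xout = times, rule = 2)$y)
    if (noise_sd_gy > 0)
      readout <- readout + with_local_seed(seed,
        matrix(stats::rnorm(length(readout), 0, noise_sd_gy), nrow(readout)))
    list(times = times, readout = readout, final = cum[nrow(cum), ],
         cum_segments = cum, t_knots = tknots)
  } else if (!is.null(dvf_schedule)) {
    if (is.null(phantom$film)) stop("phantom has no film plane")
    fpts <- phantom$film$points
    total <- numeric(nrow(fpts))
    phase_of <- function(tm) {
      for (p in seq_along(dvf_schedule)) {
        ph <- dvf_schedule[[p]]
        if (tm >= ph$t_start && tm < ph$t_end) return(p)
      }
      length(dvf_schedule)
    }
    # per-phase deformed film positions (the film moves with the material)
    phase_pts <- lapply(dvf_schedule, function(ph) {
      if (is.null(ph$dvf) || max(abs(ph$dvf$d)) == 0) return(fpts)
      inv <- invert_dvf(ph$dvf)
      fpts + sample_dvf(inv, fpts)
    })
    for (s in segs) {
      p <- phase_of((s$t_start + s$t_end) / 2)
      ph <- dvf_schedule[[p]]
      dens <- if (is.null(ph$density)) phantom$density else ph$density
      total <- total + dose_at_points(dens, s$aperture, s$delta_mu, nf,
                                      phase_pts[[p]])
    }
    if (noise_sd_gy > 0)
      total <- total + with_local_seed(seed,
        stats::rnorm(length(total), 0, noise_sd_gy))
    list(film = matrix(total, phantom$film$nx, phantom$film$nz),
         final = total)
  } else {
    stop("provide either `motion` or `dvf_schedule`")
  }
}
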