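#' Express a processing latency as trailing MU
#'
#' At a given dose rate, a latency of \code{latency_s} seconds means the
#' reconstruction can trail the live treatment by at most
#' \code{dose_rate / 60 * latency_s} MU.
#'
#' @param latency_s latency, s (>= 0).
#' @param dose_rate_mu_per_min dose rate, MU/min (> 0).
#' @return Trailing MU.
#' @export
latency_to_mu <- function(latency_s, dose_rate_mu_per_min) {
  if (any(latency_s < 0)) stop("`latency_s` must be >= 0")
  if (dose_rate_mu_per_min <= 0) stop("dose rate must be > 0")
  dose_rate_mu_per_min / 60 * latency_s
}

#' Maximum sustainable linac duty cycle for the processing budget
#'
#' The largest duty fraction \code{d} such that the per-window workload
#' \code{(d * window * msg_rate) * t_segment + t_dir + t_reset} fits in the
#' window, clamped to \code{[0, 1]}. Infeasible fixed costs (DIR + reset
#' exceeding the window) give 0 with a warning.
#'
#' @param t_segment_s time to reconstruct one dose segment, s.
#' @param t_dir_s deformable registration time per window, s (0 for the
#'   rigid workflow).
#' @param t_reset_s dose-engine reset time per window, s.
#' @param window_s processing window (the imaging interval), s.
#' @param msg_rate_hz control-point message rate, Hz.
#' @return Maximum duty fraction in \code{[0, 1]}.
#' @export
sustainable_duty_cycle <- function(t_segment_s, t_dir_s = 0, t_reset_s = 0,
                                   window_s = 10, msg_rate_hz = 5) {
  if (window_s <= 0) stop("`window_s` must be > 0")
  if (any(c(t_segment_s, t_dir_s, t_reset_s) < 0))
    stop("stage times must be >= 0")
  avail <- window_s - t_dir_s - t_reset_s
  if (avail < 0) {
    warning("fixed per-window costs exceed the window; duty cycle 0")
    return(0)
  }
  if (t_segment_s == 0) return(1)
  min(1, avail / (window_s * msg_rate_hz * t_segment_s))
}

#' Session configuration
#'
#' Cadences, stream rates and the simulated per-stage cost model of a
#' real-time session. Wall-clock timing is simulated from these constants
#' (the published stage timings are hardware-bound); the runner reproduces
#' the budget arithmetic, not the hardware.
#'
#' @param forecast_every_segments forecast cadence in delivered segments
#'   (rigid mode).
#' @param imaging_window_s imaging/processing window, s (deformable mode).
#' @param eval_every_segments deviation-series evaluation cadence.
#' @param dose_rate_mu_per_min,msg_rate_hz,segment_gap_s stream generation
#'   parameters (see \code{\link{gen_stream}}).
#' @param t_segment_s,t_dir_s,t_reset_s,t_forecast_per_segment_s simulated
#'   stage costs, s.
#' @return A list of class \code{session_config}.
#' @export
session_config <- function(forecast_every_segments = 10,
                           imaging_window_s = 10,
                           eval_every_segments = 10,
                           dose_rate_mu_per_min = 420, msg_rate_hz = 5,
                           segment_gap_s = 0.4,
                           t_segment_s = 0.082, t_dir_s = 3.0,
                           t_reset_s = 3.0,
                           t_forecast_per_segment_s = 0.72) {
  structure(as.list(environment()), class = "session_config")
}

#' Rigid-motion scenario
#'
#' @param kind motion kind (see \code{\link{gen_motion}}).
#' @param ... motion parameters passed to \code{\link{gen_motion}}.
#' @return A scenario object for \code{\link{run_session}}.
#' @export
rigid_scenario <- function(kind = c("static", "linear_drift", "patient_like"),
                           ...) {
  structure(list(mode = "rigid", kind = match.arg(kind),
                 motion_args = list(...)),
            class = "session_scenario")
}

#' Deformable roll scenario
#'
#' Treatment of the water-bag phantom paused twice to push a virtual roll
#' under the setup at two cranial-caudal positions; each pause inserts a
#' beam hold and switches the true anatomy to the corresponding ridge
#' deformation.
#'
#' @param amplitude_mm ridge crest displacement, mm.
#' @param width_mm ridge 1/e half-width, mm.
#' @param centers_z_mm CC positions of the two roll placements, mm.
#' @param pause_s duration of each delivery pause, s.
#' @return A scenario object for \code{\link{run_session}}.
#' @export
roll_scenario <- function(amplitude_mm = 14, width_mm = 15,
                          centers_z_mm = c(-25, 25), pause_s = 3) {
  structure(list(mode = "deformable", amplitude_mm = amplitude_mm,
                 width_mm = width_mm, centers_z_mm = centers_z_mm,
                 pause_s = pause_s),
            class = "session_scenario")
}

timing_entry <- function(kind, start, duration)
  data.frame(event = kind, start_s = start, duration_s = duration)

#' Run a full simulated real-time session
#'
#' Drives the whole pipeline: generates the control-point stream for the
#' plan, consumes it segment by segment, maintains the accumulated
#' delivered dose on the reference frame, computes the planned dose to the
#' same MU and end-of-fraction forecasts at the configured cadence, and
#' evaluates against the virtual measurement. Fully reproducible for a
#' given seed.
#'
#' @param plan a \code{\link{treatment_plan}}.
#' @param phantom a \code{\link{build_phantom}} object matching the
#'   scenario (diode phantom for rigid, film phantom for deformable).
#' @param scenario a \code{\link{rigid_scenario}} or
#'   \code{\link{roll_scenario}}.
#' @param model a \code{\link{beam_model}}; its \code{noise_rel_sd} governs
#'   the live reconstruction noise (planned dose and forecasts are
#'   noise-free).
#' @param config a \code{\link{session_config}}.
#' @param seed integer seed for all session randomness.
#' @return An object of class \code{session_report}; see the fields
#'   \code{delivered}, \code{planned}, \code{deviation}, \code{coverage},
#'   \code{forecasts}, \code{gamma_planned}, \code{gamma_accumulated},
#'   \code{timing}, \code{schedule}.
#' @export
run_session <- function(plan, phantom, scenario, model = beam_model(),
                        config = session_config(), seed = 1) {
  set.seed(seed)
  if (scenario$mode == "rigid")
    run_session_rigid(plan, phantom, scenario, model, config, seed)
  else
    run_session_deformable(plan, phantom, scenario, model, config, seed)
}

run_session_rigid <- function(plan, phantom, scenario, model, config, seed) {
  msgs <- gen_stream(plan, config$dose_rate_mu_per_min, config$msg_rate_hz,
                     segment_gap_s = config$segment_gap_s)
  t_end <- msgs[[length(msgs)]]$t
  motion <- do.call(gen_motion, c(list(kind = scenario$kind,
                                       duration_s = t_end,
                                       rate_hz = config$msg_rate_hz),
                                  scenario$motion_args))
  segs <- make_segments(msgs)
  synced <- sync_motion(msgs, motion)
  meas <- virtual_measurement(phantom, msgs, model, motion = motion)
  dio_pts <- as.matrix(phantom$diodes[, c("x_mm", "y_mm", "z_mm")])
  nf <- model; nf$noise_rel_sd <- 0

  # planned reference data (noise-free, unmoved anatomy)
  seg_doses <- plan_segment_doses(plan, phantom, model)
  planned_dio_seg <- t(vapply(seq_along(plan$segments), function(i)
    dose_at_points(phantom, plan_aperture(plan, i), plan$segments[[i]]$mu,
                   nf, dio_pts), numeric(nrow(dio_pts))))
  smu <- vapply(plan$segments, `[[`, numeric(1), "mu")
  cum_smu <- c(0, cumsum(smu))
  planned_dio_at <- function(mu) {
    w <- pmin(pmax((mu - cum_smu[-length(cum_smu)]) / smu, 0), 1)
    as.numeric(w %*% planned_dio_seg)
  }
  planned_total <- planned_dose_at_mu(plan, phantom, plan$total_mu, model,
                                      seg_doses)
  ctv <- phantom$masks$ctv
  planned_v95 <- v_threshold(planned_total, ctv, plan$prescription_gy)
  band <- select_diodes(planned_dio_at(plan$total_mu))

  acc <- new_accumulated(phantom)
  calc_dio <- numeric(nrow(dio_pts))
  depth_cache <- new.env(parent = emptyenv())
  timing <- list()
  eval_rows <- list(); fc_rows <- list()
  mu_eval <- c(); meas_mat <- NULL; plan_mat <- NULL; calc_mat <- NULL
  n <- length(segs)
  for (i in seq_len(n)) {
    s <- segs[[i]]
    tr <- as.numeric(synced[s$anatomy_state_id, ])
    key <- sprintf("%.4f|%.4f,%.4f,%.4f", s$aperture$gantry_deg,
                   tr[1], tr[2], tr[3])
    if (is.null(depth_cache[[key]]))
      depth_cache[[key]] <- segment_depth(phantom, s$aperture$gantry_deg,
                                          model, beam_offset = -tr)
    sd_i <- compute_segment_dose(phantom, s$aperture, s$delta_mu, model,
                                 beam_offset = -tr,
                                 depth_cm = depth_cache[[key]])
    acc <- accumulate(acc, sd_i, s$delta_mu, state_id = s$anatomy_state_id)
    calc_dio <- calc_dio + dose_at_points(phantom, s$aperture, s$delta_mu,
                                          model, dio_pts, beam_offset = -tr)
    timing[[length(timing) + 1L]] <-
      timing_entry("segment_dose", s$t_start, config$t_segment_s)
    at_eval <- i %% config$eval_every_segments == 0 || i == n
    if (at_eval) {
      mu_eval <- c(mu_eval, acc$delivered_mu)
      meas_mat <- rbind(meas_mat, meas$cum_segments[i + 1L, ])
      plan_mat <- rbind(plan_mat, planned_dio_at(acc$delivered_mu))
      calc_mat <- rbind(calc_mat, calc_dio)
    }
    if (i %% config$forecast_every_segments == 0 || i == n) {
      state <- anatomy_state(s$t_end, translation = tr,
                             id = s$anatomy_state_id)
      fc <- forecast_dose(acc, plan, state, phantom, model, ctv)
      t_fc <- config$t_forecast_per_segment_s * max(1, fc$n_remaining)
      timing[[length(timing) + 1L]] <-
        timing_entry("forecast", s$t_end, t_fc)
      fc_rows[[length(fc_rows) + 1L]] <-
        data.frame(t_s = s$t_end, mu = fc$mu_at_forecast, v95 = fc$v95,
                   n_remaining = fc$n_remaining, t_forecast_s = t_fc)
    }
  }
  deviation <- deviation_series(meas_mat, plan_mat, calc_mat, mu_eval, band)
  forecasts <- do.call(rbind, fc_rows)
  timing <- do.call(rbind, timing)
  session_report(
    mode = "rigid", scenario = scenario, seed = seed, plan = plan,
    stream = msgs, motion = motion, delivered = acc,
    planned = planned_total, planned_v95 = planned_v95,
    measurement = meas, deviation = deviation, band = band,
    coverage = data.frame(mu = forecasts$mu, v95 = forecasts$v95),
    forecasts = forecasts, timing = timing,
    schedule = schedule_report(msgs, timing, config),
    n_segments = n)
}

run_session_deformable <- function(plan, phantom, scenario, model, config,
                                   seed) {
  rate_s <- config$dose_rate_mu_per_min / 60
  t_beam <- plan$total_mu / rate_s
  p <- scenario$pause_s
  holds <- list(c(t_beam / 3, t_beam / 3 + p),
                c(2 * t_beam / 3 + p, 2 * t_beam / 3 + 2 * p))
  bounds <- c(t_beam / 3 + p / 2, 2 * t_beam / 3 + 1.5 * p)
  ref_dens <- phantom$density
  ridge <- function(cz) roll_dvf(ref_dens, c(0, 0, cz),
                                 scenario$amplitude_mm, scenario$width_mm)
  phases <- list(
    list(t_start = 0, t_end = bounds[1], u = NULL),
    list(t_start = bounds[1], t_end = bounds[2],
         u = ridge(scenario$centers_z_mm[1])),
    list(t_start = bounds[2], t_end = Inf,
         u = ridge(scenario$centers_z_mm[2])))
  phases <- lapply(phases, function(ph) {
    if (is.null(ph$u)) {
      ph$density <- ref_dens
      ph$image <- phantom$image
      ph$dvf <- NULL
    } else {
      ph$density <- warp_volume(ref_dens, ph$u,
                                fill = phantom$densities$air)
      ph$image <- warp_volume(phantom$image, ph$u, fill = 0.02)
      ph$dvf <- ph$u
    }
    ph
  })
  msgs <- gen_stream(plan, config$dose_rate_mu_per_min, config$msg_rate_hz,
                     beam_holds = holds,
                     segment_gap_s = config$segment_gap_s)
  segs <- make_segments(msgs)
  meas <- virtual_measurement(phantom, msgs, model, dvf_schedule = phases)

  phase_of <- function(tm) {
    for (q in seq_along(phases))
      if (tm >= phases[[q]]$t_start && tm < phases[[q]]$t_end) return(q)
    length(phases)
  }
  # registration runs once per imaging window; identical repeat images
  # reuse the cached field
  reg_cache <- vector("list", length(phases))
  get_state <- function(t_now) {
    wb <- floor(t_now / config$imaging_window_s) * config$imaging_window_s
    if (wb <= 0) return(NULL)  # nothing imaged yet
    q <- phase_of(wb)
    if (is.null(phases[[q]]$dvf)) return(NULL)
    if (is.null(reg_cache[[q]])) {
      u <- register_demons(phases[[q]]$image, phantom$image)
      reg_cache[[q]] <<- list(
        u = u, inv = invert_dvf(u),
        density = warp_volume(ref_dens, u, fill = phantom$densities$air))
    }
    anatomy_state(wb, u = reg_cache[[q]]$u, dvf_inv = reg_cache[[q]]$inv,
                  id = q)
  }
  acc <- new_accumulated(phantom)
  timing <- list()
  n_dir <- 0L
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    st <- get_state(s$t_start)
    if (is.null(st)) {
      sd_i <- compute_segment_dose(phantom, s$aperture, s$delta_mu, model)
      state_id <- 0L
    } else {
      sd_i <- reconstruct_segment(phantom, st, s, model,
                                  current_density = reg_cache[[st$id]]$density)
      state_id <- st$id
    }
    acc <- accumulate(acc, sd_i, s$delta_mu, state_id = state_id)
    timing[[length(timing) + 1L]] <-
      timing_entry("segment_dose", s$t_start, config$t_segment_s)
  }
  n_windows <- floor(msgs[[length(msgs)]]$t / config$imaging_window_s)
  for (w in seq_len(n_windows)) {
    timing[[length(timing) + 1L]] <-
      timing_entry("dir", w * config$imaging_window_s, config$t_dir_s)
    timing[[length(timing) + 1L]] <-
      timing_entry("engine_reset", w * config$imaging_window_s,
                   config$t_reset_s)
  }
  timing <- do.call(rbind, timing)
  nf <- model; nf$noise_rel_sd <- 0
  fpts <- phantom$film$points
  film_meas <- meas$film
  film_planned <- matrix(dose_at_points(phantom, plan_aperture(plan, 1),
                                        plan$total_mu, nf, fpts),
                         phantom$film$nx, phantom$film$nz)
  film_acc <- matrix(interp_grid(acc$dose, fpts),
                     phantom$film$nx, phantom$film$nz)
  gp <- gamma_index(film_meas, film_planned, spacing_mm = phantom$film$px_mm)
  ga <- gamma_index(film_meas, film_acc, spacing_mm = phantom$film$px_mm)
  session_report(
    mode = "deformable", scenario = scenario, seed = seed, plan = plan,
    stream = msgs, delivered = acc, measurement = meas,
    film = list(measured = film_meas, planned = film_planned,
                accumulated = film_acc),
    gamma_planned = gp, gamma_accumulated = ga, timing = timing,
    schedule = schedule_report(msgs, timing, config),
    n_segments = length(segs))
}

session_report <- function(...) {
  structure(list(...), class = "session_report")
}

schedule_report <- function(msgs, timing, config) {
  fc <- timing[timing$event == "forecast", , drop = FALSE]
  list(observed_duty_cycle = duty_cycle(msgs),
       max_sustainable_duty_cycle = sustainable_duty_cycle(
         config$t_segment_s, config$t_dir_s, config$t_reset_s,
         config$imaging_window_s, config$msg_rate_hz),
       max_sustainable_duty_cycle_rigid = sustainable_duty_cycle(
         config$t_segment_s, 0, 0, config$imaging_window_s,
         config$msg_rate_hz),
       trailing_mu = data.frame(
         event = timing$event, start_s = timing$start_s,
         trailing_mu = latency_to_mu(timing$duration_s,
                                     config$dose_rate_mu_per_min)),
       forecast_intervals_s = fc$duration_s)
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report:%s> %d segments, %.1f MU delivered\n",
              x$mode, x$n_segments, x$delivered$delivered_mu))
  if (x$mode == "rigid") {
    cat(sprintf("  planned V95 %.1f%%, final forecast V95 %.1f%%\n",
                x$planned_v95, utils::tail(x$coverage$v95, 1)))
    last <- utils::tail(x$deviation, 1)
    cat(sprintf("  final sigma_P %.3f Gy, sigma_C %.3f Gy (band of %d diodes)\n",
                last$sigma_p, last$sigma_c, length(x$band)))
  } else {
    cat(sprintf("  film gamma pass: planned %.1f%%, accumulated %.1f%%\n",
                x$gamma_planned$pass_rate, x$gamma_accumulated$pass_rate))
  }
  invisible(x)
}

#' Write a session report bundle to disk
#'
#' Deviation and coverage series as CSV, gamma and schedule summaries as
#' JSON, the timing log as JSON Lines, and the accumulated (and planned)
#' dose as NIfTI.
#'
#' @param report a \code{session_report}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_session_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  j <- function(x, f) writeLines(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                  digits = NA, na = "null"),
                                 file.path(dir, f))
  if (!is.null(report$deviation))
    utils::write.csv(report$deviation, file.path(dir, "deviation.csv"),
                     row.names = FALSE)
  if (!is.null(report$coverage))
    utils::write.csv(report$coverage, file.path(dir, "coverage.csv"),
                     row.names = FALSE)
  if (!is.null(report$gamma_planned))
    j(list(planned = report$gamma_planned[c("pass_rate", "n_evaluated",
                                            "max_gamma")],
           accumulated = report$gamma_accumulated[c("pass_rate",
                                                    "n_evaluated",
                                                    "max_gamma")]),
      "gamma.json")
  lines <- vapply(seq_len(nrow(report$timing)), function(i)
    as.character(jsonlite::toJSON(as.list(report$timing[i, ]),
                                  auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, file.path(dir, "timing.jsonl"))
  j(list(mode = report$mode, seed = report$seed,
         delivered_mu = report$delivered$delivered_mu,
         n_segments = report$n_segments,
         observed_duty_cycle = report$schedule$observed_duty_cycle,
         max_sustainable_duty_cycle =
           report$schedule$max_sustainable_duty_cycle),
    "summary.json")
  write_volume(report$delivered$dose, file.path(dir, "delivered.nii.gz"))
  if (!is.null(report$planned))
    write_volume(report$planned, file.path(dir, "planned.nii.gz"))
  invisible(dir)
}
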