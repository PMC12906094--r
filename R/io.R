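#' Read / write linac state streams as JSON Lines
#'
#' One message per line with keys \code{t}, \code{gantry_deg},
#' \code{jaws_cm} (4 numbers), \code{mlc_cm} (2 x N), \code{mu},
#' \code{beam_on}.
#'
#' @param msgs a \code{linac_stream}.
#' @param path file path.
#' @return \code{read_stream_jsonl} returns a \code{linac_stream};
#'   writers return the path invisibly.
#' @export
write_stream_jsonl <- function(msgs, path) {
  lines <- vapply(msgs, function(m)
    as.character(jsonlite::toJSON(
      list(t = m$t, gantry_deg = m$gantry_deg, jaws_cm = m$jaws_cm,
           mlc_cm = m$mlc_cm, leaf_width_cm = m$leaf_width_cm,
           mu = m$mu, beam_on = m$beam_on),
      auto_unbox = TRUE, digits = I(17))), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stream_jsonl
#' @export
read_stream_jsonl <- function(path) {
  msgs <- lapply(readLines(path), function(ln) {
    m <- jsonlite::fromJSON(ln, simplifyMatrix = TRUE)
    if (!is.matrix(m$mlc_cm)) m$mlc_cm <- do.call(rbind, m$mlc_cm)
    m
  })
  class(msgs) <- "linac_stream"
  validate_stream(msgs)
}

#' Read / write motion traces as JSON Lines
#'
#' One sample per line with keys \code{t}, \code{dx_mm}, \code{dy_mm},
#' \code{dz_mm}.
#'
#' @param motion data frame with columns \code{t}, \code{dx_mm},
#'   \code{dy_mm}, \code{dz_mm}.
#' @param path file path.
#' @return \code{read_motion_jsonl} returns the motion data frame.
#' @export
write_motion_jsonl <- function(motion, path) {
  lines <- vapply(seq_len(nrow(motion)), function(i)
    as.character(jsonlite::toJSON(as.list(motion[i, ]),
                                  auto_unbox = TRUE, digits = I(17))),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_motion_jsonl
#' @export
read_motion_jsonl <- function(path) {
  rows <- lapply(readLines(path), jsonlite::fromJSON)
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Read a session configuration from YAML
#'
#' The file may carry three top-level sections, each optional:
#' \code{beam_model} (arguments of \code{\link{beam_model}}),
#' \code{session} (arguments of \code{\link{session_config}}) and
#' \code{scenario} (a \code{mode} of \code{"rigid"} or \code{"deformable"}
#' plus the arguments of \code{\link{rigid_scenario}} or
#' \code{\link{roll_scenario}}).
#'
#' @param path YAML file path.
#' @return A list with \code{model}, \code{config} and (possibly NULL)
#'   \code{scenario}.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(cfg$scenario)) {
    mode <- cfg$scenario$mode
    args <- cfg$scenario[setdiff(names(cfg$scenario), "mode")]
    scenario <- if (identical(mode, "deformable"))
      do.call(roll_scenario, args)
    else
      do.call(rigid_scenario, args)
  }
  list(model = do.call(beam_model, as.list(cfg$beam_model)),
       config = do.call(session_config, as.list(cfg$session)),
       scenario = scenario)
}

#' Write a diode readout as CSV
#'
#' Long format with one row per readout instant and diode:
#' \code{t, diode_id, dose_gy} (cumulative dose).
#'
#' @param measurement a rigid-mode \code{\link{virtual_measurement}} result.
#' @param phantom the diode phantom the measurement was taken on.
#' @param path output CSV path.
#' @param every write every k-th readout instant (1 = all; the full 40 Hz
#'   series of a long fraction is large).
#' @return The path, invisibly.
#' @export
write_diode_readout_csv <- function(measurement, phantom, path, every = 1) {
  keep <- seq(1, length(measurement$times), by = every)
  long <- data.frame(
    t = rep(measurement$times[keep], times = nrow(phantom$diodes)),
    diode_id = rep(phantom$diodes$diode_id, each = length(keep)),
    dose_gy = as.numeric(measurement$readout[keep, ]))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
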