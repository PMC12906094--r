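#' Beam aperture at a control point
#'
#' Jaw and MLC settings projected to the isocenter plane. The beam's-eye-view
#' axes are u (leaf travel, cm) and v (leaf stacking, aligned with the
#' cranial-caudal axis at gantry 0, cm).
#'
#' @param gantry_deg gantry angle in degrees (0 = beam entering from the
#'   anterior, rotating about the cranial-caudal axis).
#' @param jaws_cm numeric(4): u1, u2, v1, v2 jaw edges, cm at isocenter.
#' @param mlc_cm 2-by-N matrix of leaf edge positions, cm at isocenter;
#'   row 1 is bank A (lower-u edge), row 2 bank B (upper-u edge).
#' @param leaf_width_cm leaf width along v, cm at isocenter.
#' @return An object of class \code{aperture}.
#' @export
aperture <- function(gantry_deg, jaws_cm, mlc_cm, leaf_width_cm = 0.7) {
  mlc_cm <- rbind(mlc_cm)
  if (nrow(mlc_cm) != 2L) stop("`mlc_cm` must be a 2-by-N matrix")
  if (any(mlc_cm[1, ] > mlc_cm[2, ] + 1e-12))
    stop("MLC leaves cross: bank A edge exceeds bank B edge")
  if (length(jaws_cm) != 4L) stop("`jaws_cm` must have 4 entries")
  if (jaws_cm[1] > jaws_cm[2] || jaws_cm[3] > jaws_cm[4])
    stop("jaw edges out of order")
  structure(list(gantry_deg = as.numeric(gantry_deg),
                 jaws_cm = as.numeric(jaws_cm),
                 mlc_cm = unname(mlc_cm),
                 leaf_width_cm = leaf_width_cm),
            class = "aperture")
}

# v-boundaries of the leaves, cm at isocenter, centered on v = 0
leaf_v_edges_cm <- function(ap) {
  n <- ncol(ap$mlc_cm)
  (seq_len(n + 1) - 1 - n / 2) * ap$leaf_width_cm
}

#' Linac state message stream
#'
#' Builds the streamed machine-state messages as one record per control
#' point. Apertures may be given as a single \code{\link{aperture}} (held
#' constant) or a list of apertures, one per message.
#'
#' @param t numeric vector of timestamps (s), strictly increasing.
#' @param mu cumulative delivered monitor units, non-decreasing.
#' @param beam_on logical vector; a message's flag describes the interval
#'   that starts at it.
#' @param apertures an \code{aperture} or list of apertures.
#' @return A list of messages with class \code{linac_stream}.
#' @export
linac_stream <- function(t, mu, beam_on, apertures) {
  n <- length(t)
  if (inherits(apertures, "aperture")) apertures <- rep(list(apertures), n)
  if (length(apertures) != n) stop("need one aperture per message")
  msgs <- lapply(seq_len(n), function(i) {
    list(t = t[i], gantry_deg = apertures[[i]]$gantry_deg,
         jaws_cm = apertures[[i]]$jaws_cm, mlc_cm = apertures[[i]]$mlc_cm,
         leaf_width_cm = apertures[[i]]$leaf_width_cm,
         mu = mu[i], beam_on = isTRUE(beam_on[i]))
  })
  class(msgs) <- "linac_stream"
  validate_stream(msgs)
  msgs
}

#' Validate a linac message stream
#'
#' Checks the stream invariants: strictly increasing timestamps,
#' non-decreasing cumulative MU, no MU delivered across beam-off intervals,
#' and non-crossing MLC leaves.
#'
#' @param msgs a \code{linac_stream}.
#' @return The stream, invisibly; signals an error naming the first
#'   offending message otherwise.
#' @export
validate_stream <- function(msgs) {
  if (length(msgs) == 0) stop("empty stream")
  t <- vapply(msgs, `[[`, numeric(1), "t")
  mu <- vapply(msgs, `[[`, numeric(1), "mu")
  on <- vapply(msgs, `[[`, logical(1), "beam_on")
  if (length(t) > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop(sprintf("invalid stream: non-increasing timestamp at message %d", bad[1] + 1L))
    bad <- which(diff(mu) < -1e-9)
    if (length(bad))
      stop(sprintf("invalid stream: decreasing cumulative MU at message %d", bad[1] + 1L))
    bad <- which(!on[-length(on)] & diff(mu) > 1e-9)
    if (length(bad))
      stop(sprintf("invalid stream: MU delivered while beam off at message %d", bad[1]))
  }
  for (i in seq_along(msgs))
    if (any(msgs[[i]]$mlc_cm[1, ] > msgs[[i]]$mlc_cm[2, ] + 1e-12))
      stop(sprintf("invalid stream: crossing MLC leaves at message %d", i))
  invisible(msgs)
}

msg_field <- function(msgs, field, type = numeric(1))
  vapply(msgs, `[[`, type, field)

#' Derive beam segments from a control-point stream
#'
#' Between two consecutive control points, if the beam was on at the first
#' and monitor units were delivered, a beam segment is created carrying the
#' interval, the delivered MU, and the aperture held at the start control
#' point (step-and-shoot assumption).
#'
#' @param msgs a \code{linac_stream}.
#' @return A list of segments (class \code{beam_segments}); each has
#'   \code{t_start}, \code{t_end}, \code{delta_mu}, an \code{aperture}, and
#'   \code{anatomy_state_id} (the index of the start message, to be bound to
#'   a synchronized anatomy state).
#' @export
make_segments <- function(msgs) {
  validate_stream(msgs)
  segs <- list()
  for (i in seq_len(length(msgs) - 1L)) {
    m0 <- msgs[[i]]; m1 <- msgs[[i + 1L]]
    dmu <- m1$mu - m0$mu
    if (isTRUE(m0$beam_on) && dmu > 1e-12) {
      segs[[length(segs) + 1L]] <- list(
        t_start = m0$t, t_end = m1$t, delta_mu = dmu,
        aperture = aperture(m0$gantry_deg, m0$jaws_cm, m0$mlc_cm,
                            m0$leaf_width_cm),
        anatomy_state_id = i)
    }
  }
  class(segs) <- "beam_segments"
  segs
}

#' Synchronize motion samples with linac messages
#'
#' Each message is paired with the motion sample of nearest timestamp; on a
#' tie the earlier sample wins, and beyond the end of the motion stream the
#' last sample is held (causal availability).
#'
#' @param msgs a \code{linac_stream}.
#' @param motion a data frame with columns \code{t}, \code{dx_mm},
#'   \code{dy_mm}, \code{dz_mm} (translations in the LR, AP, CC axes).
#' @return An n-by-3 matrix of translations (mm), one row per message.
#' @export
sync_motion <- function(msgs, motion) {
  if (is.null(motion) || nrow(motion) == 0) stop("empty motion stream")
  if (any(diff(motion$t) <= 0)) stop("motion timestamps must be strictly increasing")
  tm <- motion$t
  xyz <- as.matrix(motion[, c("dx_mm", "dy_mm", "dz_mm")])
  t <- msg_field(msgs, "t")
  idx <- vapply(t, function(ti) {
    d <- abs(tm - ti)
    # earlier sample wins ties (compared with a small tolerance so that
    # floating-point noise cannot flip the deterministic tie-break)
    which(d <= min(d) + 1e-9)[1]
  }, integer(1))
  unname(xyz[idx, , drop = FALSE])
}

#' Linac duty cycle of a stream
#'
#' The fraction of beam-on time within the span from the first beam-on to
#' the last beam-off.
#'
#' @param msgs a \code{linac_stream}.
#' @return A fraction in (0, 1].
#' @export
duty_cycle <- function(msgs) {
  validate_stream(msgs)
  t <- msg_field(msgs, "t")
  on <- msg_field(msgs, "beam_on", logical(1))
  n <- length(msgs)
  if (n < 2) stop("need at least two messages")
  ion <- which(on[-n])  # intervals [t_i, t_{i+1}) with beam on
  if (length(ion) == 0) stop("no beam-on interval: duty cycle undefined")
  t_on <- sum(t[ion + 1L] - t[ion])
  span <- t[max(ion) + 1L] - t[min(ion)]
  t_on / span
}
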