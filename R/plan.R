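#' Step-and-shoot treatment plan
#'
#' An ordered list of planned segments, each an aperture plus the monitor
#' units to deliver through it, with the fraction prescription dose.
#'
#' @param segments list of planned segments; each a list with
#'   \code{gantry_deg}, \code{jaws_cm}, \code{mlc_cm}, \code{mu} (and
#'   optionally \code{leaf_width_cm}).
#' @param prescription_gy prescription dose per fraction, Gy (> 0).
#' @return An object of class \code{treatment_plan} with \code{total_mu}
#'   equal to the sum of segment MU.
#' @export
treatment_plan <- function(segments, prescription_gy) {
  if (prescription_gy <= 0) stop("`prescription_gy` must be > 0")
  if (length(segments) < 1) stop("plan needs at least one segment")
  segments <- lapply(segments, function(s) {
    if (is.null(s$leaf_width_cm)) s$leaf_width_cm <- 0.7
    if (s$mu <= 0) stop("segment MU must be > 0")
    s$mlc_cm <- unname(rbind(s$mlc_cm))
    # constructor validates jaws/leaves
    aperture(s$gantry_deg, s$jaws_cm, s$mlc_cm, s$leaf_width_cm)
    s
  })
  structure(list(segments = segments,
                 prescription_gy = as.numeric(prescription_gy),
                 total_mu = sum(vapply(segments, `[[`, numeric(1), "mu"))),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> %d segments, %.1f MU total, %.2f Gy/fraction\n",
              length(x$segments), x$total_mu, x$prescription_gy))
  invisible(x)
}

plan_aperture <- function(plan, i) {
  s <- plan$segments[[i]]
  aperture(s$gantry_deg, s$jaws_cm, s$mlc_cm, s$leaf_width_cm)
}

#' Remainder of a plan after a given number of delivered MU
#'
#' Segments wholly past the cut are returned intact; the straddled segment
#' is returned with its residual MU; the MU of the remainder equals
#' \code{total_mu - delivered_mu}.
#'
#' @param plan a \code{treatment_plan}.
#' @param delivered_mu MU already delivered, in \code{[0, total_mu]}.
#' @return A list of planned segments (possibly empty).
#' @export
plan_remaining <- function(plan, delivered_mu) {
  if (delivered_mu < -1e-9 || delivered_mu > plan$total_mu + 1e-9)
    stop("`delivered_mu` outside [0, total MU]")
  out <- list()
  cum <- 0
  for (s in plan$segments) {
    hi <- cum + s$mu
    if (hi > delivered_mu + 1e-9) {
      res <- s
      res$mu <- hi - max(delivered_mu, cum)
      out[[length(out) + 1L]] <- res
    }
    cum <- hi
  }
  out
}

#' Read / write a treatment plan as JSON
#'
#' @param plan a \code{treatment_plan}.
#' @param path file path.
#' @return \code{read_plan_json} returns a \code{treatment_plan};
#'   \code{write_plan_json} the path, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(prescription_gy = plan$prescription_gy,
              segments = lapply(plan$segments, function(s)
                list(gantry_deg = s$gantry_deg, jaws_cm = s$jaws_cm,
                     mlc_cm = s$mlc_cm, leaf_width_cm = s$leaf_width_cm,
                     mu = s$mu)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  treatment_plan(lapply(obj$segments, function(s) {
    if (!is.matrix(s$mlc_cm))
      s$mlc_cm <- do.call(rbind, s$mlc_cm)
    s
  }), obj$prescription_gy)
}
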