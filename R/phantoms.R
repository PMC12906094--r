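#' Build a virtual phantom
#'
#' Synthetic stand-ins for the physical measurement setups: a homogeneous
#' water cylinder, a diode-array cylinder on a motion platform (time-resolved
#' point dosimetry on two orthogonal interior planes, with a spherical CTV
#' inside the high-dose region), and a deformable water-bag-over-slab setup
#' with a virtual dose film at the interface and two fiducial markers at the
#' film ends.
#'
#' Densities are nominal: water 1.0, water-equivalent slab 1.02, air 0.0012,
#' marker 1.1 g/cm^3. The \code{image} channel is an MR-like intensity
#' volume (water bright, slab intermediate, markers brightest) used by the
#' deformable registration.
#'
#' @param kind one of \code{"water_cylinder"}, \code{"delta4_like"},
#'   \code{"waterbag_film"}.
#' @param n voxels per axis (isotropic grid).
#' @param spacing_mm voxel spacing, mm.
#' @param radius_mm cylinder radius (cylinder phantoms), mm.
#' @param ctv_radius_mm radius of the spherical CTV at the isocenter, mm.
#' @param diode_spacing_mm lattice pitch of the diode planes, mm.
#' @param diode_extent_mm half-extent of the diode lattice, mm.
#' @param readout_hz diode readout rate, Hz.
#' @param film_px_mm film pixel spacing, mm.
#' @param densities named list overriding the nominal densities.
#' @return An object of class \code{phantom}: \code{density} and
#'   \code{image} \code{voxel_grid}s, \code{masks} (named list of binary
#'   grids), and, depending on kind, \code{diodes} (data frame
#'   \code{diode_id, x_mm, y_mm, z_mm} plus \code{readout_hz}) or
#'   \code{film} (point lattice and shape of the film plane) and
#'   \code{markers}.
#' @export
build_phantom <- function(kind = c("water_cylinder", "delta4_like", "waterbag_film"),
                          n = 64, spacing_mm = 3, radius_mm = 90,
                          ctv_radius_mm = 25, diode_spacing_mm = 5,
                          diode_extent_mm = 50, readout_hz = 40,
                          film_px_mm = 2, densities = list()) {
  kind <- match.arg(kind)
  dens0 <- utils::modifyList(
    list(water = 1.0, slab = 1.02, air = 0.0012, marker = 1.1), densities)
  dm <- rep(n, 3)
  base <- voxel_grid(array(dens0$air, dm), spacing = rep(spacing_mm, 3))
  pts <- grid_points(base)
  half <- (n - 1) / 2 * spacing_mm
  out <- list(kind = kind, densities = dens0)

  if (kind %in% c("water_cylinder", "delta4_like")) {
    if (radius_mm > half) stop("cylinder radius exceeds the grid bounds")
    incyl <- pts[, 1]^2 + pts[, 2]^2 <= radius_mm^2
    d <- ifelse(incyl, dens0$water, dens0$air)
    out$density <- grid_like(base, d)
    out$image <- grid_like(base, ifelse(incyl, 1.0, 0.02))
    body <- grid_like(base, as.numeric(incyl))
    ctv <- grid_like(base, as.numeric(pts[, 1]^2 + pts[, 2]^2 + pts[, 3]^2 <=
                                        ctv_radius_mm^2))
    out$masks <- list(body = body, ctv = ctv)
    if (kind == "delta4_like") {
      lat <- seq(-diode_extent_mm, diode_extent_mm, by = diode_spacing_mm)
      cor <- expand.grid(x_mm = lat, y_mm = 0, z_mm = lat)
      sag <- expand.grid(x_mm = 0, y_mm = lat, z_mm = lat)
      dio <- rbind(cor, sag)
      dio <- dio[!duplicated(dio), , drop = FALSE]
      inside <- dio$x_mm^2 + dio$y_mm^2 <= radius_mm^2
      dio <- dio[inside, , drop = FALSE]
      dio <- data.frame(diode_id = seq_len(nrow(dio)), dio, row.names = NULL)
      out$diodes <- dio
      out$readout_hz <- readout_hz
    }
  } else {  # waterbag_film
    water_top <- 48; slab_bot <- -36
    lat_x <- 80; lat_z <- 80
    if (lat_x > half || water_top > half) stop("geometry exceeds grid bounds")
    inlat <- abs(pts[, 1]) <= lat_x & abs(pts[, 3]) <= lat_z
    inwater <- inlat & pts[, 2] > 0 & pts[, 2] <= water_top
    inslab <- inlat & pts[, 2] <= 0 & pts[, 2] >= slab_bot
    d <- rep(dens0$air, nrow(pts))
    d[inwater] <- dens0$water
    d[inslab] <- dens0$slab
    img <- rep(0.02, nrow(pts))
    img[inwater] <- 1.0
    img[inslab] <- 0.55
    # fiducial markers at the film ends (single voxels on the film axis)
    fx <- c(0, 0); fz <- c(-54, 54)
    marker_pts <- cbind(fx, c(0, 0), fz)
    for (i in 1:2) {
      j <- which.min((pts[, 1] - marker_pts[i, 1])^2 +
                       (pts[, 2] - marker_pts[i, 2])^2 +
                       (pts[, 3] - marker_pts[i, 3])^2)
      d[j] <- dens0$marker
      img[j] <- 1.5
      marker_pts[i, ] <- pts[j, ]  # snap to the voxel actually marked
    }
    out$density <- grid_like(base, d)
    out$image <- grid_like(base, img)
    out$masks <- list(body = grid_like(base, as.numeric(inwater | inslab)))
    fu <- seq(-24, 24, by = film_px_mm)       # 5 cm across (x)
    fv <- seq(-50, 50, by = film_px_mm)       # 10 cm along CC (z)
    out$film <- list(points = cbind(rep(fu, times = length(fv)), 0,
                                    rep(fv, each = length(fu))),
                     nx = length(fu), nz = length(fv),
                     x_mm = fu, z_mm = fv, px_mm = film_px_mm,
                     plane_y_mm = 0)
    out$markers <- marker_pts
  }
  class(out) <- "phantom"
  out
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom:%s> %s voxels @ %g mm\n", x$kind,
              paste(dim(x$density$values), collapse = "x"),
              x$density$spacing[1]))
  invisible(x)
}

#' Generate a motion trace
#'
#' Rigid 3D translation samples in the (LR, AP, CC) patient axes. Kinds:
#' \code{static} (all zero), \code{linear_drift} (CC component linear from 0
#' to \code{amplitude_mm}, LR = AP = 0), and \code{patient_like} (a
#' piecewise-linear cranial-caudal drift to an apex followed by a partial
#' return, emulating a prostate drift-and-recover pattern).
#'
#' @param kind motion kind.
#' @param duration_s trace duration, s.
#' @param rate_hz sample rate (default 5).
#' @param amplitude_mm drift amplitude for \code{linear_drift}, mm.
#' @param apex_mm,return_to_mm,apex_frac \code{patient_like} parameters:
#'   peak displacement, final displacement, and the fraction of the
#'   duration at which the apex occurs.
#' @return A data frame with columns \code{t}, \code{dx_mm}, \code{dy_mm},
#'   \code{dz_mm} and attribute \code{kind}.
#' @export
gen_motion <- function(kind = c("static", "linear_drift", "patient_like"),
                       duration_s, rate_hz = 5, amplitude_mm = 10,
                       apex_mm = 8, return_to_mm = 2, apex_frac = 0.5) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("`duration_s` must be > 0")
  t <- seq(0, duration_s, by = 1 / rate_hz)
  dz <- switch(kind,
               static = rep(0, length(t)),
               linear_drift = amplitude_mm * t / duration_s,
               patient_like = {
                 ta <- apex_frac * duration_s
                 ifelse(t <= ta, apex_mm * t / ta,
                        apex_mm + (return_to_mm - apex_mm) *
                          (t - ta) / (duration_s - ta))
               })
  structure(data.frame(t = t, dx_mm = 0, dy_mm = 0, dz_mm = dz),
            kind = kind)
}

#' Smooth ridge displacement field (virtual roll)
#'
#' The displacement field produced by pushing a cylindrical roll (axis along
#' LR) under the deformable phantom: a Gaussian ridge with maximal
#' displacement \code{amplitude_mm} at the crest, decaying as
#' \code{exp(-r^2 / width_mm^2)} with the in-plane (AP, CC) distance
#' \code{r} from the crest line, tapered to zero within a margin of the
#' grid boundary.
#'
#' @param grid a \code{voxel_grid} defining the field geometry.
#' @param center_mm length-3 crest position, mm (the LR component is
#'   ignored: the ridge runs along LR).
#' @param amplitude_mm crest displacement, mm (>= 0).
#' @param width_mm 1/e half-width of the ridge, mm.
#' @param direction unit displacement direction (default: anterior, i.e.
#'   material apparent motion towards the beam entrance).
#' @param margin_vox boundary-taper width, voxels.
#' @return A \code{\link{dvf}}.
#' @export
roll_dvf <- function(grid, center_mm, amplitude_mm, width_mm,
                     direction = c(0, -1, 0), margin_vox = 3) {
  if (amplitude_mm < 0) stop("`amplitude_mm` must be >= 0")
  grid <- phantom_density(grid)
  pts <- grid_points(grid)
  r2 <- (pts[, 2] - center_mm[2])^2 + (pts[, 3] - center_mm[3])^2
  mag <- amplitude_mm * exp(-r2 / width_mm^2)
  # taper to zero within a margin of the grid boundary
  dmn <- dim(grid$values)
  for (ax in 1:3) {
    lo <- grid$origin[ax]
    hi <- grid$origin[ax] + (dmn[ax] - 1) * grid$spacing[ax]
    m <- margin_vox * grid$spacing[ax]
    dist <- pmin(pts[, ax] - lo, hi - pts[, ax])
    mag <- mag * pmin(pmax(dist / m, 0), 1)
  }
  direction <- direction / sqrt(sum(direction^2))
  d <- array(0, c(dmn, 3))
  for (k in 1:3)
    d[, , , k] <- array(mag * direction[k], dmn)
  dvf(d, grid$spacing, grid$origin)
}
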