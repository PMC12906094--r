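#' Dense displacement vector field
#'
#' Per-voxel 3-vector displacements (mm) on a regular grid. The field is
#' used in the pull-back sense: warping a volume \code{v} by the field
#' \code{u} yields \code{v'(x) = v(x + u(x))}.
#'
#' @param d 4D numeric array \code{(nx, ny, nz, 3)} of displacements, mm.
#' @param spacing,origin grid geometry as in \code{\link{voxel_grid}}.
#' @return An object of class \code{dvf}.
#' @export
dvf <- function(d, spacing = c(3, 3, 3), origin = NULL) {
  d <- as.array(d)
  if (length(dim(d)) != 4L || dim(d)[4] != 3L)
    stop("`d` must be an (nx, ny, nz, 3) array")
  if (any(!is.finite(d))) stop("displacements must be finite")
  g <- voxel_grid(array(0, dim(d)[1:3]), spacing, origin)
  structure(list(d = d, spacing = g$spacing, origin = g$origin),
            class = "dvf")
}

#' @export
print.dvf <- function(x, ...) {
  mag <- sqrt(x$d[, , , 1]^2 + x$d[, , , 2]^2 + x$d[, , , 3]^2)
  cat(sprintf("<dvf> %s voxels, spacing %s mm, |u| max %.3f mm\n",
              paste(dim(x$d)[1:3], collapse = "x"),
              paste(format(x$spacing), collapse = ", "), max(mag)))
  invisible(x)
}

zero_dvf <- function(grid) {
  dvf(array(0, c(dim(grid$values), 3)), grid$spacing, grid$origin)
}

dvf_component_grid <- function(u, k) {
  voxel_grid(u$d[, , , k, drop = TRUE], u$spacing, u$origin)
}

dvf_grid_geom <- function(u) voxel_grid(u$d[, , , 1], u$spacing, u$origin)

# sample a displacement field at world points; coordinates are clamped to
# the grid hull (the field is extended by its edge values, which matters
# only in the tapered-to-zero boundary margin)
sample_dvf <- function(u, points) {
  g <- dvf_grid_geom(u)
  dm <- dim(g$values)
  for (ax in 1:3) {
    lo <- g$origin[ax]
    hi <- g$origin[ax] + (dm[ax] - 1) * g$spacing[ax]
    points[, ax] <- pmin(pmax(points[, ax], lo), hi)
  }
  vapply(1:3, function(k) interp_grid(dvf_component_grid(u, k), points),
         numeric(nrow(points)))
}

#' Rigidly translate a volume
#'
#' Trilinear resampling of the volume shifted by \code{t_mm}: the output at
#' position \code{x} equals the input at \code{x - t_mm}. Regions moved in
#' from outside the grid take \code{fill}.
#'
#' @param vol a \code{voxel_grid}.
#' @param t_mm length-3 translation (LR, AP, CC), mm.
#' @param fill background value.
#' @return The translated \code{voxel_grid}.
#' @export
apply_translation <- function(vol, t_mm, fill = 0) {
  if (all(t_mm == 0)) return(vol)
  pts <- grid_points(vol)
  pts[, 1] <- pts[, 1] - t_mm[1]
  pts[, 2] <- pts[, 2] - t_mm[2]
  pts[, 3] <- pts[, 3] - t_mm[3]
  grid_like(vol, interp_grid(vol, pts, fill = fill))
}

#' Warp a volume through a displacement field
#'
#' Pull-back resampling \code{v'(x) = v(x + u(x))}.
#'
#' @param vol a \code{voxel_grid} on the same grid as the field.
#' @param u a \code{\link{dvf}}.
#' @param fill background value.
#' @return The warped \code{voxel_grid}.
#' @export
warp_volume <- function(vol, u, fill = 0) {
  stop_if_grid_mismatch(vol, dvf_grid_geom(u))
  pts <- grid_points(vol)
  pts[, 1] <- pts[, 1] + as.numeric(u$d[, , , 1])
  pts[, 2] <- pts[, 2] + as.numeric(u$d[, , , 2])
  pts[, 3] <- pts[, 3] + as.numeric(u$d[, , , 3])
  grid_like(vol, interp_grid(vol, pts, fill = fill))
}

#' @description Masks are warped with linear interpolation and re-thresholded
#' at 0.5 to avoid nearest-neighbour aliasing.
#' @rdname warp_volume
#' @export
warp_mask <- function(vol, u) {
  w <- warp_volume(grid_like(vol, as.numeric(vol$values != 0)), u, fill = 0)
  grid_like(vol, as.numeric(w$values >= 0.5))
}

#' Compose two displacement fields
#'
#' Returns the field \code{c} with \code{warp(warp(v, a), b) = warp(v, c)},
#' i.e. \code{c(x) = b(x) + a(x + b(x))}.
#'
#' @param a,b \code{\link{dvf}} objects on the same grid.
#' @return A \code{dvf}.
#' @export
compose_dvf <- function(a, b) {
  stop_if_grid_mismatch(dvf_grid_geom(a), dvf_grid_geom(b))
  pts <- grid_points(dvf_grid_geom(b))
  shifted <- pts
  shifted[, 1] <- pts[, 1] + as.numeric(b$d[, , , 1])
  shifted[, 2] <- pts[, 2] + as.numeric(b$d[, , , 2])
  shifted[, 3] <- pts[, 3] + as.numeric(b$d[, , , 3])
  av <- sample_dvf(a, shifted)
  out <- b$d
  for (k in 1:3)
    out[, , , k] <- b$d[, , , k] + array(av[, k], dim(b$d)[1:3])
  dvf(out, b$spacing, b$origin)
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the inverse of a smooth, non-folding field:
#' \code{v(x) = -u(x + v(x))}, so that composing \code{u} with the result
#' is approximately the identity.
#'
#' @param u a \code{\link{dvf}}.
#' @param tol convergence tolerance on the update, mm.
#' @param max_iter iteration cap; non-convergence raises an error reporting
#'   the residual.
#' @param damping step fraction of the fixed-point update (values below 1
#'   stabilize fields with larger local gradients).
#' @return The inverse \code{dvf}.
#' @export
invert_dvf <- function(u, tol = 1e-3, max_iter = 200, damping = 0.5) {
  pts <- grid_points(dvf_grid_geom(u))
  dm <- dim(u$d)[1:3]
  v <- -u$d
  for (it in seq_len(max_iter)) {
    shifted <- pts
    shifted[, 1] <- pts[, 1] + as.numeric(v[, , , 1])
    shifted[, 2] <- pts[, 2] + as.numeric(v[, , , 2])
    shifted[, 3] <- pts[, 3] + as.numeric(v[, , , 3])
    uv <- sample_dvf(u, shifted)
    vnew <- v
    for (k in 1:3)
      vnew[, , , k] <- (1 - damping) * v[, , , k] -
        damping * array(uv[, k], dm)
    delta <- max(abs(vnew - v))
    v <- vnew
    if (delta < tol * damping) return(dvf(v, u$spacing, u$origin))
  }
  stop(sprintf("DVF inversion did not converge: residual %.4g mm after %d iterations",
               delta, max_iter))
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

smooth_array <- function(arr, sigma_vox) {
  v <- as.numeric(arr)
  d <- dim(arr)
  for (ax in 0:2) {
    if (d[ax + 1] > 1 && sigma_vox[ax + 1] > 0)
      v <- cpp_sepconv(v, d, gauss_kernel(sigma_vox[ax + 1]), ax)
  }
  array(v, d)
}

#' Gaussian smoothing of a voxel grid
#'
#' Separable Gaussian filter with replicate boundary handling.
#'
#' @param grid a \code{voxel_grid}.
#' @param sigma_mm Gaussian sigma in mm (scalar or per-axis).
#' @return The smoothed \code{voxel_grid}.
#' @export
smooth_grid <- function(grid, sigma_mm) {
  sigma_vox <- rep_len(sigma_mm, 3L) / grid$spacing
  grid_like(grid, smooth_array(grid$values, sigma_vox))
}

# resample a grid to a coarser level (factor f), with pre-smoothing
downsample_grid <- function(grid, f) {
  if (f == 1) return(grid)
  sm <- smooth_grid(grid, sigma_mm = 0.5 * f * grid$spacing)
  nd <- pmax(2L, ceiling(dim(grid$values) / f))
  coarse <- voxel_grid(array(0, nd), spacing = grid$spacing * f,
                       origin = grid$origin)
  grid_like(coarse, interp_grid(sm, grid_points(coarse), fill = 0))
}

array_gradient <- function(arr, spacing) {
  d <- dim(arr)
  lapply(1:3, function(ax) {
    if (d[ax] == 1) return(array(0, d))
    ip <- pmin(seq_len(d[ax]) + 1L, d[ax])
    im <- pmax(seq_len(d[ax]) - 1L, 1L)
    denom <- (ip - im) * spacing[ax]
    g <- switch(ax,
                (arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE]) /
                  denom,
                aperm(aperm(arr[, ip, , drop = FALSE] -
                              arr[, im, , drop = FALSE],
                            c(2, 1, 3)) / denom, c(2, 1, 3)),
                aperm(aperm(arr[, , ip, drop = FALSE] -
                              arr[, , im, drop = FALSE],
                            c(3, 2, 1)) / denom, c(3, 2, 1)))
    g
  })
}

#' Demons-style deformable registration
#'
#' A mono-modal, multi-resolution, diffusion-regularized demons registrar:
#' at each level the moving image is warped by the current field, an
#' intensity-driven update is computed, and the accumulated field is
#' smoothed with a Gaussian. The intensity mean-squared error is
#' non-increasing by construction: a level stops as soon as an iteration
#' would increase it. The result is deterministic. Externally produced
#' fields can be used anywhere a \code{\link{dvf}} is accepted, so a more
#' capable registration algorithm can be plugged in.
#'
#' @param fixed,moving \code{voxel_grid} images on the same grid with
#'   comparable intensities.
#' @param levels number of resolution levels (coarsest factor
#'   \code{2^(levels-1)}).
#' @param iters_per_level maximum iterations per level.
#' @param smooth_sigma_mm Gaussian regularization sigma, mm.
#' @param step_cap_vox maximum update step per iteration, voxels.
#' @param patience iterations without improvement of the intensity MSE
#'   before a level stops; only improving iterations are kept, so the
#'   reported residual trace is non-increasing.
#' @return A \code{dvf} \code{u} minimizing the intensity mismatch of
#'   \code{warp_volume(moving, u)} against \code{fixed}.
#' @export
register_demons <- function(fixed, moving, levels = 3, iters_per_level = 80,
                            smooth_sigma_mm = 3, step_cap_vox = 0.8,
                            patience = 8) {
  stop_if_grid_mismatch(fixed, moving)
  u <- NULL
  mse_trace <- numeric(0)
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    fx <- downsample_grid(fixed, f)
    mv <- downsample_grid(moving, f)
    dm <- dim(fx$values)
    if (is.null(u)) {
      u <- zero_dvf(fx)
    } else {
      # upsample the coarser field to this level
      pts <- grid_points(fx)
      d <- array(0, c(dm, 3))
      for (k in 1:3)
        d[, , , k] <- array(interp_grid(dvf_component_grid(u, k), pts,
                                        fill = 0), dm)
      u <- dvf(d, fx$spacing, fx$origin)
    }
    kappa <- mean(fx$spacing)
    cap <- step_cap_vox * fx$spacing
    mse_best <- Inf
    u_best <- u
    stale <- 0L
    for (it in seq_len(iters_per_level)) {
      w <- warp_volume(mv, u, fill = 0)
      diff <- w$values - fx$values
      mse <- mean(diff^2)
      if (mse < mse_best) {
        mse_best <- mse
        mse_trace <- c(mse_trace, mse)
        u_best <- u
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
      g <- array_gradient(w$values, fx$spacing)
      denom <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2 + (diff / kappa)^2
      d <- u$d
      for (k in 1:3) {
        upd <- -diff * g[[k]] / denom
        upd[!is.finite(upd)] <- 0
        upd <- pmin(pmax(upd, -cap[k]), cap[k])
        d[, , , k] <- u$d[, , , k] + upd
      }
      sigma_vox <- rep_len(smooth_sigma_mm, 3L) / fx$spacing
      for (k in 1:3)
        d[, , , k] <- smooth_array(d[, , , k, drop = TRUE], sigma_vox)
      u <- dvf(d, fx$spacing, fx$origin)
    }
    u <- u_best
  }
  # no image information constrains the field at the scene boundary (air);
  # taper it to zero there so the field stays contained and invertible
  u <- taper_dvf_boundary(u)
  # enforce the smoothness bound on produced fields (max neighbour
  # difference of each displacement component below the voxel spacing),
  # which also guarantees an invertible, non-folding field
  sigma_vox <- rep_len(smooth_sigma_mm, 3L) / u$spacing
  for (pass in 1:6) {
    if (max_neighbour_diff(u) < 0.9 * min(u$spacing)) break
    d <- u$d
    for (k in 1:3)
      d[, , , k] <- smooth_array(d[, , , k, drop = TRUE], sigma_vox)
    u <- dvf(d, u$spacing, u$origin)
  }
  attr(u, "mse_trace") <- mse_trace
  u
}

taper_dvf_boundary <- function(u, margin_vox = 4) {
  g <- dvf_grid_geom(u)
  pts <- grid_points(g)
  w <- rep(1, nrow(pts))
  dm <- dim(g$values)
  for (ax in 1:3) {
    lo <- g$origin[ax]
    hi <- g$origin[ax] + (dm[ax] - 1) * g$spacing[ax]
    m <- margin_vox * g$spacing[ax]
    dist <- pmin(pts[, ax] - lo, hi - pts[, ax])
    w <- w * pmin(pmax(dist / m, 0), 1)
  }
  d <- u$d
  for (k in 1:3) d[, , , k] <- array(as.numeric(d[, , , k]) * w, dm)
  dvf(d, u$spacing, u$origin)
}

# largest finite difference of any displacement component between
# neighbouring voxels (mm)
max_neighbour_diff <- function(u) {
  out <- 0
  for (k in 1:3) {
    dd <- u$d[, , , k, drop = TRUE]
    dm <- dim(dd)
    if (dm[1] > 1) out <- max(out, abs(dd[-1, , ] - dd[-dm[1], , ]))
    if (dm[2] > 1) out <- max(out, abs(dd[, -1, ] - dd[, -dm[2], ]))
    if (dm[3] > 1) out <- max(out, abs(dd[, , -1] - dd[, , -dm[3]]))
  }
  out
}
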