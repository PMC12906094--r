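#' Voxelized 3D scalar field
#'
#' A minimal container for 3D scalar fields on a regular grid: a density
#' phantom (g/cm^3), an image intensity channel, or a dose distribution (Gy).
#' Axes are (x = left-right, y = anterior-posterior, z = cranial-caudal),
#' positions in mm, with voxel \code{[i, j, k]} centered at
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param values 3D numeric array.
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, mm position of the first voxel center.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(values, spacing = c(3, 3, 3), origin = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite")
  if (is.null(origin))  # center the grid on the isocenter
    origin <- -(dim(values) - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' Dose distribution on a voxel grid
#'
#' @param values 3D numeric array of dose values (Gy); must be finite and
#'   non-negative.
#' @inheritParams voxel_grid
#' @return An object of class \code{c("dose_grid", "voxel_grid")}.
#' @export
dose_grid <- function(values, spacing = c(3, 3, 3), origin = NULL) {
  g <- voxel_grid(values, spacing, origin)
  if (any(!is.finite(g$values)) || any(g$values < 0))
    stop("dose values must be finite and non-negative")
  class(g) <- c("dose_grid", "voxel_grid")
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm, range [%.4g, %.4g]\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

grid_like <- function(grid, values) {
  out <- grid
  out$values <- array(values, dim = dim(grid$values))
  out
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("voxel grids do not match (dimensions, spacing or origin differ)")
  invisible(TRUE)
}

#' Voxel center coordinates of a grid
#'
#' @param grid a \code{voxel_grid}.
#' @return An n-by-3 matrix of world coordinates (mm), voxels in
#'   column-major (array) order.
#' @export
grid_points <- function(grid) {
  d <- dim(grid$values)
  cbind(rep(grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
            times = d[2] * d[3]),
        rep(rep(grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
                each = d[1]), times = d[3]),
        rep(grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3],
            each = d[1] * d[2]))
}

#' Trilinear interpolation of a voxel grid at world points
#'
#' @param grid a \code{voxel_grid}.
#' @param points n-by-3 matrix of world coordinates (mm).
#' @param fill value returned outside the grid.
#' @return Numeric vector of interpolated values.
#' @export
interp_grid <- function(grid, points, fill = 0) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_interp3(as.numeric(grid$values), dim(grid$values),
              grid$spacing, grid$origin, points, fill)
}

#' Read / write a voxel grid as NIfTI
#'
#' Spacing is stored in the pixel dimensions and the origin in the sform
#' matrix. Only the axis-aligned geometry used by this package is supported.
#'
#' @param grid a \code{voxel_grid}.
#' @param path file path (.nii or .nii.gz).
#' @return \code{write_volume} returns the path invisibly;
#'   \code{read_volume} returns a \code{voxel_grid}.
#' @export
write_volume <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  m <- diag(4)
  m[1, 1] <- grid$spacing[1]
  m[2, 2] <- grid$spacing[2]
  m[3, 3] <- grid$spacing[3]
  m[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  voxel_grid(array(as.numeric(img), dim = dim(img)),
             spacing = abs(diag(m)[1:3]),
             origin = as.numeric(m[1:3, 4]))
}
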