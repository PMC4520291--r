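#' Density map object
#'
#' A `density_map` holds a 3D scalar field on a regular cubic voxel grid,
#' the representation used for both experimental (target) and simulated
#' (probe) electron-microscopy maps. The grid is stored as an R array
#' indexed `[i, j, k]` along the crystallographic x, y and z axes (x
#' fastest, i.e. the same memory layout as a C-order `(z, y, x)` volume).
#' `origin` is the real-space coordinate, in Angstrom, of the *center* of
#' voxel `[1, 1, 1]`; voxel `[i, j, k]` is centered at
#' `origin + apix * (i - 1, j - 1, k - 1)`.
#'
#' Only isotropic voxels are supported: `apix` is a single edge length in
#' Angstrom shared by the three axes.
#'
#' @param grid 3D numeric array of intensities (arbitrary units); every
#'   axis must have length >= 2 and all values must be finite.
#' @param apix voxel edge length in Angstrom (> 0).
#' @param origin length-3 numeric, real-space position (Angstrom) of the
#'   center of voxel `[1, 1, 1]`.
#' @param label free-text label carried through I/O.
#' @return An object of class `density_map`.
#' @examples
#' m <- density_map(array(runif(4^3), c(4, 4, 4)), apix = 1.5)
#' @export
density_map <- function(grid, apix, origin = c(0, 0, 0), label = "") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a three-dimensional array", call. = FALSE)
  if (any(dim(grid) < 2L))
    stop("every grid axis must have length >= 2", call. = FALSE)
  if (!is.numeric(apix) || length(apix) != 1L || !is.finite(apix) || apix <= 0)
    stop("`apix` must be a single positive number (Angstrom)", call. = FALSE)
  if (!is.numeric(origin) || length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 numeric vector", call. = FALSE)
  if (!all(is.finite(grid)))
    stop("all grid intensities must be finite", call. = FALSE)
  storage.mode(grid) <- "double"
  structure(
    list(grid = grid, apix = as.numeric(apix), origin = as.numeric(origin),
         label = as.character(label)[1L]),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_map: %d x %d x %d voxels, apix %.4g A\n", d[1], d[2], d[3], x$apix))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A; range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3], min(x$grid), max(x$grid)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

is_density_map <- function(x) inherits(x, "density_map")

stopifnot_map <- function(x, arg = "map") {
  if (!is_density_map(x)) stop("`", arg, "` must be a density_map", call. = FALSE)
  invisible(x)
}

# Real-space coordinates (n x 3, Angstrom) of voxel centers given 1-based indices.
voxel_coords <- function(map, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx, 2L, c(1, 1, 1), "-") * map$apix, 2L, map$origin, "+")
}

# Nearest voxel index (1-based, n x 3) for real-space coordinates; may fall
# outside the grid — callers decide how to treat that.
nearest_voxel <- function(map, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  round(sweep(coords, 2L, map$origin, "-") / map$apix) + 1L
}

voxel_in_grid <- function(map, idx) {
  d <- dim(map$grid)
  idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
}

#' Volume-based density threshold
#'
#' Finds the density contour level that encloses a given molecular volume:
#' the largest value `t` such that the voxels with density `>= t` occupy at
#' least `target_volume` cubic Angstrom. This is the standard way to set a
#' surface threshold when the molecular weight of the fitted molecule is
#' known (protein volume about 1.21 A^3 per Dalton, see
#' [volume_from_mass()]).
#'
#' @param map a [density_map()].
#' @param target_volume desired enclosed volume in A^3; must be positive
#'   and no larger than the full grid volume.
#' @return The threshold density value (same units as the map).
#' @export
volume_threshold <- function(map, target_volume) {
  stopifnot_map(map)
  vox <- map$apix^3
  total <- length(map$grid) * vox
  if (!is.numeric(target_volume) || length(target_volume) != 1L ||
      !is.finite(target_volume) || target_volume <= 0)
    stop("`target_volume` must be a single positive number (A^3)", call. = FALSE)
  if (target_volume > total)
    stop(sprintf("target volume %.4g A^3 exceeds the grid volume %.4g A^3",
                 target_volume, total), call. = FALSE)
  k <- ceiling(target_volume / vox)
  sort(map$grid, decreasing = TRUE)[k]
}

#' Expected molecular volume from mass
#'
#' Converts a molecular weight to an expected enclosed volume using the
#' standard protein partial specific volume of 1.21 A^3 per Dalton.
#'
#' @param mass_da molecular mass in Daltons.
#' @param a3_per_da volume per Dalton (default 1.21).
#' @return Volume in A^3.
#' @export
volume_from_mass <- function(mass_da, a3_per_da = 1.21) {
  if (mass_da <= 0) stop("mass must be positive", call. = FALSE)
  mass_da * a3_per_da
}

# Logical array marking surface voxels: above threshold with at least one
# of the 6 face-neighbours below it (out-of-grid counts as below).
surface_logical <- function(map, threshold) {
  above <- map$grid >= threshold
  if (!any(above)) stop("no voxels above threshold", call. = FALSE)
  interior <- above
  for (axis in 1:3)
    for (by in c(-1L, 1L))
      interior <- interior & shift_fill(above, axis, by, FALSE)
  above & !interior
}

# Surface voxel indices (n x 3) without normal estimation or filtering.
surface_voxels <- function(map, threshold) {
  pts <- which(surface_logical(map, threshold), arr.ind = TRUE)
  dimnames(pts) <- NULL
  pts
}

# Shift an array along one axis by `by` voxels, filling vacated entries with
# `fill` (used with logical grids for neighbourhood tests). `by = +1` means
# the value at index i comes from index i + 1.
shift_fill <- function(a, axis, by, fill) {
  d <- dim(a)
  n <- d[axis]
  src <- seq_len(n) + by
  ok <- src >= 1L & src <= n
  out <- array(fill, dim = d)
  take <- function(x, ax, i) switch(ax, x[i, , , drop = FALSE],
                                    x[, i, , drop = FALSE],
                                    x[, , i, drop = FALSE])
  assign_slice <- function(x, ax, i, value) {
    switch(ax,
           x[i, , ] <- value,
           x[, i, ] <- value,
           x[, , i] <- value)
    x
  }
  out <- assign_slice(out, axis, which(ok), take(a, axis, src[ok]))
  out
}

# Shift with edge replication (equivalent to reflective padding for the
# radius-1 kernels used here).
shift_clamp <- function(a, axis, by) {
  d <- dim(a)
  n <- d[axis]
  src <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis, a[src, , , drop = FALSE], a[, src, , drop = FALSE],
         a[, , src, drop = FALSE])
}

# Central-difference gradient (per-voxel d/dx, d/dy, d/dz in density units
# per voxel; edges use one-sided differences via edge replication).
central_gradient <- function(grid) {
  list(
    gx = (shift_clamp(grid, 1L, 1L) - shift_clamp(grid, 1L, -1L)) / 2,
    gy = (shift_clamp(grid, 2L, 1L) - shift_clamp(grid, 2L, -1L)) / 2,
    gz = (shift_clamp(grid, 3L, 1L) - shift_clamp(grid, 3L, -1L)) / 2
  )
}

#' Extract the density surface at a threshold
#'
#' Classifies as surface every voxel with density `>= threshold` that has at
#' least one of its 6 face-neighbours below the threshold (neighbours
#' outside the grid count as below). A unit outward normal is estimated at
#' each surface voxel from the local density gradient: by default the
#' negative central-difference gradient; alternatively pre-computed gradient
#' components (e.g. Sobel responses, see [sobel_components()]) can be
#' supplied. Surface voxels with a vanishing gradient carry no orientation
#' information and are dropped from the point set.
#'
#' @param map a [density_map()].
#' @param threshold density value defining the envelope; must not exceed the
#'   grid maximum.
#' @param gradient optional list with 3D arrays `gx`, `gy`, `gz` to use in
#'   place of the central-difference gradient.
#' @return An object of class `surface_points`: list with `points` (n x 3
#'   integer matrix of voxel indices), `normals` (n x 3, unit rows),
#'   `threshold`, and `dropped` (count of zero-gradient voxels removed).
#' @export
extract_surface <- function(map, threshold, gradient = NULL) {
  stopifnot_map(map)
  surf <- surface_logical(map, threshold)
  pts <- which(surf, arr.ind = TRUE)
  dimnames(pts) <- NULL
  if (is.null(gradient)) gradient <- central_gradient(map$grid)
  g <- cbind(gradient$gx[surf], gradient$gy[surf], gradient$gz[surf])
  nrm <- sqrt(rowSums(g^2))
  keep <- nrm > 1e-12
  dropped <- sum(!keep)
  if (!any(keep)) stop("no surface voxels with a defined normal", call. = FALSE)
  normals <- -g[keep, , drop = FALSE] / nrm[keep]
  structure(list(points = pts[keep, , drop = FALSE], normals = normals,
                 threshold = threshold, dropped = dropped),
            class = "surface_points")
}

#' @export
print.surface_points <- function(x, ...) {
  cat(sprintf("surface_points: %d voxels at threshold %.4g (%d dropped)\n",
              nrow(x$points), x$threshold, x$dropped))
  invisible(x)
}
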