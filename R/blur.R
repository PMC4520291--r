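#' Simulate a density map from an atomic structure
#'
#' Places an isotropic 3D Gaussian at every atom position, with standard
#' deviation `sigma = sigma_factor * resolution` and amplitude proportional
#' to the atomic mass, and sums the contributions on a regular grid that
#' spans the structure's bounding box plus `pad` on every side. Gaussians
#' are truncated at 3 sigma, which bounds the per-voxel omission error at
#' about 1e-4 of an atom's peak. This is the standard real-space blurring
#' used both to make the probe map of a fitted model and to build
#' simulated benchmark maps; the default sigma factor is 0.225 and the
#' default grid spacing is `resolution / 3`, capped at 3.5 Angstrom per
#' pixel.
#'
#' @param structure an [atomic_structure()].
#' @param resolution nominal map resolution in Angstrom (> 0).
#' @param apix grid spacing in Angstrom; defaults to `min(resolution/3,
#'   3.5)`. Values above 3.5 A are refused unless `force = TRUE`, since
#'   coarser grids undersample the Gaussian.
#' @param sigma_factor ratio of the Gaussian standard deviation to the
#'   resolution (default 0.225).
#' @param pad real-space padding in Angstrom added around the bounding box
#'   (default `2 * resolution`).
#' @param force allow `apix > 3.5`.
#' @return A [density_map()] with non-negative intensities.
#' @export
simulate_map <- function(structure, resolution, apix = NULL,
                         sigma_factor = 0.225, pad = NULL, force = FALSE) {
  if (!is_atomic_structure(structure))
    stop("`structure` must be an atomic_structure", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number (Angstrom)", call. = FALSE)
  if (is.null(apix)) apix <- min(resolution / 3, 3.5)
  if (apix <= 0) stop("`apix` must be positive", call. = FALSE)
  if (apix > 3.5 && !force)
    stop("apix ", apix, " exceeds the 3.5 A per pixel cap; pass force = TRUE ",
         "to override", call. = FALSE)
  if (is.null(pad)) pad <- 2 * resolution
  if (pad < 0) stop("`pad` must be >= 0", call. = FALSE)

  xyz <- coords_matrix(structure)
  w <- structure$atoms$mass
  lo <- unname(apply(xyz, 2L, min)) - pad
  hi <- unname(apply(xyz, 2L, max)) + pad
  n <- pmax(ceiling((hi - lo) / apix) + 1L, 2L)
  if (any(n > 2048L))
    stop("structure extent requires a grid larger than 2048 voxels per axis",
         call. = FALSE)
  origin <- lo

  sigma <- sigma_factor * resolution
  cut <- 3 * sigma
  rvox <- ceiling(cut / apix)
  grid <- array(0, dim = n)
  inv2s2 <- 1 / (2 * sigma^2)

  for (atom in seq_len(nrow(xyz))) {
    centre <- (xyz[atom, ] - origin) / apix + 1  # fractional voxel index
    i0 <- pmax(ceiling(centre - rvox), 1)
    i1 <- pmin(floor(centre + rvox), n)
    if (any(i0 > i1)) next
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    dx2 <- ((ix - centre[1]) * apix)^2
    dy2 <- ((iy - centre[2]) * apix)^2
    dz2 <- ((iz - centre[3]) * apix)^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    g <- w[atom] * exp(-r2 * inv2s2)
    g[r2 > cut^2] <- 0
    grid[ix, iy, iz] <- grid[ix, iy, iz] + g
  }
  density_map(grid, apix = apix, origin = origin,
              label = paste0("simulated ", resolution, "A from ", structure$label))
}

#' Resample a map onto another map's grid
#'
#' Trilinear interpolation of the probe map at the voxel centers of the
#' target grid; target voxels outside the probe's extent are set to zero.
#' All two-map scores require both maps on a common grid, so a probe map
#' simulated on its own bounding box is passed through this before
#' scoring.
#'
#' @param probe a [density_map()] to be interpolated.
#' @param target a [density_map()] supplying the output grid geometry.
#' @return A [density_map()] on the target grid.
#' @export
resample_on_grid <- function(probe, target) {
  stopifnot_map(probe, "probe")
  stopifnot_map(target, "target")
  dt <- dim(target$grid)
  dp <- dim(probe$grid)

  # fractional probe indices of every target voxel center, per axis
  fr <- lapply(1:3, function(ax) {
    pos <- target$origin[ax] + (seq_len(dt[ax]) - 1) * target$apix
    (pos - probe$origin[ax]) / probe$apix + 1
  })
  inside_any <- vapply(1:3, function(ax)
    any(fr[[ax]] >= 1 & fr[[ax]] <= dp[ax]), logical(1))
  if (!all(inside_any))
    stop("probe and target grids do not overlap in real space", call. = FALSE)

  fx <- rep(fr[[1]], times = dt[2] * dt[3])
  fy <- rep(rep(fr[[2]], each = dt[1]), times = dt[3])
  fz <- rep(fr[[3]], each = dt[1] * dt[2])

  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0

  out <- numeric(length(fx))
  # gather one corner of the trilinear cell, returning 0 outside the probe
  corner <- function(ii, jj, kk) {
    ok <- ii >= 1 & ii <= dp[1] & jj >= 1 & jj <= dp[2] & kk >= 1 & kk <= dp[3]
    v <- numeric(length(ii))
    if (any(ok)) {
      lin <- (kk[ok] - 1) * dp[1] * dp[2] + (jj[ok] - 1) * dp[1] + ii[ok]
      v[ok] <- probe$grid[lin]
    }
    v
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wgt <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
           (if (dk) tz else 1 - tz)
    nz <- wgt != 0
    if (!any(nz)) next
    v <- numeric(length(wgt))
    v[nz] <- corner(i0[nz] + di, j0[nz] + dj, k0[nz] + dk)
    out <- out + wgt * v
  }
  density_map(array(out, dim = dt), apix = target$apix, origin = target$origin,
              label = paste0("resampled(", probe$label, ")"))
}
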