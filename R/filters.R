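#' 3D Sobel gradient components
#'
#' Separable Sobel convolution of the voxel grid: along the differentiated
#' axis the kernel is the central difference `[1, 0, -1]`, and along each of
#' the two remaining axes the smoothing kernel `[1, 2, 1]`. The three
#' responses approximate the density gradient (scaled by a constant factor
#' of 8 relative to the plain central difference). Edges are handled by
#' reflective padding, which for these radius-1 kernels is equivalent to
#' replicating the edge plane.
#'
#' @param map a [density_map()].
#' @param mask_above optional density value; input voxels below it are set
#'   to zero before the convolution, so the response concentrates on the
#'   envelope edge (used by the Sobel variant of the normal-vector score).
#' @return List of 3D arrays `gx`, `gy`, `gz` matching the grid dimensions.
#' @seealso [sobel_filter()] for the gradient-magnitude map.
#' @export
sobel_components <- function(map, mask_above = NULL) {
  stopifnot_map(map)
  a <- map$grid
  if (!is.null(mask_above)) a[a < mask_above] <- 0
  diff1 <- function(x, axis) shift_clamp(x, axis, 1L) - shift_clamp(x, axis, -1L)
  smooth1 <- function(x, axis)
    shift_clamp(x, axis, 1L) + 2 * x + shift_clamp(x, axis, -1L)
  gx <- smooth1(smooth1(diff1(a, 1L), 2L), 3L)
  gy <- smooth1(smooth1(diff1(a, 2L), 1L), 3L)
  gz <- smooth1(smooth1(diff1(a, 3L), 1L), 2L)
  list(gx = gx, gy = gy, gz = gz)
}

#' 3D Sobel edge-magnitude filter
#'
#' Gradient-magnitude map from the three separable Sobel responses
#' (Euclidean combination). Bright output marks steep density edges, i.e.
#' the molecular surface region of an EM map.
#'
#' @inheritParams sobel_components
#' @param mask_above optional density value; output voxels whose *input*
#'   density is below it are zeroed after filtering.
#' @return A [density_map()] of gradient magnitudes (>= 0).
#' @export
sobel_filter <- function(map, mask_above = NULL) {
  stopifnot_map(map)
  g <- sobel_components(map)
  mag <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  if (!is.null(mask_above)) mag[map$grid < mask_above] <- 0
  density_map(mag, apix = map$apix, origin = map$origin,
              label = paste0("sobel(", map$label, ")"))
}

#' Discrete 3D Laplacian filter
#'
#' 6-neighbour stencil: the sum of the face-neighbours minus six times the
#' centre voxel, with reflective (edge-replicating) padding at the grid
#' boundary. Cross-correlating Laplacian-filtered maps emphasises edge
#' agreement and is the basis of the LAP score.
#'
#' @param map a [density_map()].
#' @return A [density_map()] of filtered values.
#' @export
laplacian_filter <- function(map) {
  stopifnot_map(map)
  a <- map$grid
  out <- -6 * a
  for (axis in 1:3)
    for (by in c(-1L, 1L))
      out <- out + shift_clamp(a, axis, by)
  density_map(out, apix = map$apix, origin = map$origin,
              label = paste0("laplacian(", map$label, ")"))
}
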