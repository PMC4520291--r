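#' @title Goodness-of-fit scores
#' @description Scores quantifying agreement between a probe (model-derived)
#'   map and a target (experimental or simulated) map, or between a fitted
#'   structure and a target map. Polarity differs between scores: CCC,
#'   SCCC, LAP, MI, SMI and ENV are better when larger; NV, NV-S and CD
#'   are better when smaller. [score_polarity()] records this.
#' @name scores
NULL

#' Score polarity
#'
#' @param score score name (e.g. `"ccc"`, `"nv_s"`); segment-score columns
#'   such as `"sccc.helix1"` inherit the polarity of their base score.
#' @return `+1` if larger values are better, `-1` if smaller are better.
#' @export
score_polarity <- function(score) {
  base <- sub("\\..*$", "", score)
  descending <- c("ccc", "sccc", "lap", "mi", "smi", "env")
  ascending <- c("nv", "nv_s", "cd")
  out <- ifelse(base %in% descending, 1L,
                ifelse(base %in% ascending, -1L, NA_integer_))
  if (anyNA(out))
    stop("unknown score name(s): ", paste(score[is.na(out)], collapse = ", "),
         "; supported: ", paste(c(descending, ascending), collapse = ", "),
         call. = FALSE)
  out
}

supported_scores <- function() c("ccc", "lap", "mi", "env", "nv", "nv_s", "cd",
                                 "sccc", "smi")

check_common_grid <- function(probe, target) {
  if (!identical(dim(probe$grid), dim(target$grid)) ||
      abs(probe$apix - target$apix) > 1e-9 ||
      max(abs(probe$origin - target$origin)) > 1e-6)
    stop("probe and target must share a grid; use resample_on_grid() first",
         call. = FALSE)
}

masked_values <- function(map, mask) {
  if (is.null(mask)) as.numeric(map$grid) else as.numeric(map$grid[mask])
}

#' Cross-correlation coefficient (CCC)
#'
#' Pearson correlation of voxel intensities between the probe and target
#' maps over the full common grid (or an optional voxel mask):
#' `sum((p - mean(p)) (t - mean(t))) / sqrt(sum((p - mean(p))^2) sum((t -
#' mean(t))^2))`. Invariant to positive affine rescaling of either map;
#' 1 is a perfect fit.
#'
#' @param probe,target [density_map()] objects on a common grid.
#' @param mask optional logical array (or index vector) selecting the
#'   voxels to evaluate.
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(probe, target, mask = NULL) {
  check_common_grid(probe, target)
  p <- masked_values(probe, mask)
  t_ <- masked_values(target, mask)
  cp <- p - mean(p)
  ct <- t_ - mean(t_)
  denom <- sqrt(sum(cp^2) * sum(ct^2))
  if (denom == 0)
    stop("undefined CCC: zero intensity variance over the evaluated voxels",
         call. = FALSE)
  sum(cp * ct) / denom
}

#' Laplacian-filtered cross-correlation (LAP)
#'
#' CCC of the two maps after applying the discrete Laplacian filter, which
#' emphasises density edges; useful at resolutions worse than 10-15 A.
#'
#' @inheritParams ccc
#' @return LAP score in `[-1, 1]`.
#' @export
lap_ccc <- function(probe, target, mask = NULL) {
  ccc(laplacian_filter(probe), laplacian_filter(target), mask = mask)
}

#' Joint intensity histogram of two maps
#'
#' Equal-width binning of each map over its own intensity range (values at
#' the maximum fall in the last bin), and the joint probability table over
#' the evaluated voxels. The binning underlies the mutual-information
#' score; 20 bins is the conventional choice for EM maps.
#'
#' @inheritParams ccc
#' @param bins number of bins per axis (>= 2), default 20.
#' @return Object of class `joint_histogram`: list with `joint`
#'   (bins x bins probability matrix), `marginal_x`, `marginal_y`,
#'   `edges_x`, `edges_y`, `bins`.
#' @export
joint_histogram <- function(probe, target, bins = 20L, mask = NULL) {
  check_common_grid(probe, target)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  x <- masked_values(probe, mask)
  y <- masked_values(target, mask)
  bx <- bin_index(x, bins)
  by <- bin_index(y, bins)
  counts <- matrix(tabulate((by$idx - 1L) * bins + bx$idx, nbins = bins * bins),
                   nrow = bins)
  joint <- counts / length(x)
  structure(list(joint = joint,
                 marginal_x = rowSums(joint), marginal_y = colSums(joint),
                 edges_x = bx$edges, edges_y = by$edges, bins = bins),
            class = "joint_histogram")
}

bin_index <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    idx <- rep(1L, length(v))
    edges <- c(lo, rep(hi, bins))
  } else {
    w <- (hi - lo) / bins
    idx <- pmin(floor((v - lo) / w) + 1L, bins)
    edges <- lo + w * 0:bins
  }
  list(idx = as.integer(idx), edges = edges)
}

#' Mutual information (MI) between two maps
#'
#' Relative entropy between the joint intensity distribution and the
#' product of the marginals, in bits:
#' `sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` over occupied histogram
#' cells. Both maps are binned independently into `bins` equal-width
#' levels over their own ranges. MI is non-negative; `MI(m, m)` equals the
#' binned entropy of `m`, the largest value achievable against that
#' target.
#'
#' @inheritParams joint_histogram
#' @return Mutual information in bits (>= 0). A map with no intensity
#'   spread yields 0.
#' @export
mutual_information <- function(probe, target, bins = 20L, mask = NULL) {
  h <- joint_histogram(probe, target, bins = bins, mask = mask)
  pj <- h$joint
  px <- h$marginal_x
  py <- h$marginal_y
  occ <- which(pj > 0, arr.ind = TRUE)
  if (nrow(occ) == 0L) return(0)
  p <- pj[occ]
  mi <- sum(p * log2(p / (px[occ[, 1]] * py[occ[, 2]])))
  max(mi, 0)
}

#' Binned Shannon entropy of a map
#'
#' Entropy (bits) of the equal-width binned intensity distribution; equals
#' `mutual_information(m, m, bins)`.
#'
#' @param map a [density_map()].
#' @inheritParams joint_histogram
#' @return Entropy in bits.
#' @export
binned_entropy <- function(map, bins = 20L, mask = NULL) {
  v <- masked_values(map, mask)
  idx <- bin_index(v, bins)$idx
  p <- tabulate(idx, nbins = bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Segment mask: blur the segment alone at the working resolution on the
# target grid and keep voxels above the segment's own volume threshold
# (1.21 A^3/Da of segment mass).
segment_mask <- function(model, segment, target, resolution,
                         sigma_factor = 0.225) {
  seg <- segment_structure(model, segment)
  seg_map <- simulate_map(seg, resolution, apix = target$apix,
                          sigma_factor = sigma_factor)
  seg_on_target <- resample_on_grid(seg_map, target)
  thr <- volume_threshold(seg_on_target, volume_from_mass(total_mass(seg)))
  mask <- seg_on_target$grid >= thr
  if (!any(mask))
    stop("segment '", segment$label, "' produced an empty mask", call. = FALSE)
  mask
}

#' Segment-based cross-correlation (SCCC)
#'
#' CCC restricted to the map region occupied by one structural segment:
#' the whole model is blurred at the working resolution, and the
#' correlation is evaluated only over voxels where the segment's own
#' blurred density exceeds its volume-based threshold. This localises the
#' assessment to a domain or secondary-structure element, which is where
#' flexible-fitting errors concentrate.
#'
#' @param model fitted [atomic_structure()] (the whole model).
#' @param segment a [segment_selection()].
#' @param target target [density_map()].
#' @param resolution working resolution in Angstrom.
#' @param sigma_factor Gaussian width factor for the blurring (default
#'   0.225).
#' @return Masked CCC value.
#' @export
sccc <- function(model, segment, target, resolution, sigma_factor = 0.225) {
  probe <- resample_on_grid(
    simulate_map(model, resolution, apix = target$apix,
                 sigma_factor = sigma_factor), target)
  mask <- segment_mask(model, segment, target, resolution, sigma_factor)
  ccc(probe, target, mask = mask)
}

#' Segment-based mutual information (SMI)
#'
#' [mutual_information()] restricted to the segment mask used by
#' [sccc()].
#'
#' @inheritParams sccc
#' @param bins histogram bins (default 20).
#' @return SMI in bits.
#' @export
smi <- function(model, segment, target, resolution, bins = 20L,
                sigma_factor = 0.225) {
  probe <- resample_on_grid(
    simulate_map(model, resolution, apix = target$apix,
                 sigma_factor = sigma_factor), target)
  mask <- segment_mask(model, segment, target, resolution, sigma_factor)
  mutual_information(probe, target, bins = bins, mask = mask)
}

#' Envelope score (ENV)
#'
#' Counts how well the atoms of a fitted model fill the thresholded target
#' envelope. Each atom whose nearest voxel is above the threshold scores
#' `+1`; atoms in below-threshold voxels (or outside the grid, which
#' triggers a warning) are protrusions and score `-2`; every
#' above-threshold voxel with no atom within one voxel radius (Chebyshev
#' distance 1) is empty space and scores `-1`. The weights are
#' configurable; larger totals are better fits.
#'
#' @param model fitted [atomic_structure()].
#' @param target target [density_map()].
#' @param threshold density value binarising the target.
#' @param weights named numeric with entries `inside`, `protrusion`,
#'   `empty`.
#' @return Integer-valued score.
#' @export
envelope_score <- function(model, target, threshold,
                           weights = c(inside = 1, protrusion = -2, empty = -1)) {
  stopifnot_map(target, "target")
  above <- target$grid >= threshold
  idx <- nearest_voxel(target, coords_matrix(model))
  ok <- voxel_in_grid(target, idx)
  if (any(!ok))
    warning(sum(!ok), " atom(s) fall outside the map grid; counted as protrusions",
            call. = FALSE)
  inside <- rep(FALSE, nrow(idx))
  if (any(ok)) {
    d <- dim(target$grid)
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    inside[ok] <- above[lin]
  }
  atom_part <- sum(inside) * weights[["inside"]] +
    sum(!inside) * weights[["protrusion"]]

  # occupancy: above-threshold voxels within one voxel (26-neighbourhood)
  # of any atom's voxel count as filled
  occupied <- array(FALSE, dim = dim(target$grid))
  if (any(ok)) {
    d <- dim(target$grid)
    vox <- unique(idx[ok, , drop = FALSE])
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nb <- cbind(vox[, 1] + dx, vox[, 2] + dy, vox[, 3] + dz)
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (any(keep)) {
        lin <- (nb[keep, 3] - 1) * d[1] * d[2] + (nb[keep, 2] - 1) * d[1] +
          nb[keep, 1]
        occupied[lin] <- TRUE
      }
    }
  }
  empty <- sum(above & !occupied)
  unname(atom_part + empty * weights[["empty"]])
}

# Map gradient fields used for surface normals: plain central differences
# or Sobel responses on the threshold-masked map.
surface_with_normals <- function(map, threshold, use_sobel = FALSE) {
  grad <- if (use_sobel) sobel_components(map, mask_above = threshold) else NULL
  extract_surface(map, threshold, gradient = grad)
}

# Chunked nearest-neighbour: for each row of `from`, index of nearest row
# of `to` (ties -> lowest index). Coordinates in columns.
nearest_index <- function(from, to, chunk = 2e6) {
  n <- nrow(from); m <- nrow(to)
  rows_per <- max(1L, floor(chunk / m))
  out <- integer(n)
  to_sq <- rowSums(to^2)
  start <- 1L
  while (start <= n) {
    end <- min(start + rows_per - 1L, n)
    block <- from[start:end, , drop = FALSE]
    d2 <- outer(rowSums(block^2), to_sq, "+") - 2 * block %*% t(to)
    out[start:end] <- max.col(-d2, ties.method = "first")
    start <- end + 1L
  }
  out
}

#' Normal-vector score (NV / NV-S)
#'
#' Mean angular difference, in radians, between the surface normals of the
#' target and probe envelopes. For every surface point of the target
#' (within its volume threshold) the probe normal is taken at the probe
#' surface voxel nearest in space; the score is the average of
#' `arccos(a . b)` over those pairs and lies in `[0, pi]`, 0 being a
#' perfect match. With `use_sobel = TRUE` the normals derive from Sobel
#' gradient responses computed on the threshold-masked maps (the NV-S
#' variant), which sharpens surface detection.
#'
#' @param probe,target [density_map()] objects on a common grid.
#' @param threshold_t,threshold_p surface thresholds for target and probe.
#' @param use_sobel use Sobel-filtered gradients for the normals.
#' @return Mean angle in radians, in `[0, pi]`.
#' @export
normal_vector_score <- function(probe, target, threshold_t, threshold_p,
                                use_sobel = FALSE) {
  check_common_grid(probe, target)
  st <- surface_with_normals(target, threshold_t, use_sobel)
  sp <- surface_with_normals(probe, threshold_p, use_sobel)
  nn <- nearest_index(st$points, sp$points)
  dots <- rowSums(st$normals * sp$normals[nn, , drop = FALSE])
  mean(acos(pmin(pmax(dots, -1), 1)))
}

#' Chamfer distance (CD) between map surfaces
#'
#' Average real-space distance from every probe surface point to its
#' nearest target surface point: `(1/n) sum_x min_y ||x - y||` with `X` the
#' probe surface and `Y` the target surface. Zero means the probe surface
#' lies entirely on the target surface; the measure is not symmetric in
#' its arguments.
#'
#' @inheritParams normal_vector_score
#' @return Distance in Angstrom (>= 0).
#' @export
chamfer_distance <- function(probe, target, threshold_t, threshold_p) {
  xp <- voxel_coords(probe, surface_voxels(probe, threshold_p))
  xt <- voxel_coords(target, surface_voxels(target, threshold_t))
  chamfer_points(xp, xt)
}

#' Chamfer distance between two point sets
#'
#' The point-set primitive behind [chamfer_distance()]: mean distance from
#' each row of `x` to its nearest row of `y`.
#'
#' @param x,y numeric matrices of 3D points (rows), Angstrom.
#' @return Mean nearest-neighbour distance in Angstrom.
#' @export
chamfer_points <- function(x, y) {
  x <- matrix(as.numeric(x), ncol = 3L)
  y <- matrix(as.numeric(y), ncol = 3L)
  if (nrow(x) == 0L || nrow(y) == 0L)
    stop("empty point set", call. = FALSE)
  nn <- nearest_index(x, y)
  mean(sqrt(pmax(rowSums((x - y[nn, , drop = FALSE])^2), 0)))
}
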