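#' Generate a local ensemble of rigid fits
#'
#' Random rigid-body perturbations around the current placement: rotation
#' axis uniform on the sphere, rotation angle uniform on `[0, max_rot]`
#' degrees, translation direction uniform on the sphere with magnitude
#' uniform on `[0, max_trans]` Angstrom, all about the model's centre of
#' mass. The unperturbed placement is always included first as
#' `"model_0"` — the reference every local-search assessment compares
#' against. The canonical local-search bounds are 10 Angstrom and 60
#' degrees.
#'
#' Uniform angle about a uniform axis is not the uniform distribution on
#' SO(3); for the small perturbative angles used here that distinction is
#' immaterial and the simple scheme keeps the magnitude bound exact.
#'
#' @param model an [atomic_structure()].
#' @param n number of random fits (>= 1); the ensemble has `n + 1`
#'   members including `model_0`.
#' @param max_trans maximum translation magnitude, Angstrom (default 10).
#' @param max_rot maximum rotation angle, degrees, in `[0, 180]` (default
#'   60).
#' @param seed integer seed; the ensemble is fully reproducible from it.
#' @return List of `n + 1` [fit_transform()] objects with ids
#'   `model_0 ... model_n`. Each random member carries `angle_deg`,
#'   `trans_mag` and `axis` attributes for reporting.
#' @export
generate_local_ensemble <- function(model, n, max_trans = 10, max_rot = 60,
                                    seed = 1L) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (max_trans < 0) stop("`max_trans` must be >= 0", call. = FALSE)
  if (max_rot < 0 || max_rot > 180)
    stop("`max_rot` must lie in [0, 180] degrees", call. = FALSE)
  pivot <- center_of_mass(model)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  fits <- vector("list", n + 1L)
  fits[[1L]] <- fit_transform(fit_id = "model_0", pivot = pivot)
  attr(fits[[1L]], "angle_deg") <- 0
  attr(fits[[1L]], "trans_mag") <- 0
  attr(fits[[1L]], "axis") <- c(0, 0, 1)
  for (i in seq_len(n)) {
    axis <- random_unit_vector()
    angle <- stats::runif(1, 0, max_rot)
    tdir <- random_unit_vector()
    tmag <- stats::runif(1, 0, max_trans)
    ft <- fit_transform(rotation = rotation_about_axis(axis, angle),
                        translation = tdir * tmag, pivot = pivot,
                        fit_id = paste0("model_", i))
    attr(ft, "angle_deg") <- angle
    attr(ft, "trans_mag") <- tmag
    attr(ft, "axis") <- axis
    fits[[i + 1L]] <- ft
  }
  fits
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) return(v / nv)
  }
}

#' Serialize an ensemble's transforms as TSV
#'
#' Columns: fit_id, axis (x, y, z), rotation angle (degrees), translation
#' vector and magnitude.
#'
#' @param fits list of [fit_transform()] from
#'   [generate_local_ensemble()].
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_transforms <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    ax <- attr(f, "axis")
    data.frame(fit_id = f$fit_id,
               axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
               angle_deg = attr(f, "angle_deg"),
               tx = f$translation[1], ty = f$translation[2],
               tz = f$translation[3],
               trans_mag = sqrt(sum(f$translation^2)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load an externally generated ensemble of fits
#'
#' Reads a set of PDB files, or a single multi-model (MODEL/ENDMDL) PDB
#' file, containing alternative placements of the same structure. All
#' members must share the reference's C-alpha set; the first member is the
#' reference.
#'
#' @param paths character vector of PDB paths; a single path may be a
#'   multi-model file.
#' @param skip_het drop HETATM records.
#' @return List with `reference` (an [atomic_structure()]) and
#'   `structures` (list of [atomic_structure()], labelled by filename or
#'   model number).
#' @export
load_ensemble <- function(paths, skip_het = TRUE) {
  if (length(paths) < 1L) stop("no ensemble members given", call. = FALSE)
  structures <- list()
  if (length(paths) == 1L) {
    pdb <- tryCatch(bio3d::read.pdb(paths, multi = TRUE, verbose = FALSE),
                    error = function(e) stop("PDB format error in '", paths,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    nmodel <- nrow(pdb$xyz)
    base <- structure_from_bio3d(pdb$atom, skip_het = skip_het,
                                 label = basename(paths))
    if (is.null(nmodel) || nmodel <= 1L) {
      structures <- list(base)
    } else {
      sel_idx <- which(if (skip_het) pdb$atom$type == "ATOM"
                       else rep(TRUE, nrow(pdb$atom)))
      if (nrow(base$atoms) != length(sel_idx))
        stop("multi-model files with altloc records are not supported",
             call. = FALSE)
      for (m in seq_len(nmodel)) {
        xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
        s <- set_coords(base, xyz[sel_idx, , drop = FALSE])
        s$label <- paste0(basename(paths), "#", m)
        structures[[m]] <- s
      }
    }
  } else {
    structures <- lapply(paths, function(p) read_pdb(p, skip_het = skip_het))
  }
  ref_key <- calpha_table(structures[[1L]])$key
  for (s in structures[-1L]) {
    key <- calpha_table(s)$key
    if (!identical(key, ref_key))
      stop("ensemble member '", s$label,
           "' does not share the reference C-alpha set", call. = FALSE)
  }
  list(reference = structures[[1L]], structures = structures)
}
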