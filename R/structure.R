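#' Atomic structure object
#'
#' An `atomic_structure` is an ordered table of atom records — the model
#' ("probe") side of every fit assessment. Each row carries the PDB
#' identity fields, Cartesian coordinates in Angstrom and an atomic mass in
#' Daltons (used for map simulation, volume thresholds and centres of
#' mass).
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `res_name`, `chain`, `res_seq` (integer), `ins` (insertion code, ""
#'   when absent), `x`, `y`, `z`, `mass`.
#' @param label free-text label.
#' @return Object of class `atomic_structure`.
#' @export
atomic_structure <- function(atoms, label = "") {
  need <- c("serial", "name", "element", "res_name", "chain", "res_seq",
            "ins", "x", "y", "z", "mass")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("`atoms` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(atoms) == 0L) stop("structure has no atoms", call. = FALSE)
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive", call. = FALSE)
  key <- paste(atoms$chain, atoms$res_seq, atoms$ins, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom records: ", key[duplicated(key)][1L], call. = FALSE)
  atoms$res_seq <- as.integer(atoms$res_seq)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = as.character(label)[1L]),
            class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("atomic_structure: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(paste(a$chain, a$res_seq, a$ins))),
              paste(unique(a$chain), collapse = "")))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

is_atomic_structure <- function(x) inherits(x, "atomic_structure")

coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# Fixed internal mass table (Daltons); unknown elements fall back to
# carbon with a warning.
.element_mass_table <- c(
  H = 1.00794, D = 2.0141, C = 12.0107, N = 14.0067, O = 15.9994,
  F = 18.9984, "NA" = 22.9898, MG = 24.305, P = 30.9738, S = 32.065,
  CL = 35.453, K = 39.0983, CA = 40.078, MN = 54.938, FE = 55.845,
  CO = 58.9332, NI = 58.6934, CU = 63.546, ZN = 65.38, SE = 78.96,
  BR = 79.904, I = 126.904)

element_masses <- function(elements) {
  el <- toupper(trimws(elements))
  m <- unname(.element_mass_table[el])
  bad <- is.na(m)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(el[bad]), collapse = ", "),
            ": assigning carbon mass", call. = FALSE)
    m[bad] <- .element_mass_table[["C"]]
  }
  m
}

# Element from the PDB element column when present, otherwise from the
# atom name: skip leading digits, then take a two-letter symbol if it is
# a known element, else the first letter.
infer_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  missing <- is.na(el) | el == ""
  if (any(missing)) {
    guess <- vapply(elety[missing], function(nm) {
      nm <- sub("^[0-9]+", "", toupper(trimws(nm)))
      two <- substr(nm, 1L, 2L)
      # only accept a two-letter symbol when the atom name is itself the
      # bare symbol (metal ions etc.), so CA/CB keep reading as carbon
      if (nchar(nm) == 2L && two %in% names(.element_mass_table) &&
          !two %in% c("CA", "CB", "CD", "CE", "CG", "CZ", "NA", "ND",
                      "NE", "NZ", "OD", "OE", "OG", "OH", "SD", "SG"))
        two
      else substr(nm, 1L, 1L)
    }, character(1))
    el[missing] <- guess
  }
  el
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records. Where several altloc copies
#' of an atom exist, the highest-occupancy one is kept (ties: first in
#' file). Elements come from the PDB element column when present,
#' otherwise they are inferred from the atom name; masses are assigned from
#' a periodic table (unknown elements fall back to carbon with a warning).
#'
#' @param path PDB file path.
#' @param skip_het drop HETATM records (default TRUE).
#' @return An [atomic_structure()].
#' @export
read_pdb <- function(path, skip_het = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  structure_from_bio3d(pdb$atom, skip_het = skip_het,
                       label = basename(path))
}

structure_from_bio3d <- function(atom, skip_het = TRUE, label = "") {
  if (skip_het) atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L)
    stop("no atoms selected (file may contain only HETATM records)", call. = FALSE)
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- " "
  # altloc resolution: highest occupancy, ties -> first occurrence
  atom$alt[is.na(atom$alt)] <- ""
  if (any(atom$alt != "")) {
    key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    ord <- order(key, -occ, seq_len(nrow(atom)))
    atom <- atom[ord, , drop = FALSE]
    atom <- atom[!duplicated(paste(atom$chain, atom$resno, atom$insert,
                                   atom$elety)), , drop = FALSE]
    atom <- atom[order(atom$eleno), , drop = FALSE]
  }
  element <- infer_element(atom$elesy, atom$elety)
  atoms <- data.frame(
    serial = atom$eleno, name = atom$elety, element = element,
    res_name = atom$resid, chain = atom$chain,
    res_seq = as.integer(atom$resno), ins = atom$insert,
    x = atom$x, y = atom$y, z = atom$z,
    mass = element_masses(element),
    stringsAsFactors = FALSE)
  atomic_structure(atoms, label = label)
}

#' Write an atomic structure to a PDB file
#'
#' Emits standards-compliant fixed-width ATOM records (3-decimal
#' coordinates, conventional atom-name justification) via bio3d.
#'
#' @param structure an [atomic_structure()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  if (!is_atomic_structure(structure))
    stop("`structure` must be an atomic_structure", call. = FALSE)
  xyz <- coords_matrix(structure)
  if (any(abs(xyz) >= 10000 - 0.0005))
    stop("coordinates exceed the PDB fixed-width range (|x| < 10000 A)",
         call. = FALSE)
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", nrow(a)),
                   resno = a$res_seq, resid = a$res_name,
                   eleno = a$serial, elety = a$name,
                   chain = a$chain, insert = ifelse(a$ins == "", NA, a$ins),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Rigid-body fit transform
#'
#' A rotation about a pivot point followed by a translation, labelled with
#' a fit identifier: `x -> R (x - pivot) + pivot + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, Angstrom.
#' @param pivot length-3 numeric, the point the rotation acts about.
#' @param fit_id identifier string.
#' @return Object of class `fit_transform`.
#' @export
fit_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                          pivot = c(0, 0, 0), fit_id = "fit") {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("`rotation` must be 3x3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be a proper rotation (det = +1)", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 pivot = as.numeric(pivot), fit_id = as.character(fit_id)[1L]),
            class = "fit_transform")
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues construction of the proper rotation by `angle_deg` degrees
#' about `axis`.
#'
#' @param axis length-3 direction (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("rotation axis must be non-zero", call. = FALSE)
  u <- u / nu
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to a structure
#'
#' @param structure an [atomic_structure()].
#' @param t a [fit_transform()].
#' @return The transformed [atomic_structure()] (atom order and identities
#'   unchanged).
#' @export
apply_transform <- function(structure, t) {
  if (!inherits(t, "fit_transform"))
    stop("`t` must be a fit_transform", call. = FALSE)
  xyz <- coords_matrix(structure)
  moved <- sweep(xyz, 2L, t$pivot, "-") %*% t(t$rotation)
  moved <- sweep(moved, 2L, t$pivot + t$translation, "+")
  set_coords(structure, moved)
}

# Invert a fit_transform analytically.
invert_transform <- function(t) {
  Rinv <- t(t$rotation)
  fit_transform(rotation = Rinv,
                translation = -(Rinv %*% t$translation)[, 1],
                pivot = t$pivot, fit_id = paste0(t$fit_id, "_inv"))
}

calpha_table <- function(structure) {
  a <- structure$atoms
  ca <- a[a$name == "CA" & a$element == "C", , drop = FALSE]
  if (nrow(ca) == 0L) stop("structure has no C-alpha atoms", call. = FALSE)
  key <- paste0(ca$chain, ":", ca$res_seq, ca$ins)
  ord <- order(ca$chain, ca$res_seq, ca$ins)
  list(key = key[ord], xyz = as.matrix(ca[ord, c("x", "y", "z")]))
}

#' C-alpha RMSD between two placements of a structure
#'
#' Root-mean-square deviation over C-alpha atoms paired by chain and
#' residue number. No superposition is performed: the two structures are
#' compared in the frame of the density map, so the value reflects the
#' difference between rigid placements, which is what fit clustering needs.
#'
#' @param a,b [atomic_structure()] objects with identical C-alpha sets.
#' @return RMSD in Angstrom.
#' @export
calpha_rmsd <- function(a, b) {
  ca <- calpha_table(a)
  cb <- calpha_table(b)
  if (!identical(ca$key, cb$key)) {
    only <- union(setdiff(ca$key, cb$key), setdiff(cb$key, ca$key))
    first <- if (length(only)) only[1L] else "residue ordering"
    stop("C-alpha sets differ between structures (first mismatch: ",
         first, ")", call. = FALSE)
  }
  sqrt(mean(rowSums((ca$xyz - cb$xyz)^2)))
}

#' Mass-weighted centre of mass
#'
#' @param structure an [atomic_structure()].
#' @return Length-3 numeric, Angstrom.
#' @export
center_of_mass <- function(structure) {
  xyz <- coords_matrix(structure)
  w <- structure$atoms$mass
  unname(colSums(xyz * w) / sum(w))
}

total_mass <- function(structure) sum(structure$atoms$mass)
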