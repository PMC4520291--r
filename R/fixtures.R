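#' Build a synthetic poly-alanine test structure
#'
#' Generates a toy protein with 5 heavy atoms per residue (N, CA, C, O,
#' CB) on ideal alpha-helical C-alpha geometry (2.3 A helix radius, 1.5 A
#' rise and 100 degrees twist per residue, giving the canonical ~3.8 A
#' consecutive C-alpha spacing). The `"two-domain"` motif joins two such
#' helices through a hinge whose angle is drawn from the seed, emulating a
#' conformational-change test case; `"helix"` is the single-domain case.
#' Everything is deterministic given the seed and writes as a valid PDB.
#'
#' @param n_residues number of residues (>= 3).
#' @param motif `"helix"` or `"two-domain"`.
#' @param seed integer seed controlling the hinge angle (and nothing else
#'   for the plain helix).
#' @param chain chain identifier.
#' @return An [atomic_structure()].
#' @export
make_toy_structure <- function(n_residues, motif = c("helix", "two-domain"),
                               seed = 1L, chain = "A") {
  motif <- match.arg(motif)
  if (n_residues < 3L) stop("`n_residues` must be >= 3", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  ca <- helix_ca(n_residues)
  if (motif == "two-domain") {
    n1 <- floor(n_residues / 2)
    hinge <- stats::runif(1, 10, 45)
    axis <- random_unit_vector()
    R <- rotation_about_axis(axis, hinge)
    pivot <- ca[n1, ]
    tail_idx <- (n1 + 1):n_residues
    ca[tail_idx, ] <- sweep(sweep(ca[tail_idx, , drop = FALSE], 2, pivot, "-") %*% t(R),
                            2, pivot, "+")
  }

  atoms <- residue_atoms(ca, chain)
  atomic_structure(atoms, label = paste0("toy-", motif, "-", n_residues))
}

# Ideal alpha-helix C-alpha trace along z.
helix_ca <- function(n, radius = 2.3, rise = 1.5, twist_deg = 100) {
  i <- seq_len(n) - 1L
  th <- i * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

# Five heavy atoms per residue at fixed local offsets in a frame that
# follows the chain (tangent t, normal u, binormal v). Geometry is
# PDB-plausible, not stereochemically refined.
residue_atoms <- function(ca, chain) {
  n <- nrow(ca)
  masses <- c(N = 14.0067, C = 12.0107, O = 15.9994)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nxt <- ca[min(i + 1L, n), ] - ca[max(i - 1L, 1L), ]
    t_ <- nxt / sqrt(sum(nxt^2))
    ref <- if (abs(t_[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * t_) * t_
    u <- u / sqrt(sum(u^2))
    v <- c(t_[2] * u[3] - t_[3] * u[2],
           t_[3] * u[1] - t_[1] * u[3],
           t_[1] * u[2] - t_[2] * u[1])
    off <- rbind(N  = -1.46 * t_ + 0.30 * u,
                 CA = c(0, 0, 0),
                 C  = 1.52 * t_ + 0.30 * u,
                 O  = 1.60 * t_ + 1.20 * u + 0.30 * v,
                 CB = -0.50 * t_ - 1.20 * u + 0.90 * v)
    xyz <- sweep(off, 2L, ca[i, ], "+")
    el <- c("N", "C", "C", "O", "C")
    rows[[i]] <- data.frame(
      serial = (i - 1L) * 5L + 1:5,
      name = c("N", "CA", "C", "O", "CB"), element = el,
      res_name = "ALA", chain = chain, res_seq = i, ins = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      mass = unname(masses[el]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build a complete synthetic benchmark case
#'
#' A desk-scale analogue of the simulated local-search benchmark: a toy
#' structure is blurred into a target map (sigma factor 0.225, grid
#' spacing capped at 3.5 A per pixel) and a random local ensemble is
#' generated around the true placement with translations up to 10 A and
#' rotations up to 60 degrees — fit `"model_0"` being the unperturbed
#' truth used to simulate the map.
#'
#' @param resolution map resolution in Angstrom, within `[3, 30]`.
#' @param n_fits number of random fits (the ensemble has `n_fits + 1`
#'   members).
#' @param seed integer seed; the whole case is reproducible from it.
#' @param n_residues size of the toy structure (default 40).
#' @param motif toy motif, `"helix"` (default) or `"two-domain"`.
#' @param max_trans,max_rot perturbation bounds (default 10 A, 60 deg).
#' @return List with `target` ([density_map()]), `model`
#'   ([atomic_structure()]) and `fits` (list of [fit_transform()]).
#' @export
make_benchmark_case <- function(resolution, n_fits, seed = 1L,
                                n_residues = 40L, motif = "helix",
                                max_trans = 10, max_rot = 60) {
  if (resolution < 3 || resolution > 30)
    stop("`resolution` must lie in [3, 30] Angstrom", call. = FALSE)
  model <- make_toy_structure(n_residues, motif = motif, seed = seed)
  target <- simulate_map(model, resolution,
                         apix = min(resolution / 3, 3.5),
                         sigma_factor = 0.225)
  fits <- generate_local_ensemble(model, n = n_fits, max_trans = max_trans,
                                  max_rot = max_rot, seed = seed + 1L)
  list(target = target, model = model, fits = fits)
}
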