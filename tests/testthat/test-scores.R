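# ---- cross-correlation ----

test_that("CCC is 1 for self and for positive affine rescalings", {
  m <- random_map(c(8, 8, 8), seed = 1)
  expect_equal(ccc(m, m), 1)
  m2 <- density_map(2.5 * m$grid + 7, m$apix, m$origin)
  expect_equal(ccc(m2, m), 1, tolerance = 1e-12)
  expect_equal(ccc(m, m2), ccc(m2, m))
})

test_that("CCC equals the naive double-loop Pearson on random pairs", {
  for (seed in 1:3) {
    a <- random_map(c(8, 8, 8), seed = seed)
    b <- random_map(c(8, 8, 8), seed = seed + 100)
    expect_equal(ccc(a, b), naive_pearson(as.numeric(a$grid), as.numeric(b$grid)),
                 tolerance = 1e-12)
  }
})

test_that("CCC stays within [-1, 1] over many random pairs", {
  for (seed in 1:100) {
    a <- random_map(c(5, 5, 5), seed = seed)
    b <- random_map(c(5, 5, 5), seed = seed + 1000)
    v <- ccc(a, b)
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("zero-variance input is an undefined CCC", {
  flat <- density_map(array(1, c(4, 4, 4)), 1)
  m <- random_map(c(4, 4, 4))
  expect_error(ccc(flat, m), "undefined CCC")
})

test_that("masked CCC evaluates only the selected voxels", {
  a <- random_map(c(6, 6, 6), seed = 7)
  b <- random_map(c(6, 6, 6), seed = 8)
  mask <- array(FALSE, c(6, 6, 6)); mask[2:4, 2:4, 2:4] <- TRUE
  expect_equal(ccc(a, b, mask = mask),
               naive_pearson(a$grid[mask], b$grid[mask]), tolerance = 1e-12)
})

test_that("maps on different grids are refused until resampled", {
  a <- random_map(c(6, 6, 6))
  b <- random_map(c(7, 6, 6))
  expect_error(ccc(a, b), "common|share a grid")
})

# ---- Laplacian-filtered CCC ----

test_that("LAP is 1 for self and ignores additive constants", {
  m <- blob_map(c(8, 8, 8), sigma = 2)
  expect_equal(lap_ccc(m, m), 1)
  m2 <- density_map(m$grid + 100, m$apix, m$origin)
  expect_equal(lap_ccc(m2, m), 1, tolerance = 1e-12)
})

test_that("LAP is definitionally the CCC of Laplacian-filtered maps", {
  a <- random_map(c(7, 7, 7), seed = 3)
  b <- random_map(c(7, 7, 7), seed = 4)
  expect_identical(lap_ccc(a, b), ccc(laplacian_filter(a), laplacian_filter(b)))
})

# ---- mutual information ----

test_that("MI of a two-level map with itself is exactly 1 bit", {
  g <- array(c(rep(0, 32), rep(1, 32)), c(4, 4, 4))
  m <- density_map(g, 1)
  expect_equal(mutual_information(m, m, bins = 2), 1)
})

test_that("MI(m, m) equals the binned entropy", {
  for (seed in 1:5) {
    m <- random_map(c(6, 6, 6), seed = seed)
    expect_equal(mutual_information(m, m, bins = 20), binned_entropy(m, 20),
                 tolerance = 1e-12)
  }
})

test_that("MI matches the naive histogram double sum", {
  for (seed in 1:3) {
    a <- random_map(c(8, 8, 8), seed = seed)
    b <- random_map(c(8, 8, 8), seed = seed + 50)
    expect_equal(mutual_information(a, b, bins = 5),
                 naive_mi(as.numeric(a$grid), as.numeric(b$grid), 5),
                 tolerance = 1e-12)
  }
})

test_that("MI is non-negative and vanishes for independent maps", {
  for (seed in 1:100) {
    a <- random_map(c(4, 4, 4), seed = seed)
    b <- random_map(c(4, 4, 4), seed = seed + 777)
    expect_gte(mutual_information(a, b, bins = 4), 0)
  }
  big_a <- random_map(c(24, 24, 24), seed = 1)
  big_b <- random_map(c(24, 24, 24), seed = 2)
  # independent uniform maps: MI -> 0 as the grid grows; bound reflects
  # finite-sample bias ~ (bins-1)^2 / (2 n ln 2)
  expect_lt(mutual_information(big_a, big_b, bins = 5), 0.005)
})

test_that("a flat map carries zero mutual information", {
  flat <- density_map(array(2, c(5, 5, 5)), 1)
  m <- random_map(c(5, 5, 5))
  expect_equal(mutual_information(flat, m), 0)
  expect_equal(mutual_information(m, flat), 0)
})

test_that("MI is invariant under bin-preserving monotone transforms", {
  a <- random_map(c(6, 6, 6), seed = 10)
  b <- random_map(c(6, 6, 6), seed = 11)
  mi0 <- mutual_information(a, b, bins = 8)
  a2 <- density_map(3 * a$grid - 2, a$apix, a$origin)  # affine: same bins
  expect_equal(mutual_information(a2, b, bins = 8), mi0, tolerance = 1e-12)
})

test_that("the joint histogram is a proper probability table", {
  a <- random_map(c(6, 6, 6), seed = 12)
  b <- random_map(c(6, 6, 6), seed = 13)
  h <- joint_histogram(a, b, bins = 10)
  expect_equal(sum(h$joint), 1, tolerance = 1e-9)
  expect_true(all(h$joint >= 0))
  expect_equal(h$marginal_x, rowSums(h$joint))
  expect_equal(h$marginal_y, colSums(h$joint))
})

# ---- segment scores ----

two_segment_setup <- function(resolution = 8) {
  model <- make_toy_structure(24, "helix", seed = 2)
  target <- simulate_map(model, resolution, apix = 2)
  seg_n <- segment_selection(data.frame(chain = "A", start = 1, end = 12), "nterm")
  seg_c <- segment_selection(data.frame(chain = "A", start = 13, end = 24), "cterm")
  seg_all <- segment_selection(data.frame(chain = "A", start = 1, end = 24), "all")
  list(model = model, target = target, seg_n = seg_n, seg_c = seg_c,
       seg_all = seg_all, resolution = resolution)
}

test_that("SCCC of the whole structure equals the masked whole-model CCC", {
  su <- two_segment_setup()
  probe <- resample_on_grid(
    simulate_map(su$model, su$resolution, apix = su$target$apix), su$target)
  mask <- cryoscore:::segment_mask(su$model, su$seg_all, su$target, su$resolution)
  expect_equal(sccc(su$model, su$seg_all, su$target, su$resolution),
               ccc(probe, su$target, mask = mask), tolerance = 1e-12)
})

test_that("a perfectly placed model has SCCC 1 in every segment", {
  su <- two_segment_setup()
  expect_equal(sccc(su$model, su$seg_n, su$target, su$resolution), 1,
               tolerance = 1e-9)
  expect_equal(sccc(su$model, su$seg_c, su$target, su$resolution), 1,
               tolerance = 1e-9)
})

test_that("displacing one terminus hurts that segment's SCCC most", {
  su <- two_segment_setup()
  moved <- su$model
  sel <- resolve_segment(moved, su$seg_c)
  moved$atoms$x[sel] <- moved$atoms$x[sel] + 6
  sccc_c0 <- sccc(su$model, su$seg_c, su$target, su$resolution)
  sccc_c1 <- sccc(moved, su$seg_c, su$target, su$resolution)
  sccc_n0 <- sccc(su$model, su$seg_n, su$target, su$resolution)
  sccc_n1 <- sccc(moved, su$seg_n, su$target, su$resolution)
  drop_c <- sccc_c0 - sccc_c1
  drop_n <- sccc_n0 - sccc_n1
  expect_gt(drop_c, 0)
  expect_lt(drop_n, drop_c)
})

test_that("SMI reduces to the masked MI and penalises misplacement", {
  su <- two_segment_setup()
  probe <- resample_on_grid(
    simulate_map(su$model, su$resolution, apix = su$target$apix), su$target)
  mask <- cryoscore:::segment_mask(su$model, su$seg_all, su$target, su$resolution)
  expect_equal(smi(su$model, su$seg_all, su$target, su$resolution),
               mutual_information(probe, su$target, mask = mask),
               tolerance = 1e-12)
  moved <- apply_transform(su$model,
                           fit_transform(rotation_about_axis(c(0, 1, 0), 25),
                                         c(4, 0, 0),
                                         pivot = center_of_mass(su$model)))
  expect_lt(smi(moved, su$seg_c, su$target, su$resolution),
            smi(su$model, su$seg_c, su$target, su$resolution))
})

# ---- envelope score ----

test_that("ENV equals the atom count when the envelope is perfectly filled", {
  # atoms on a 3x3x3 lattice at voxel centers, map above threshold there only
  pos <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  at <- data.frame(serial = 1:27, name = "CA", element = "C", res_name = "ALA",
                   chain = "A", res_seq = 1:27, ins = "",
                   x = pos[, 1], y = pos[, 2], z = pos[, 3], mass = 12)
  s <- atomic_structure(at)
  g <- array(0, c(5, 5, 5))
  g[2:4, 2:4, 2:4] <- 1
  m <- density_map(g, 1, origin = c(-1, -1, -1))
  expect_equal(envelope_score(s, m, 0.5), 27)
})

test_that("an atom with no density anywhere near is a pure protrusion", {
  s <- one_atom <- atomic_structure(data.frame(
    serial = 1, name = "CA", element = "C", res_name = "ALA", chain = "A",
    res_seq = 1, ins = "", x = 2, y = 2, z = 2, mass = 12))
  m <- density_map(array(0, c(5, 5, 5)), 1)
  expect_equal(envelope_score(s, m, 0.5), -2)
})

test_that("ENV matches a hand-computed toy configuration", {
  # map: 5 above-threshold voxels along x at y=z=1 (indices 1:5,1,1)
  g <- array(0, c(7, 3, 3))
  g[1:5, 1, 1] <- 1
  m <- density_map(g, 1, origin = c(0, 0, 0))
  # atoms at voxels 1 and 3 (inside), and one at (6,2,2) voxel -> below thr
  at <- data.frame(serial = 1:3, name = c("C1", "C2", "C3"), element = "C",
                   res_name = "LIG", chain = "A", res_seq = 1:3, ins = "",
                   x = c(0, 2, 6), y = c(0, 0, 1), z = c(0, 0, 1), mass = 12)
  s <- atomic_structure(at)
  # by hand: +1 +1 (inside) -2 (protrusion); envelope voxels within
  # Chebyshev 1 of atom voxels (1,1,1),(3,1,1),(7,2,2): covers x=1..4 of the
  # envelope -> voxel (5,1,1) is empty -> -1.  Total = 1+1-2-1 = -1.
  expect_equal(envelope_score(s, m, 0.5), -1)
})

test_that("ENV decreases monotonically as atoms leave the envelope", {
  su <- two_segment_setup()
  thr <- volume_threshold(su$target, volume_from_mass(total_mass(su$model)))
  shifts <- c(0, 4, 8, 16)
  vals <- vapply(shifts, function(dx) {
    s <- su$model
    s$atoms$x <- s$atoms$x + dx
    suppressWarnings(envelope_score(s, su$target, thr))
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("atoms outside the grid count as protrusions with a warning", {
  s <- atomic_structure(data.frame(
    serial = 1, name = "CA", element = "C", res_name = "ALA", chain = "A",
    res_seq = 1, ins = "", x = 1000, y = 0, z = 0, mass = 12))
  m <- density_map(array(1, c(4, 4, 4)), 1)
  expect_warning(v <- envelope_score(s, m, 0.5), "outside the map")
  expect_equal(v, -2 - 4^3)   # all 64 envelope voxels empty
})

# ---- normal-vector score ----

test_that("NV is exactly 0 for identical maps and pi for opposed ramps", {
  m <- blob_map(c(10, 10, 10), sigma = 2.5)
  thr <- volume_threshold(m, 100)
  expect_equal(normal_vector_score(m, m, thr, thr), 0, tolerance = 1e-6)
  expect_equal(normal_vector_score(m, m, thr, thr, use_sobel = TRUE), 0,
               tolerance = 1e-6)

  up <- ramp_map(c(8, 6, 6))
  down <- ramp_map(c(8, 6, 6), descending = TRUE)
  expect_equal(normal_vector_score(down, up, 4.5, 4.5), pi)
})

test_that("NV lies in [0, pi] for arbitrary map pairs", {
  for (seed in 1:20) {
    a <- blob_map(c(9, 9, 9), centre = c(4, 5, 5) + (seed %% 3), sigma = 2)
    b <- blob_map(c(9, 9, 9), centre = c(6, 4, 5), sigma = 2.5)
    v <- normal_vector_score(a, b, volume_threshold(a, 40),
                             volume_threshold(b, 40))
    expect_gte(v, 0); expect_lte(v, pi)
  }
})

test_that("NV equals a naive per-point reimplementation on offset blobs", {
  a <- blob_map(c(10, 10, 10), centre = c(5, 5, 5), sigma = 2)
  b <- blob_map(c(10, 10, 10), centre = c(6.5, 5.5, 5), sigma = 2)
  thr_a <- volume_threshold(a, 60)
  thr_b <- volume_threshold(b, 60)
  expect_equal(normal_vector_score(b, a, thr_a, thr_b),
               naive_nv(b$grid, a$grid, thr_b, thr_a), tolerance = 1e-12)
})

# ---- Chamfer distance ----

test_that("CD is zero for identical surfaces and 5 for a 3-4-5 pair", {
  m <- blob_map(c(9, 9, 9), sigma = 2)
  thr <- volume_threshold(m, 50)
  expect_equal(chamfer_distance(m, m, thr, thr), 0)
  expect_equal(chamfer_points(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)), 5)
})

test_that("CD matches the O(n^2) brute force on random point sets", {
  set.seed(99)
  for (rep in 1:3) {
    X <- matrix(stats::runif(3 * 150, 0, 20), ncol = 3)
    Y <- matrix(stats::runif(3 * 180, 0, 20), ncol = 3)
    expect_equal(chamfer_points(X, Y), naive_chamfer(X, Y), tolerance = 1e-12)
  }
})

test_that("CD is non-negative and not symmetric in its arguments", {
  a <- blob_map(c(10, 10, 10), centre = c(4, 5, 5), sigma = 1.8)
  b <- blob_map(c(10, 10, 10), centre = c(7, 5, 5), sigma = 2.6)
  ta <- volume_threshold(a, 30); tb <- volume_threshold(b, 80)
  d1 <- chamfer_distance(a, b, tb, ta)
  d2 <- chamfer_distance(b, a, ta, tb)
  expect_gte(d1, 0); expect_gte(d2, 0)
  expect_false(isTRUE(all.equal(d1, d2)))
})

# ---- ensemble scoring ----

test_that("the identity fit of a self-simulated map ranks first", {
  bm <- make_benchmark_case(10, n_fits = 6, seed = 5, n_residues = 16)
  tab <- score_ensemble(bm$fits, bm$model, bm$target, 10,
                        which = c("ccc", "mi", "nv_s"))
  expect_equal(tab$fit_id[tab$rank_ccc == 1], "model_0")
  expect_equal(tab$ccc[1], 1, tolerance = 1e-9)
  expect_equal(tab$fit_id[tab$rank_mi == 1], "model_0")
  expect_equal(tab$fit_id[tab$rank_nv_s == 1], "model_0")
})

test_that("a single-fit ensemble gets rank 1 everywhere", {
  bm <- make_benchmark_case(12, n_fits = 1, seed = 2, n_residues = 10)
  tab <- score_ensemble(bm$fits[1], bm$model, bm$target, 12,
                        which = c("ccc", "mi"))
  expect_equal(tab$rank_ccc, 1L)
  expect_equal(tab$rank_mi, 1L)
})

test_that("ranks agree with an independent sort of the score column", {
  bm <- make_benchmark_case(10, n_fits = 9, seed = 8, n_residues = 12)
  tab <- score_ensemble(bm$fits, bm$model, bm$target, 10,
                        which = c("ccc", "cd"))
  # descending score -> rank for ccc; ascending for cd
  expect_equal(tab$rank_ccc, order(order(-tab$ccc)))
  expect_equal(tab$rank_cd, order(order(tab$cd)))
  expect_setequal(tab$rank_ccc, seq_len(nrow(tab)))
})

test_that("scoring is deterministic: identical inputs, identical outputs", {
  bm <- make_benchmark_case(10, n_fits = 3, seed = 4, n_residues = 10)
  t1 <- score_ensemble(bm$fits, bm$model, bm$target, 10, which = c("ccc", "nv_s"))
  t2 <- score_ensemble(bm$fits, bm$model, bm$target, 10, which = c("ccc", "nv_s"))
  expect_identical(t1, t2)
})

test_that("unknown score names are rejected with the supported list", {
  bm <- make_benchmark_case(10, n_fits = 1, seed = 1, n_residues = 8)
  expect_error(score_ensemble(bm$fits, bm$model, bm$target, 10, which = "bogus"),
               "unknown score.*supported")
  expect_error(score_ensemble(bm$fits, bm$model, bm$target, 10, which = "sccc"),
               "require `segments`")
})

test_that("segment columns appear per segment with matching polarity", {
  su <- two_segment_setup()
  fits <- generate_local_ensemble(su$model, 2, max_trans = 5, max_rot = 30,
                                  seed = 3)
  tab <- score_ensemble(fits, su$model, su$target, su$resolution,
                        which = c("ccc", "sccc"),
                        segments = list(su$seg_n, su$seg_c))
  expect_true(all(c("sccc.nterm", "sccc.cterm", "rank_sccc.nterm") %in% names(tab)))
  expect_equal(tab$fit_id[tab$`rank_sccc.nterm` == 1], "model_0")
})
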