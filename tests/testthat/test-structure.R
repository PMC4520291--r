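test_that("a 3-residue poly-alanine has 15 atoms and survives a PDB round trip", {
  s <- make_toy_structure(3, "helix")
  expect_equal(nrow(s$atoms), 15)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, p)
  s2 <- read_pdb(p)
  expect_equal(nrow(s2$atoms), 15)
  expect_equal(coords_matrix(s2), coords_matrix(s), tolerance = 1e-3)
  expect_identical(s2$atoms$chain, s$atoms$chain)
  expect_identical(s2$atoms$res_seq, s$atoms$res_seq)
  expect_identical(s2$atoms$name, s$atoms$name)
})

test_that("coordinates outside the PDB fixed-width range are refused", {
  s <- make_toy_structure(3, "helix")
  s$atoms$x[1] <- 12345
  expect_error(write_pdb(s, tempfile()), "fixed-width range")
})

test_that("a HETATM-only file yields a 'no atoms selected' error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(p, c(
    pdb_atom_line(1, "O", "HOH", "A", 1, 1, 2, 3, type = "HETATM"),
    pdb_atom_line(2, "O", "HOH", "A", 2, 4, 5, 6, type = "HETATM")))
  expect_error(read_pdb(p, skip_het = TRUE), "no atoms selected")
  expect_equal(nrow(read_pdb(p, skip_het = FALSE)$atoms), 2)
})

test_that("altloc copies resolve to the highest occupancy", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(p, c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.3, altloc = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 9, 0, 0, occ = 0.7, altloc = "B"),
    pdb_atom_line(4, "C", "ALA", "A", 1, 2, 0, 0)))
  s <- read_pdb(p)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9)
})

test_that("segment files parse per the line grammar", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("helix1 A:10-25", "rb1 A:1-40,A:80-120", "# comment", ""), p)
  segs <- read_segments(p)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$label, "helix1")
  expect_equal(nrow(segs[[1]]$ranges), 1)
  expect_equal(nrow(segs[[2]]$ranges), 2)
  expect_equal(segs[[2]]$ranges$start, c(1, 80))

  writeLines("bad A:25-10", p)
  expect_error(read_segments(p), "start > end|line 1")
  writeLines("nonsense", p)
  expect_error(read_segments(p), "line 1")
})

test_that("segment round trip is lossless", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("helix1 A:10-25", "rb1 A:1-40,B:80-120"), p)
  segs <- read_segments(p)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_segments(segs, p2)
  expect_identical(readLines(p2), readLines(p))
})

test_that("segments resolve against structures and reject empty matches", {
  s <- make_toy_structure(10, "helix")
  seg <- segment_selection(data.frame(chain = "A", start = 2, end = 4), "mid")
  expect_equal(sum(resolve_segment(s, seg)), 3 * 5)
  expect_equal(nrow(segment_structure(s, seg)$atoms), 15)
  bad <- segment_selection(data.frame(chain = "B", start = 2, end = 4), "none")
  expect_error(resolve_segment(s, bad), "matches no residue")
})

test_that("rigid transforms behave as an exact group action", {
  s <- make_toy_structure(8, "helix")
  # identity
  t0 <- fit_transform(fit_id = "id")
  expect_equal(coords_matrix(apply_transform(s, t0)), coords_matrix(s))
  # 180 degrees about z through the centroid fixes the centroid
  com <- center_of_mass(s)
  t180 <- fit_transform(rotation_about_axis(c(0, 0, 1), 180), pivot = com)
  expect_equal(center_of_mass(apply_transform(s, t180)), com, tolerance = 1e-9)
  # random transform composed with its inverse restores coordinates
  set.seed(11)
  for (i in 1:5) {
    tr <- fit_transform(random_rotation(), stats::rnorm(3, sd = 5),
                        pivot = stats::rnorm(3, sd = 3))
    back <- apply_transform(apply_transform(s, tr), invert_transform(tr))
    expect_equal(coords_matrix(back), coords_matrix(s), tolerance = 1e-9)
  }
})

test_that("rigid transforms preserve pairwise interatomic distances", {
  s <- make_toy_structure(6, "helix")
  set.seed(21)
  d0 <- dist(coords_matrix(s))
  for (i in 1:5) {
    tr <- fit_transform(random_rotation(), stats::rnorm(3, sd = 8),
                        pivot = stats::rnorm(3))
    expect_equal(as.numeric(dist(coords_matrix(apply_transform(s, tr)))),
                 as.numeric(d0), tolerance = 1e-9)
  }
})

test_that("improper or skew rotation matrices are rejected", {
  expect_error(fit_transform(diag(c(1, 1, -1))), "det")
  expect_error(fit_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("calpha_rmsd matches direct computation and its metric properties", {
  a <- make_toy_structure(10, "helix")
  expect_equal(calpha_rmsd(a, a), 0)
  b <- a
  b$atoms$x <- b$atoms$x + 3
  b$atoms$y <- b$atoms$y + 4
  expect_equal(calpha_rmsd(a, b), 5)
  expect_equal(calpha_rmsd(b, a), 5)

  # naive per-atom loop oracle on a random pair
  set.seed(31)
  c_ <- apply_transform(a, fit_transform(random_rotation(), stats::rnorm(3),
                                         pivot = center_of_mass(a)))
  ca_a <- a$atoms[a$atoms$name == "CA", c("x", "y", "z")]
  ca_c <- c_$atoms[c_$atoms$name == "CA", c("x", "y", "z")]
  acc <- 0
  for (i in seq_len(nrow(ca_a)))
    acc <- acc + sum((as.numeric(ca_a[i, ]) - as.numeric(ca_c[i, ]))^2)
  expect_equal(calpha_rmsd(a, c_), sqrt(acc / nrow(ca_a)), tolerance = 1e-12)
})

test_that("calpha_rmsd is invariant under a joint rigid transform", {
  a <- make_toy_structure(9, "helix")
  set.seed(41)
  b <- apply_transform(a, fit_transform(random_rotation(), stats::rnorm(3, sd = 4),
                                        pivot = center_of_mass(a)))
  r0 <- calpha_rmsd(a, b)
  for (i in 1:100) {
    tr <- fit_transform(random_rotation(), stats::rnorm(3, sd = 10),
                        pivot = stats::rnorm(3, sd = 5))
    r1 <- calpha_rmsd(apply_transform(a, tr), apply_transform(b, tr))
    expect_lt(abs(r1 - r0), 1e-9)
  }
})

test_that("mismatched C-alpha sets raise an informative error", {
  a <- make_toy_structure(6, "helix")
  b <- make_toy_structure(7, "helix")
  expect_error(calpha_rmsd(a, b), "C-alpha sets differ")
})

test_that("centre of mass is the mass-weighted mean", {
  at <- data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
                   res_name = "LIG", chain = "A", res_seq = 1:2, ins = "",
                   x = c(0, 2), y = 0, z = 0, mass = c(1, 1))
  expect_equal(center_of_mass(atomic_structure(at)), c(1, 0, 0))
  at1 <- at[1, ]
  at1$x <- 5; at1$y <- -2; at1$z <- 0.5
  expect_equal(center_of_mass(atomic_structure(at1)), c(5, -2, 0.5))
  at$mass <- c(2, 1); at$x <- c(0, 3)
  expect_equal(center_of_mass(atomic_structure(at)), c(1, 0, 0))
})
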