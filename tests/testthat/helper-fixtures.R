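# Shared fixture builders for the test suite (everything generated in
# code; nothing read from disk).

# snap doubles to their float32 representation, the native precision of
# mode-2 MRC data
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
          n = length(x), size = 4L)
}

random_map <- function(dims = c(8, 8, 8), seed = 1, apix = 1,
                       origin = c(0, 0, 0), quantize = FALSE) {
  set.seed(seed)
  v <- stats::runif(prod(dims))
  if (quantize) v <- float32(v)
  density_map(array(v, dim = dims), apix = apix, origin = origin)
}

# smooth blob map: Gaussian bump centred mid-grid (has well-defined
# surface normals everywhere on its envelope)
blob_map <- function(dims = c(12, 12, 12), centre = NULL, sigma = 2.5,
                     apix = 1, origin = c(0, 0, 0)) {
  if (is.null(centre)) centre <- (dims + 1) / 2
  g <- array(0, dims)
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    g[i, j, k] <- exp(-sum((c(i, j, k) - centre)^2) / (2 * sigma^2))
  }
  density_map(g, apix = apix, origin = origin)
}

# linear ramp along the x axis
ramp_map <- function(dims = c(8, 6, 6), apix = 1, slope = 1, descending = FALSE) {
  i <- if (descending) rev(seq_len(dims[1])) else seq_len(dims[1])
  g <- array(rep(slope * i, times = prod(dims[2:3])), dim = dims)
  density_map(g, apix = apix)
}

# minimal hand-written PDB text (fixed-width) for parser edge cases
write_mini_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1, type = "ATOM", altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, namef, altloc, resname, chain, resseq, x, y, z,
          occ, 0, element)
}

# independent MRC writer used to test axis-order normalization: stores the
# same real-space grid with an arbitrary axis correspondence
write_mrc_permuted <- function(map, path, axes = c(2, 3, 1)) {
  arr <- aperm(map$grid, axes)       # storage: cols along crystal axes[1], ...
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  dcry <- dim(map$grid)
  wi(dim(arr)); wi(2L); wi(c(0L, 0L, 0L)); wi(dcry)
  wf(dcry * map$apix); wf(c(90, 90, 90))
  wi(axes)
  wf(c(min(arr), max(arr), mean(arr)))
  wi(1L); wi(0L); wi(integer(25L))
  wf(map$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(stats::sd(arr)); wi(0L)
  writeBin(raw(800L), con)
  wf(as.numeric(arr))
  path
}

# random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
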