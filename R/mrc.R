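#' Read a CCP4/MRC density map
#'
#' Parses the MRC 2014 format (1024-byte header followed by the voxel
#' block). Data modes 0 (signed 8-bit), 1 (signed 16-bit) and 2 (32-bit
#' float) are accepted; the machine stamp is honoured so big-endian files
#' read correctly. The axis-correspondence words (MAPC/MAPR/MAPS) are
#' applied on read, so the returned grid is always in canonical x-fastest
#' order whatever the file's storage order. The map origin is taken from
#' the MRC 2014 ORIGIN record when set, otherwise from the CCP4-style
#' NXSTART/NYSTART/NZSTART words times the voxel size.
#'
#' Only isotropic voxels are supported; files whose cell implies different
#' spacings along the axes are rejected, as every downstream score assumes
#' a single `apix`.
#'
#' @param path path to an MRC/CCP4 map file.
#' @return A [density_map()].
#' @seealso [write_mrc()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (is.na(size) || size < 1024)
    stop("MRC format error: file is shorter than the 1024-byte header", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)

  endian <- mrc_detect_endian(hdr)
  word_int <- function(i, n = 1L)
    readBin(hdr[(4L * (i - 1L) + 1L):(4L * (i + n - 1L))], "integer",
            n = n, size = 4L, endian = endian)
  word_flt <- function(i, n = 1L)
    readBin(hdr[(4L * (i - 1L) + 1L):(4L * (i + n - 1L))], "double",
            n = n, size = 4L, endian = endian)

  nxyz <- word_int(1L, 3L)           # columns, rows, sections
  mode <- word_int(4L)
  nstart <- word_int(5L, 3L)
  mxyz <- word_int(8L, 3L)           # sampling along cell x, y, z
  cella <- word_flt(11L, 3L)
  mapcrs <- word_int(17L, 3L)        # crystal axis of cols, rows, sections
  nsymbt <- word_int(24L)
  origin_rec <- word_flt(50L, 3L)

  if (!(mode %in% 0:2))
    stop("MRC format error: unsupported MODE ", mode,
         " (modes 0, 1 and 2 are supported)", call. = FALSE)
  if (any(nxyz < 1L) || any(nxyz > 1e5))
    stop("MRC format error: implausible NX/NY/NZ (", paste(nxyz, collapse = ","),
         ")", call. = FALSE)
  if (!identical(sort(mapcrs), 1:3))
    stop("MRC format error: MAPC/MAPR/MAPS must be a permutation of 1,2,3, got ",
         paste(mapcrs, collapse = ","), call. = FALSE)
  if (nsymbt < 0 || size < 1024 + nsymbt)
    stop("MRC format error: bad NSYMBT", call. = FALSE)

  mxyz[mxyz <= 0L] <- nxyz[match(1:3, mapcrs)][mxyz <= 0L]
  apix3 <- cella / mxyz
  if (any(!is.finite(apix3)) || any(apix3 <= 0))
    stop("MRC format error: non-positive cell dimensions CELLA", call. = FALSE)
  if (diff(range(apix3)) > 1e-3 * mean(apix3))
    stop("anisotropic voxels are not supported (apix ",
         paste(sprintf("%.4f", apix3), collapse = ", "),
         "); resample the map to a cubic grid first", call. = FALSE)
  apix <- mean(apix3)

  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  nvox <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = TRUE, endian = endian)),
    "2" = readBin(con, "double", n = nvox, size = 4L, endian = endian))
  if (length(vals) < nvox)
    stop("MRC format error: truncated data block (expected ", nvox,
         " voxels, got ", length(vals), ")", call. = FALSE)

  arr <- array(vals, dim = nxyz)            # storage order: col, row, section
  perm <- match(1:3, mapcrs)                # -> canonical x, y, z
  arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]

  origin <- if (any(abs(origin_rec) > 0)) origin_rec else nstart_xyz * apix
  density_map(arr, apix = apix, origin = origin,
              label = paste0("read from ", basename(path)))
}

mrc_detect_endian <- function(hdr) {
  stamp <- as.integer(hdr[213:214])
  if (stamp[1] == 0x44) return("little")
  if (stamp[1] == 0x11) return("big")
  # No valid stamp (some writers leave it zero): pick the byte order under
  # which the MODE word is sane.
  mode_le <- readBin(hdr[13:16], "integer", size = 4L, endian = "little")
  if (mode_le %in% 0:16) "little" else "big"
}

#' Write a CCP4/MRC density map
#'
#' Writes mode-2 (32-bit float) little-endian MRC 2014 files with canonical
#' axis order (MAPC,MAPR,MAPS = 1,2,3), the map origin in the ORIGIN
#' record, and header statistics (DMIN/DMAX/DMEAN/RMS) filled in. Reading
#' the file back with [read_mrc()] reproduces the grid bit-exactly for
#' float32-valued data and `apix`/`origin` to float precision.
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(map, path) {
  stopifnot_map(map)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  d <- dim(map$grid)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(d)                      # NX NY NZ
  wi(2L)                     # MODE 2 = float32
  wi(c(0L, 0L, 0L))          # NXSTART NYSTART NZSTART
  wi(d)                      # MX MY MZ
  wf(d * map$apix)           # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(1:3)                    # MAPC MAPR MAPS (canonical)
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))  # DMIN DMAX DMEAN
  wi(1L)                     # ISPG
  wi(0L)                     # NSYMBT
  wi(integer(25L))           # EXTRA, words 25-49
  wf(map$origin)             # ORIGIN x y z (words 50-52, MRC 2014)
  writeBin(charToRaw("MAP "), con)            # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp, little
  wf(stats::sd(map$grid))    # RMS
  wi(1L)                     # NLABL
  lab <- substr(paste0(map$label, strrep(" ", 80L)), 1L, 80L)
  writeBin(charToRaw(lab), con)
  writeBin(raw(800L - 80L), con)              # remaining label slots
  wf(as.numeric(map$grid))   # voxel block, x fastest
  invisible(path)
}
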