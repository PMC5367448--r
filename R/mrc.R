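# MRC2014 map I/O.
#
# The package writes mode-2 (32-bit float) volumes with x the fastest
# axis (mapc/mapr/maps = 1/2/3), the voxel size encoded through the cell
# dimensions, and the physical origin recorded both in the ORIGIN fields
# and (as voxel multiples) in nstart, for maximum reader compatibility.
# Little-endian throughout (machine stamp 0x44 0x44 0x00 0x00).

MRC_HEADER_BYTES <- 1024L

#' Write a density map as an MRC2014 file
#'
#' @param map A `density_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  g <- map$grid
  nstart <- round(map$origin / map$voxel)
  wi(d)                          # nx ny nz
  wi(2L)                         # mode 2: float32
  wi(nstart)                     # nxstart nystart nzstart
  wi(d)                          # mx my mz
  wf(d * map$voxel)              # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1L, 2L, 3L))              # mapc mapr maps
  wf(c(min(g), max(g), mean(g))) # dmin dmax dmean
  wi(1L)                         # ispg (volume)
  wi(0L)                         # nsymbt
  wi(rep(0L, 25))                # extra
  wf(map$origin)                 # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst
  wf(sd(as.numeric(g)))          # rms
  wi(1L)                         # nlabl
  lab <- "thinfilament::write_mrc"
  lab <- substr(paste0(lab, strrep(" ", 80)), 1, 80)
  writeBin(charToRaw(lab), con)
  writeBin(raw(800 - 80), con)   # remaining label slots
  writeBin(as.numeric(g), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 map file
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32), x-fastest axis
#' ordering.  The physical origin is taken from the ORIGIN record if
#' non-zero, otherwise from nstart.
#'
#' @param path Path to an MRC file.
#' @return A `density_map`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  nstart <- ri(3)
  m <- ri(3)
  cella <- rf(3)
  rf(3)            # cellb
  mapcrs <- ri(3)
  rf(3)            # dmin dmax dmean
  ri(1); ri(1)     # ispg nsymbt
  ri(25)           # extra
  origin <- rf(3)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "MAP ")
    stopf("invalid-argument: %s is not an MRC2014 file (magic '%s')", path, magic)
  readBin(con, "raw", 4)  # machst (little-endian assumed)
  rf(1)                   # rms
  ri(1)                   # nlabl
  readBin(con, "raw", 800)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stopf("invalid-argument: only x-fastest axis order is supported")
  voxel <- cella[1] / m[1]
  vz <- cella / m
  if (max(abs(vz - voxel)) > 1e-4 * voxel)
    stopf("invalid-argument: anisotropic voxels are not supported")
  n <- prod(d)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stopf("invalid-argument: unsupported MRC mode %d", mode))
  if (length(vals) != n) stopf("invalid-argument: truncated MRC data in %s", path)
  org <- if (any(origin != 0)) origin else nstart * voxel
  density_map(array(vals, dim = d), voxel, org)
}
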