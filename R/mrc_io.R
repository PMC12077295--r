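#' Read an MRC/CCP4 density map
#'
#' Parses the 1024-byte MRC2014 header and the data block (modes 0, 1 and 2),
#' handling both little- and big-endian files via the machine-stamp. The axis
#' order is normalized to (x, y, z) regardless of the file's `mapc/mapr/maps`
#' permutation, so node `(i, j, k)` (0-based) of the returned grid is at
#' `origin + c(i, j, k) * voxel` Angstrom. The `ORIGIN` record is preferred
#' when it is non-zero; otherwise the origin is derived from the start indices
#' (`nxstart/nystart/nzstart`), matching common visualization-tool behavior.
#'
#' @param path Path to an MRC/CCP4 map file.
#' @return A [density_grid()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 1024L) stop("truncated MRC file (header incomplete): ", path)

  machst <- raw[213:216]
  endian <- if (machst[1] == as.raw(0x11)) "big" else "little"
  geti <- function(words) readBin(raw[(4 * (words[1] - 1) + 1):(4 * words[length(words)])],
                                  "integer", n = length(words), size = 4, endian = endian)
  getf <- function(words) readBin(raw[(4 * (words[1] - 1) + 1):(4 * words[length(words)])],
                                  "numeric", n = length(words), size = 4, endian = endian)

  n_crs <- geti(1:3)
  mode <- geti(4)
  if (any(n_crs <= 0) || any(n_crs > 1e5) || !(mode %in% c(0L, 1L, 2L))) {
    # machine stamp unreliable in some writers; retry with the other endianness
    endian <- if (endian == "little") "big" else "little"
    n_crs <- geti(1:3)
    mode <- geti(4)
    if (any(n_crs <= 0) || !(mode %in% c(0L, 1L, 2L)))
      stop("unreadable MRC header (bad dimensions or unsupported mode): ", path)
  }
  nstart <- geti(5:7)
  m_xyz <- geti(8:10)
  cella <- getf(11:13)
  cellb <- getf(14:16)
  mapcrs <- geti(17:19)
  nsymbt <- geti(24)
  orig <- getf(50:52)

  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal cell (angles != 90 degrees) is not supported")
  if (!identical(sort(mapcrs), 1:3))
    stop("invalid axis correspondence (mapc/mapr/maps) in MRC header")
  if (any(m_xyz <= 0) || any(cella <= 0))
    stop("invalid sampling/cell fields in MRC header")

  nval <- prod(n_crs)
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  data_off <- 1024L + nsymbt
  if (length(raw) < data_off + nval * bytes_per)
    stop("truncated MRC file (data block incomplete): ", path)
  body <- raw[(data_off + 1):(data_off + nval * bytes_per)]
  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(body, "integer", n = nval, size = 1, signed = TRUE)),
    `1` = as.numeric(readBin(body, "integer", n = nval, size = 2, signed = TRUE,
                             endian = endian)),
    `2` = readBin(body, "numeric", n = nval, size = 4, endian = endian))
  arr <- array(vals, n_crs)

  # reorder (column, row, section) -> (x, y, z)
  perm <- order(mapcrs)
  arr <- aperm(arr, perm)
  voxel <- cella / m_xyz
  if (all(abs(orig) < 1e-6)) {
    start_xyz <- nstart[perm]
    origin <- start_xyz * voxel
  } else {
    origin <- orig
  }
  density_grid(arr, voxel, origin)
}

#' Write an MRC/CCP4 density map
#'
#' Writes a [density_grid()] as a little-endian mode-2 (float32) MRC2014 file
#' with canonical axis order (`mapc/mapr/maps = 1/2/3`), the grid origin stored
#' in the `ORIGIN` record, and density statistics filled in.
#'
#' @param grid A [density_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- grid$values
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2: float32
  wi(c(0L, 0L, 0L))           # nstart
  wi(d)                       # mx my mz
  wf(d * grid$voxel)          # cella
  wf(c(90, 90, 90))           # cellb
  wi(1:3)                     # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))
  wi(c(1L, 0L))               # ispg, nsymbt
  wi(rep(0L, 25))             # extra words 25-49
  wf(grid$origin)             # ORIGIN record, words 50-52
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(as.numeric(v)))
  wi(1L)                      # nlabl
  lab <- "Created by cryoab"
  writeChar(formatC(lab, width = -80), con, nchars = 80, eos = NULL)
  writeBin(raw(800 - 80), con)
  wf(as.numeric(v))
  invisible(path)
}
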