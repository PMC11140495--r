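#' Read an MRC volume
#'
#' Minimal MRC2014 reader for the modes the pipeline touches: 0 (int8),
#' 1 (int16), 2 (float32) and 6 (uint16). Data are returned as a numeric
#' array indexed `[x, y, z]` with x fastest, matching the on-disk order; the
#' voxel size is recovered from the cell dimensions.
#'
#' @param path Path to an MRC file.
#' @return A list with `data` (3D array) and `voxel_size` (Angstrom/voxel).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", 10L, size = 4L, endian = "little")
  nx <- hdr_i[1L]; ny <- hdr_i[2L]; nz <- hdr_i[3L]
  mode <- hdr_i[4L]
  cella <- {
    seek(con, 40L)
    readBin(con, "numeric", 3L, size = 4L, endian = "little")
  }
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 1024L + nsymbt)
  n <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode)
  )
  voxel <- if (nx > 0 && cella[1L] > 0) cella[1L] / nx else 1
  list(data = array(data, dim = c(nx, ny, nz)), voxel_size = voxel)
}

#' Write an MRC volume (mode 2, 32-bit float)
#'
#' Deterministic writer: identical input produces a byte-identical file (no
#' timestamps). The voxel size is stored in the cell dimensions, and voxel
#' data roundtrip exactly through [read_mrc()].
#'
#' @param vol Numeric 3D array.
#' @param path Output path.
#' @param voxel_size Voxel size in Angstrom/voxel.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path, voxel_size = 1) {
  stopifnot(length(dim(vol)) == 3L)
  dims <- dim(vol)
  v <- as.numeric(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(dims)                     # nx ny nz
  wi(2L)                       # mode 2: float32
  wi(c(0L, 0L, 0L))            # nxstart
  wi(dims)                     # mx my mz
  wf(dims * voxel_size)        # cella
  wf(c(90, 90, 90))            # cellb
  wi(c(1L, 2L, 3L))            # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))
  wi(1L)                       # ispg: volume
  wi(0L)                       # nsymbt
  wi(integer(25L))             # extra
  wf(c(0, 0, 0))               # origin
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian machst
  wf(stats::sd(v) * sqrt((length(v) - 1) / length(v)))
  wi(0L)                       # nlabl
  writeBin(raw(800L), con)     # labels
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}
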