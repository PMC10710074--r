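#' Read an MRC/MRCS image or stack
#'
#' Minimal MRC2014 reader for the modes used by this package: mode 0 (int8),
#' mode 1 (int16), mode 2 (float32) and mode 6 (uint16). Returns the data
#' with the x axis fastest, matching the on-disk layout: a 2D image comes
#' back as a `micrograph` (matrix indexed `[x, y]`), a stack as a 3D array
#' `[x, y, section]` with the pixel size attached.
#'
#' @param path Path to an `.mrc`/`.mrcs` file.
#' @return A [micrograph()] for single images, otherwise a 3D array with
#'   attribute `pixel_a`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("MRC file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]; mode <- hdr_ints[4]
  mx <- hdr_ints[8]; my <- hdr_ints[9]; mz <- hdr_ints[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (nx <= 0 || ny <= 0 || nz <= 0) stop_data("Corrupt MRC header (non-positive dimensions).")
  pixel <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    stop_data(sprintf("Unsupported MRC mode %d.", mode))
  )
  if (length(data) < n) stop_data("Truncated MRC data block.")
  if (nz == 1L) {
    micrograph(matrix(data, nrow = nx, ncol = ny), pixel_a = pixel)
  } else {
    structure(array(data, dim = c(nx, ny, nz)), pixel_a = pixel)
  }
}

#' Write an MRC/MRCS image or stack
#'
#' Writes a matrix (single image) or 3D array (stack/movie) as MRC2014,
#' x axis fastest, little-endian, with the pixel size recorded in the cell
#' dimensions. Mode 2 (float32) is the default; mode 1 (int16) suits
#' integer counted movies.
#'
#' @param data A numeric matrix `[x, y]`, 3D array `[x, y, section]`,
#'   [micrograph()], or `counted_movie`.
#' @param path Output path.
#' @param pixel_a Pixel size in Angstrom; taken from the object's attribute
#'   when present.
#' @param mode MRC data mode: 2 (float32, default) or 1 (int16).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, pixel_a = NULL, mode = 2) {
  if (inherits(data, "micrograph")) {
    if (is.null(pixel_a)) pixel_a <- attr(data, "pixel_a")
    data <- unclass(data)
  }
  if (is.null(pixel_a)) pixel_a <- attr(data, "pixel_a")
  if (is.null(pixel_a)) pixel_a <- 1
  d <- dim(data)
  if (length(d) == 2) d <- c(d, 1L)
  if (length(d) != 3) stop_invalid("`data` must be a 2D matrix or 3D array.")
  if (!mode %in% c(1, 2)) stop_invalid("Only MRC modes 1 (int16) and 2 (float32) are written.")
  vals <- as.vector(data)
  if (mode == 1 && any(abs(vals) > 32767)) {
    stop_data("Values exceed int16 range; write with mode = 2.")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wint(c(d[1], d[2], d[3], mode))     # nx ny nz mode
  wint(c(0, 0, 0))                    # nxstart nystart nzstart
  wint(c(d[1], d[2], d[3]))           # mx my mz
  wflt(c(d * pixel_a))                # cella
  wflt(c(90, 90, 90))                 # cellb
  wint(c(1, 2, 3))                    # mapc mapr maps
  wflt(c(min(vals), max(vals), mean(vals)))  # dmin dmax dmean
  wint(c(0, 0))                       # ispg nsymbt
  writeBin(raw(100), con)             # extra (words 26-49)
  wflt(c(0, 0, 0))                    # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wflt(stats::sd(vals))               # rms
  wint(0)                             # nlabl
  writeBin(raw(800), con)             # labels
  if (mode == 1) {
    writeBin(as.integer(round(vals)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  invisible(path)
}
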