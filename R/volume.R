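#' 3D density volume
#'
#' A `tomo_volume` holds a 3D scalar grid together with its (isotropic) voxel
#' size in nanometres and the position, in nm, of the centre of voxel
#' `[1, 1, 1]`.  Array dimension 1 is x, dimension 2 is y, dimension 3 is z;
#' z is the beam direction throughout the package.
#'
#' @param data 3D numeric array of finite values.
#' @param voxel_size voxel edge length in nm (single positive number).
#' @param origin nm position of the centre of voxel `[1,1,1]` (length-3).
#' @return An object of class `tomo_volume`.
#' @export
volume <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (nm)")
  if (any(!is.finite(data))) stop("volume data must be finite")
  if (length(origin) != 3L) stop("origin must be length 3")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "tomo_volume")
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels, %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  origin (nm): %.3g %.3g %.3g   range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.tomo_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "tomo_volume")

#' Physical extent of a volume
#'
#' @param v a `tomo_volume`.
#' @return length-3 vector, nm, spanned by the grid (`dim * voxel_size`).
#' @export
volume_extent <- function(v) dim(v$data) * v$voxel_size

#' Nm coordinates of all voxel centres along each axis
#' @noRd
axis_coords <- function(v, axis) {
  v$origin[axis] + (seq_len(dim(v$data)[axis]) - 1) * v$voxel_size
}

# ---- MRC2014 I/O -----------------------------------------------------------
# Minimal MRC2014 mode-2 (float32) reader/writer, little-endian.  Cell
# dimensions are stored in Angstrom per the format convention; the package
# works in nm, so values are multiplied/divided by 10 at this boundary.

#' Read an MRC2014 volume
#'
#' Reads a mode 0/1/2 MRC file into a [volume()].  Only isotropic voxel
#' sizes are accepted; the MRC origin record (Angstrom) is converted to nm.
#'
#' @param path file path.
#' @return A `tomo_volume`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]; mode <- ints1[4]
  mx <- ints1[8]; my <- ints1[9]; mz <- ints1[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # cellb
  readBin(con, "integer", n = 3, size = 4, endian = "little")  # mapc/r/s
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/max/mean
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ispg, nsymbt
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra 25..49
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # machst
  readBin(con, "numeric", n = 1, size = 4, endian = "little")  # rms
  nlabl <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readChar(con, 800, useBytes = TRUE)
  if (!identical(substr(map, 1, 3), "MAP"))
    stop("malformed MRC header: MAP marker missing")
  if (nx < 1 || ny < 1 || nz < 1)
    stop("malformed MRC header: non-positive dimensions (nx/ny/nz)")
  if (mx < 1 || my < 1 || mz < 1)
    stop("malformed MRC header: non-positive sampling (mx/my/mz)")
  vs <- cella / c(mx, my, mz) / 10  # Angstrom -> nm
  if (any(vs <= 0)) stop("malformed MRC header: non-positive cell (cella)")
  if (diff(range(vs)) > 1e-4 * vs[1])
    stop("isotropic required: anisotropic voxel size in MRC header")
  n <- nx * ny * nz
  dat <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("malformed MRC header: unsupported mode ", mode))
  if (length(dat) != n) stop("MRC data truncated")
  volume(array(as.numeric(dat), dim = c(nx, ny, nz)),
         voxel_size = vs[1], origin = orig / 10)
}

#' Write a volume as MRC2014 (mode 2 float)
#'
#' @param v a `tomo_volume`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(v, path) {
  stopifnot(is_volume(v))
  d <- dim(v$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(d, 2L, 0L, 0L, 0L, d))                  # nx..nzstart, mx my mz
  wf(d * v$voxel_size * 10)                    # cella, Angstrom
  wf(c(90, 90, 90))                            # cellb
  wi(c(1L, 2L, 3L))                            # mapc mapr maps
  wf(c(min(v$data), max(v$data), mean(v$data)))
  wi(c(1L, 0L))                                # ispg, nsymbt
  wi(rep(0L, 25))                              # extra
  wf(v$origin * 10)                            # origin, Angstrom
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v$data))
  wi(1L)
  lab <- formatC("catmtools", width = -80)
  writeChar(paste0(lab, strrep(" ", 80 * 9)), con, nchars = 800, eos = NULL)
  writeBin(as.numeric(v$data), con, size = 4, endian = "little")
  invisible(path)
}
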