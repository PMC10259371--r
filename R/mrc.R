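#' Write a map or image stack in MRC2014 format
#'
#' Mode-2 (float32) little-endian MRC2014 with the voxel size recorded in
#' the cell dimensions.  A 3D array is written as a volume; a matrix or a
#' 3D array flagged as a stack is written as an image stack (one section
#' per image).
#'
#' @param x A `density_map`, a `projection_set`, a numeric matrix (single
#'   image) or a 3D array.
#' @param path Output path.
#' @param voxel_size Angstrom per voxel/pixel; taken from `x` when it
#'   carries one.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_size = NULL) {
  is_stack <- FALSE
  if (inherits(x, "density_map")) {
    voxel_size <- x$voxel_size; arr <- x$voxels
  } else if (inherits(x, "projection_set")) {
    voxel_size <- x$pixel_size; arr <- x$images; is_stack <- TRUE
  } else if (is.matrix(x)) {
    arr <- array(x, dim = c(dim(x), 1L)); is_stack <- TRUE
  } else if (is.array(x) && length(dim(x)) == 3) {
    arr <- x
  } else stop_invalid("cannot write object of class %s as MRC", class(x)[1])
  if (is.null(voxel_size)) voxel_size <- 1
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  vals <- as.numeric(arr)
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode 2 = float32
  wi(c(0, 0, 0))                          # nxstart nystart nzstart
  wi(d)                                   # mx my mz
  wf(d * voxel_size)                      # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1, 2, 3))                          # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals))) # dmin dmax dmean
  wi(if (is_stack) 0 else 1)              # ispg: 0 for stacks, 1 volume
  wi(0)                                   # nsymbt
  wi(rep(0, 25))                          # extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(vals))                     # rms
  wi(0)                                   # nlabl
  writeBin(raw(800), con)                 # empty labels
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 file
#'
#' Supports mode 2 (float32) volumes and image stacks as written by
#' [write_mrc()].
#'
#' @param path Path to an MRC file.
#' @return List with `data` (3D array), `voxel_size`, `is_stack`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop_invalid("unsupported MRC mode %d (need 2)", mode)
  ri(3)                # starts
  mx <- ri(3)
  cella <- rf(3)
  rf(3)                # cellb
  ri(3)                # axis order
  rf(3)                # dmin dmax dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  if (nsymbt != 0) stop_invalid("extended headers not supported")
  seek(con, 1024)
  n <- prod(d)
  vals <- rf(n)
  if (length(vals) != n) stop_invalid("truncated MRC data section")
  list(data = array(vals, dim = d),
       voxel_size = cella[1] / mx[1],
       is_stack = ispg == 0)
}
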