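# MRC/CCP4 2014 volume I/O.
#
# Maps are always held in memory in canonical X,Y,Z axis order with the
# first array index fastest, matching the MRC column-fastest layout when
# MAPC,MAPR,MAPS = 1,2,3.  Files with permuted axis order are normalized
# on read; files are always written unpermuted.

.mrc_modes <- c("0" = "int8", "1" = "int16", "2" = "float32", "6" = "uint16")

#' Read an MRC/CCP4 density map
#'
#' Reads a volume in MRC/CCP4 2014 format.  The voxel spacing is taken
#' from the header cell dimensions divided by the grid sampling
#' (`CELLA / MX,MY,MZ`); the origin from the `ORIGIN` header words if any
#' of them is nonzero, otherwise from `NXSTART,NYSTART,NZSTART` times the
#' spacing (the two dialects found in deposited maps).  On-disk axis
#' permutations (`MAPC,MAPR,MAPS`) are normalized so the returned values
#' array is always in X,Y,Z order.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_grid()].
#' @seealso [write_map()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_flt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")

  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]
  mode <- hdr_int[4]
  if (is.na(mode) || !(as.character(mode) %in% names(.mrc_modes))) {
    stop("unsupported MRC data mode ", mode, " (not a real/integer volume)")
  }
  if (any(c(nc, nr, ns) <= 0) || any(c(nc, nr, ns) > 1e6)) {
    stop("corrupt MRC header: grid size ", nc, " x ", nr, " x ", ns)
  }
  starts <- hdr_int[5:7]
  m_xyz <- hdr_int[8:10]
  cella <- hdr_flt[11:13]
  axes <- hdr_int[17:19]                  # MAPC, MAPR, MAPS
  if (!identical(sort(axes), 1:3)) {
    stop("corrupt MRC header: MAPC,MAPR,MAPS = ",
         paste(axes, collapse = ","))
  }
  nsymbt <- hdr_int[24]
  orig <- hdr_flt[50:52]

  if (any(m_xyz <= 0)) m_xyz <- c(nc, nr, ns)[order(axes)]
  spacing <- ifelse(cella > 0, cella / m_xyz, 1)

  seek(con, 1024 + max(0, nsymbt))
  nvox <- as.numeric(nc) * nr * ns
  what <- .mrc_modes[[as.character(mode)]]
  data <- switch(what,
    float32 = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    int8    = readBin(con, "integer", n = nvox, size = 1, signed = TRUE,
                      endian = "little"),
    int16   = readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                      endian = "little"),
    uint16  = readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                      endian = "little"))
  if (length(data) != nvox) stop("truncated MRC data section in ", path)
  arr <- array(as.numeric(data), c(nc, nr, ns))
  # file order (col, row, sec) runs along crystal axes `axes`;
  # reorder so index 1,2,3 run along X,Y,Z
  if (!identical(axes, 1:3)) arr <- aperm(arr, order(axes))

  start_xyz <- integer(3)
  start_xyz[axes] <- starts
  origin <- if (any(orig != 0)) orig else start_xyz * spacing
  if (any(!is.finite(arr))) stop("map contains non-finite voxel values")
  density_grid(arr, origin = origin, spacing = spacing)
}

#' Write a density map in MRC/CCP4 2014 format
#'
#' Volumes are written as 32-bit floats in canonical X,Y,Z axis order
#' (`MAPC,MAPR,MAPS = 1,2,3`) with the grid origin stored in the `ORIGIN`
#' header words and header statistics (min/max/mean/rms) recomputed from
#' the data.  Round-trips through [read_map()] up to float32 precision.
#'
#' @param grid a [density_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot_grid(grid)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write map: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  d <- dim(grid$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  v <- grid$values
  wi(d)                                   # NX, NY, NZ (cols, rows, secs)
  wi(2)                                   # MODE 2: float32
  wi(c(0, 0, 0))                          # NXSTART..
  wi(d)                                   # MX, MY, MZ
  wf(d * grid$spacing)                    # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(1:3)                                 # MAPC, MAPR, MAPS
  wf(c(min(v), max(v), mean(v)))          # DMIN, DMAX, DMEAN
  wi(c(1, 0))                             # ISPG, NSYMBT
  wi(rep(0L, 25))                         # EXTRA
  wf(grid$origin)                         # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sqrt(mean((v - mean(v))^2)))         # RMS
  wi(1)                                   # NLABL
  lab <- sprintf("%-80s", "mlfit")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 720), collapse = ""), con, nchars = 720,
            eos = NULL)
  wf(v)
  invisible(path)
}
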