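# Minimal MRC/CCP4 volume I/O: mode 2 (float32), little-endian, orthogonal
# cells with isotropic voxels. Axis order (MAPC/MAPR/MAPS) is normalized to
# x-fastest on read.

#' Write a map to MRC (mode 2)
#'
#' @param map a `potential_map` (a `difference_map`'s sigma-scaled data is
#'   written as-is).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                    # NX NY NZ (columns, rows, sections)
  wi(2)                    # MODE 2: float32
  wi(c(0, 0, 0))           # N*START
  wi(d)                    # MX MY MZ
  wf(d * map$voxel)        # CELLA
  wf(c(90, 90, 90))        # CELLB
  wi(c(1, 2, 3))           # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(1)                    # ISPG
  wi(0)                    # NSYMBT
  wi(rep(0, 2))            # EXTRA words 26-27
  wi(20140)                # NVERSION
  wi(rep(0, 22))           # EXTRA words 29-49 (crystallographic unused)
  wf(map$origin)           # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # MACHST little-endian
  wf(map_sigma(map))       # RMS
  wi(0)                    # NLABL
  writeBin(raw(800), con)  # labels
  writeBin(as.numeric(map$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a map from MRC (mode 2)
#'
#' Supports mode 2 (float32) volumes with orthogonal cells and isotropic
#' voxels; permuted axis orders are normalized to the internal x-fastest
#' convention.
#'
#' @param path MRC/CCP4 file path.
#' @return a `potential_map`.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nf <- ri(3)              # file-order dims (columns, rows, sections)
  mode <- ri(1)
  nstart <- ri(3)
  m <- ri(3)               # MX MY MZ (cell-axis order)
  cella <- rf(3)
  cellb <- rf(3)
  maps <- ri(3)            # MAPC MAPR MAPS
  stats3 <- rf(3)
  ri(2)                    # ISPG, NSYMBT
  nsymbt <- 0
  ri(25)                   # EXTRA
  origin <- rf(3)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "MAP ")
    stop("not an MRC 2014 file (missing MAP magic): ", path)
  if (mode != 2)
    stop("unsupported MRC mode ", mode, " (only mode 2, float32, is supported)")
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal cell angles are not supported")
  vox <- cella / m
  if (max(vox) - min(vox) > 1e-4 * mean(vox))
    stop("anisotropic voxel sizes are not supported: ",
         paste(signif(vox, 6), collapse = ", "))
  seek(con, 1024 + nsymbt)
  data <- readBin(con, "numeric", prod(nf), size = 4, endian = "little")
  A <- array(data, dim = nf)
  ax <- maps
  if (!all(sort(ax) == 1:3)) stop("invalid MAPC/MAPR/MAPS: ",
                                  paste(ax, collapse = ","))
  B <- aperm(A, match(1:3, ax))
  nstart_xyz <- nstart[match(1:3, ax)]
  potential_map(B, mean(vox), origin + nstart_xyz * mean(vox))
}
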