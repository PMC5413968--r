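# CCP4/MRC volume I/O (mode 2, 32-bit float, little-endian).  Only
# axis-aligned P1-style grids are handled: MAPC/MAPR/MAPS must be 1/2/3 and
# the voxel size must be isotropic (the downstream statistics require an
# isotropic Cartesian grid).  The Cartesian origin is carried in the
# MRC-2014 ORIGIN fields (words 50-52); NSTART words are written as 0.

MRC_HEADER_WORDS <- 256L

#' Read a CCP4/MRC density map
#'
#' Reads a mode-2 (32-bit float) CCP4/MRC volume into a
#' \code{\link{density_map}}.  Files with anisotropic voxels (beyond a
#' 1e-3 Angstrom tolerance) or permuted axis order are rejected, since the
#' ensemble statistics require a common isotropic Cartesian grid.
#' \code{NaN} values in the file are mapped to missing (\code{NA}) voxels.
#'
#' @param path path to a CCP4/MRC file.
#' @param label provenance label; defaults to the file name.
#' @return A \code{\link{density_map}}.
#' @export
read_map <- function(path, label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 4L * MRC_HEADER_WORDS)
  if (length(hdr_raw) < 4L * MRC_HEADER_WORDS)
    stop("not a CCP4/MRC map: file shorter than header: ", path)
  magic <- rawToChar(hdr_raw[209:212])  # word 53
  if (magic != "MAP ")
    stop("not a CCP4/MRC map (missing 'MAP ' magic): ", path)
  word_int <- function(w)
    readBin(hdr_raw[(4L * (w - 1L) + 1L):(4L * w)], "integer",
            size = 4L, endian = "little")
  word_flt <- function(w)
    readBin(hdr_raw[(4L * (w - 1L) + 1L):(4L * w)], "numeric",
            size = 4L, endian = "little")
  nxyz <- c(word_int(1L), word_int(2L), word_int(3L))
  mode <- word_int(4L)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
  mxyz <- c(word_int(8L), word_int(9L), word_int(10L))
  cella <- c(word_flt(11L), word_flt(12L), word_flt(13L))
  mapcrs <- c(word_int(17L), word_int(18L), word_int(19L))
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported axis order MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = "/"), " (only 1/2/3)")
  nsymbt <- word_int(24L)
  origin <- c(word_flt(50L), word_flt(51L), word_flt(52L))
  if (any(mxyz <= 0L) || any(cella <= 0))
    stop("invalid MRC header (non-positive MX/MY/MZ or cell): ", path)
  sp <- cella / mxyz
  if (max(sp) - min(sp) > 1e-3)
    stop("anisotropic voxels (", paste(signif(sp, 6), collapse = ", "),
         " A); only isotropic grids are supported")
  spacing <- mean(sp)
  if (all(origin == 0)) {
    nstart <- c(word_int(5L), word_int(6L), word_int(7L))
    origin <- nstart * spacing
  }
  if (nsymbt > 0L) readBin(con, "raw", n = nsymbt)
  nvox <- prod(nxyz)
  vals <- readBin(con, "numeric", n = nvox, size = 4L, endian = "little")
  if (length(vals) < nvox)
    stop("truncated CCP4/MRC map (expected ", nvox, " voxels, got ",
         length(vals), "): ", path)
  vals[is.nan(vals)] <- NA_real_
  density_map(array(vals, dim = nxyz), spacing = spacing, origin = origin,
              label = label)
}

#' Write a CCP4/MRC density map
#'
#' Writes a \code{\link{density_map}} as a mode-2 (float32) little-endian
#' CCP4/MRC volume readable by standard crystallography viewers.  Missing
#' voxels are stored as \code{NaN}.
#'
#' @param map a \code{\link{density_map}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- map$values
  fin <- v[!is.na(v)]
  wi(d)                       # NX NY NZ
  wi(2L)                      # MODE
  wi(c(0L, 0L, 0L))           # NXSTART..
  wi(d)                       # MX MY MZ
  wf(d * map$spacing)         # CELLA
  wf(c(90, 90, 90))           # cell angles
  wi(c(1L, 2L, 3L))           # MAPC MAPR MAPS
  wf(c(if (length(fin)) min(fin) else 0,
       if (length(fin)) max(fin) else 0,
       if (length(fin)) mean(fin) else 0))   # DMIN DMAX DMEAN
  wi(1L)                      # ISPG
  wi(0L)                      # NSYMBT
  wi(integer(25L))            # EXTRA (words 25-49)
  wf(map$origin)              # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)            # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST
  wf(if (length(fin)) stats::sd(fin) else 0)  # RMS
  wi(1L)                      # NLABL
  lab <- substr(paste0(map$label, strrep(" ", 80L)), 1L, 80L)
  writeBin(charToRaw(lab), con)
  writeBin(raw(9L * 80L), con)  # labels 2-10 blank; header totals 1024 bytes
  v[is.na(v)] <- NaN
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}
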