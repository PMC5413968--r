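# Dense scalar field on an isotropic Cartesian grid.  Voxel [1,1,1] (R
# indexing) is centred at `origin`; the centre of voxel [i,j,k] is
# origin + (c(i,j,k) - 1) * spacing.  Missing voxels (e.g. outside the
# support of a warped map) are NA; all finite values are valid densities.

#' Construct a density map
#'
#' A \code{density_map} is a dense 3D scalar field (electron density, in
#' arbitrary map units) on an isotropic Cartesian grid.
#'
#' @param values numeric 3D array, at least 2 voxels along each axis.
#'   \code{NA} marks missing voxels; all other values must be finite.
#' @param spacing voxel edge length in Angstrom (isotropic), > 0.
#' @param origin length-3 Cartesian position (Angstrom) of the centre of
#'   voxel \code{[1,1,1]}.
#' @param label free-text provenance string.
#' @return An object of class \code{density_map} with fields \code{values},
#'   \code{spacing}, \code{origin}, \code{label}.
#' @export
density_map <- function(values, spacing, origin = c(0, 0, 0), label = "") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (any(dim(values) < 2L))
    stop("grid must have at least 2 voxels per axis")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("'spacing' must be a single positive number")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be a finite length-3 vector")
  storage.mode(values) <- "double"
  if (any(is.infinite(values) | is.nan(values), na.rm = TRUE))
    stop("map values must be finite or NA")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label = as.character(label)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, spacing %.4g A\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A; %d missing voxels\n",
              x$origin[1], x$origin[2], x$origin[3], sum(is.na(x$values))))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Voxel volume of a map
#'
#' @param map a \code{density_map}.
#' @return Voxel volume \code{spacing^3} in cubic Angstrom.
#' @export
voxel_volume <- function(map) {
  stopifnot(inherits(map, "density_map"))
  map$spacing^3
}

#' Convert voxel indices to Cartesian positions
#'
#' @param map a \code{density_map} (or a list with \code{spacing}/\code{origin}).
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of Cartesian positions (Angstrom) of voxel centres.
#' @export
index_to_position <- function(map, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx, 2L, 1), 1L, 0) * map$spacing +
    matrix(map$origin, nrow(idx), 3L, byrow = TRUE)
}

#' Convert Cartesian positions to (fractional) voxel indices
#'
#' Inverse of \code{\link{index_to_position}}; returns fractional indices,
#' so \code{position_to_index(map, index_to_position(map, i))} recovers
#' \code{i} exactly for on-grid points.
#'
#' @param map a \code{density_map}.
#' @param pos n x 3 matrix of Cartesian positions (Angstrom).
#' @return n x 3 matrix of 1-based (possibly fractional) voxel indices.
#' @export
position_to_index <- function(map, pos) {
  pos <- matrix(as.numeric(pos), ncol = 3L)
  sweep(pos, 2L, map$origin) / map$spacing + 1
}

#' Cartesian positions of all voxel centres
#'
#' @param map a \code{density_map}.
#' @return An \code{nvox x 3} matrix of positions, in R array (column-major)
#'   voxel order.
#' @export
grid_positions <- function(map) {
  d <- dim(map$values)
  idx <- cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2]))
  index_to_position(map, idx)
}

# Trilinear interpolation of a 3D array at fractional 1-based indices.
# Points with any contributing corner outside the grid or NA return NA.
interp_trilinear <- function(values, fidx) {
  d <- dim(values)
  n <- nrow(fidx)
  i0 <- floor(fidx)
  f <- fidx - i0
  out <- rep(NA_real_, n)
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
        i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
        i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  # allow points exactly on the upper grid boundary
  hi <- !ok &
    fidx[, 1] >= 1 & fidx[, 1] <= d[1] &
    fidx[, 2] >= 1 & fidx[, 2] <= d[2] &
    fidx[, 3] >= 1 & fidx[, 3] <= d[3]
  if (any(hi)) {
    i0[hi, ] <- pmin(i0[hi, , drop = FALSE], rep(d - 1L, each = sum(hi)))
    f[hi, ] <- fidx[hi, , drop = FALSE] - i0[hi, , drop = FALSE]
    ok <- ok | hi
  }
  if (!any(ok)) return(out)
  i0k <- i0[ok, , drop = FALSE]
  fk <- f[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fk[, 1] else 1 - fk[, 1]) *
         (if (dy) fk[, 2] else 1 - fk[, 2]) *
         (if (dz) fk[, 3] else 1 - fk[, 3])
    v <- values[cbind(i0k[, 1] + dx, i0k[, 2] + dy, i0k[, 3] + dz)]
    acc <- acc + w * v
  }
  out[ok] <- acc
  out
}

#' Interpolate a map at arbitrary Cartesian positions
#'
#' Trilinear interpolation; positions outside the grid (or touching a
#' missing voxel) give \code{NA}.
#'
#' @param map a \code{density_map}.
#' @param pos n x 3 matrix of Cartesian positions (Angstrom).
#' @return Numeric vector of interpolated densities.
#' @export
interpolate_map <- function(map, pos) {
  interp_trilinear(map$values, position_to_index(map, pos))
}

# shared grid check used across modules
check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$spacing - b$spacing) > 1e-9 ||
      any(abs(a$origin - b$origin) > 1e-6))
    stop("maps are not on the same grid")
  invisible(TRUE)
}
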