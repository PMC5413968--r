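# Resolution management.  Crystals diffract to different limits, so maps
# are only comparable after truncation to a common information content.
# Datasets are scheduled into resolution bins: each dataset is analysed
# once, in the finest bin whose ceiling is at or above its own resolution,
# and contributes to the ensemble ("characterization") in every coarser
# bin; datasets coarser than a bin's ceiling never contribute to that bin.
# Truncation is emulated in Fourier space with a spherical cutoff at
# |k| = 1/d_min, the crystallographic resolution convention.

#' Build an analysis plan from dataset resolutions and bin ceilings
#'
#' @param resolutions numeric vector of dataset resolutions d_i (Angstrom),
#'   named by dataset id (names optional; indices used otherwise).
#' @param bin_ceilings strictly increasing vector of bin ceilings (Angstrom).
#' @return An object of class \code{analysis_plan}: for every bin, the
#'   analysis set (datasets analysed at that ceiling) and characterization
#'   set (datasets whose maps inform the statistical model at that ceiling).
#'   Datasets coarser than the coarsest ceiling are excluded with a warning.
#' @export
assign_bins <- function(resolutions, bin_ceilings) {
  if (any(diff(bin_ceilings) <= 0))
    stop("bin ceilings must be strictly increasing")
  if (any(resolutions <= 0)) stop("resolutions must be positive")
  ids <- names(resolutions)
  if (is.null(ids)) ids <- as.character(seq_along(resolutions))
  excluded <- ids[resolutions > max(bin_ceilings)]
  if (length(excluded))
    warning("excluded (coarser than coarsest bin ceiling ",
            max(bin_ceilings), " A): ", paste(excluded, collapse = ", "))
  bins <- lapply(seq_along(bin_ceilings), function(b) {
    ceil <- bin_ceilings[b]
    chr <- ids[resolutions <= ceil]
    # analysed here iff this is the finest bin with ceiling >= d_i
    lower <- if (b == 1L) 0 else bin_ceilings[b - 1L]
    ana <- ids[resolutions <= ceil & resolutions > lower]
    list(ceiling = ceil, analysis = ana, characterization = chr)
  })
  structure(list(bins = bins, excluded = excluded,
                 resolutions = stats::setNames(as.numeric(resolutions), ids)),
            class = "analysis_plan")
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat("analysis_plan:\n")
  for (b in x$bins)
    cat(sprintf("  <= %.2f A: analyse %d, characterize %d\n",
                b$ceiling, length(b$analysis), length(b$characterization)))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

# Spatial frequency magnitude |k| (1/Angstrom) for every grid voxel of the
# DFT of an n1 x n2 x n3 array with the given spacing.
freq_magnitude <- function(dims, spacing) {
  f <- lapply(dims, function(n) {
    k <- 0:(n - 1L)
    pmin(k, n - k) / (n * spacing)
  })
  sqrt(outer(outer(f[[1]]^2, f[[2]]^2, `+`), f[[3]]^2, `+`))
}

#' Fourier keep-mask for a resolution cutoff
#'
#' @param map a \code{\link{density_map}} (grid only is used).
#' @param d_min resolution cutoff (Angstrom).
#' @return Logical 3D array: TRUE where the DFT coefficient's spatial
#'   frequency satisfies |k| <= 1/d_min (periods >= d_min kept).
#' @export
resolution_mask <- function(map, d_min) {
  freq_magnitude(dim(map$values), map$spacing) <= 1 / d_min + 1e-9
}

#' Low-pass truncate a map to a resolution limit
#'
#' Emulates recalculating the map from diffraction data truncated at
#' \code{d_min}: the discrete Fourier transform is computed, coefficients
#' with spatial frequency above 1/\code{d_min} (spherical cutoff) are
#' zeroed, and the map is back-transformed.  A linear projection:
#' idempotent, and exact on band-limited input.
#'
#' @param map a \code{\link{density_map}} with no missing voxels.
#' @param d_min resolution limit (Angstrom); must be >= 2 x spacing
#'   (the grid's Nyquist period).
#' @return The truncated \code{\link{density_map}} on the same grid.
#' @export
lowpass_truncate <- function(map, d_min) {
  stopifnot(inherits(map, "density_map"))
  if (d_min < 2 * map$spacing - 1e-9)
    stop("d_min (", d_min, " A) below the grid Nyquist period (",
         2 * map$spacing, " A)")
  if (anyNA(map$values))
    stop("lowpass_truncate requires a complete map (no missing voxels)")
  keep <- resolution_mask(map, d_min)
  ft <- stats::fft(map$values)
  ft[!keep] <- 0+0i
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  density_map(out, spacing = map$spacing, origin = map$origin,
              label = paste0(map$label, sprintf(" [<= %.2f A]", d_min)))
}

#' Intersection of Fourier keep-masks
#'
#' Applying the common mask to every dataset's Fourier representation
#' leaves all datasets with identical support, mirroring truncation of
#' reflection data to the Miller indices common to all datasets.
#'
#' @param masks list of logical arrays on identical grids.
#' @return The element-wise AND of all masks.
#' @export
common_support <- function(masks) {
  if (!length(masks)) stop("no masks supplied")
  dims <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), dims)) stop("masks are on mismatched grids")
  Reduce(`&`, masks)
}

#' Apply a Fourier keep-mask to a map
#'
#' @param map a complete \code{\link{density_map}}.
#' @param mask logical array from \code{\link{resolution_mask}} or
#'   \code{\link{common_support}}.
#' @return The filtered map.
#' @export
apply_fourier_mask <- function(map, mask) {
  stopifnot(inherits(map, "density_map"))
  if (!identical(dim(mask), dim(map$values)))
    stop("mask grid does not match map grid")
  if (anyNA(map$values)) stop("map must be complete (no missing voxels)")
  ft <- stats::fft(map$values)
  ft[!mask] <- 0+0i
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  density_map(out, spacing = map$spacing, origin = map$origin,
              label = map$label)
}

# Default bin ceilings: `step`-Angstrom steps spanning the observed
# resolution range, each ceiling rounded up so every dataset fits a bin.
default_bin_ceilings <- function(resolutions, step = 0.1) {
  lo <- ceiling(min(resolutions) / step - 1e-9) * step
  hi <- ceiling(max(resolutions) / step - 1e-9) * step
  unique(round(seq(lo, hi, by = step), 10))
}
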