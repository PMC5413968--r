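# Flexible (locally rigid) structural alignment.  Each residue gets its own
# least-squares rigid transform, fitted on the C-alpha atoms of a sliding
# window centred on it; maps are then warped voxel-wise using the transform
# of the nearest residue.  This relaxes the strict-isomorphism requirement
# of Fo-Fo style comparisons: crystals only need to be locally similar.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation \code{R} and translation \code{t} minimizing
#' \code{sum || R p_i + t - q_i ||^2} over paired points.
#'
#' @param P,Q paired n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return A list with \code{rotation} (3 x 3, proper: det = +1),
#'   \code{translation} (length 3) and \code{rmsd} (post-fit RMSD, Angstrom).
#' @export
superpose <- function(P, Q) {
  P <- matrix(as.numeric(P), ncol = 3L)
  Q <- matrix(as.numeric(Q), ncol = 3L)
  if (nrow(P) != nrow(Q)) stop("P and Q must be paired (same number of rows)")
  if (nrow(P) < 3L) stop("superposition requires at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  sv <- svd(crossprod(Pc, Qc))          # H = t(Pc) Qc
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) point set: superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

apply_transform <- function(xyz, rotation, translation) {
  sweep(matrix(as.numeric(xyz), ncol = 3L) %*% t(rotation), 2L,
        -translation)
}

# C-alpha table of a model, ordered by chain then residue number
calpha_table <- function(model) {
  ca <- model[model$atom == "CA" & (model$altloc == "" | model$altloc == "A"), ,
              drop = FALSE]
  ca[order(ca$chain, ca$resno), , drop = FALSE]
}

#' Flexible (per-residue) alignment of a model onto a reference
#'
#' For every residue, a rigid transform is fitted (\code{\link{superpose}})
#' on the C-alpha atoms of the residue window centred on it (truncated at
#' chain ends).  The stored transforms map moving-frame coordinates into
#' the reference frame.  Models must share chain and residue numbering.
#'
#' @param moving,reference \code{\link{structure_model}}s with identical
#'   chain/residue numbering of their C-alpha atoms.
#' @param window odd window length in residues (>= 3); default 7.
#' @return An object of class \code{local_alignment}: per-residue list of
#'   \code{rotation}, \code{translation}, plus the aligned C-alpha position
#'   \code{ca_ref} (reference frame) used for voxel-to-residue assignment.
#' @export
flexible_alignment <- function(moving, reference, window = 7L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  ca_m <- calpha_table(moving)
  ca_r <- calpha_table(reference)
  key_m <- paste(ca_m$chain, ca_m$resno)
  key_r <- paste(ca_r$chain, ca_r$resno)
  if (!identical(sort(key_m), sort(key_r)))
    stop("residue correspondence mismatch between moving and reference")
  ca_m <- ca_m[match(key_r, key_m), , drop = FALSE]
  half <- (window - 1L) %/% 2L
  residues <- list()
  for (ch in unique(ca_r$chain)) {
    sel <- which(ca_r$chain == ch)
    n <- length(sel)
    if (n < window)
      stop("chain ", ch, " has ", n, " C-alpha atoms; window is ", window)
    Pm <- coords(ca_m[sel, , drop = FALSE])
    Pr <- coords(ca_r[sel, , drop = FALSE])
    for (j in seq_len(n)) {
      win <- max(1L, j - half):min(n, j + half)
      fit <- superpose(Pm[win, , drop = FALSE], Pr[win, , drop = FALSE])
      key <- paste(ch, ca_r$resno[sel[j]])
      residues[[key]] <- list(
        rotation = fit$rotation,
        translation = fit$translation,
        ca_ref = as.vector(apply_transform(Pm[j, , drop = FALSE],
                                           fit$rotation, fit$translation)),
        rmsd = fit$rmsd)
    }
  }
  structure(list(residues = residues,
                 reference_chains = unique(ca_r$chain),
                 window = window),
            class = "local_alignment")
}

#' Identity alignment for a model
#'
#' Convenience constructor: every residue gets the identity transform.
#' Useful when a dataset is already in the reference frame.
#'
#' @param model a \code{\link{structure_model}}.
#' @return A \code{local_alignment} with identity transforms.
#' @export
identity_alignment <- function(model) {
  ca <- calpha_table(model)
  residues <- list()
  for (j in seq_len(nrow(ca))) {
    residues[[paste(ca$chain[j], ca$resno[j])]] <- list(
      rotation = diag(3), translation = c(0, 0, 0),
      ca_ref = as.numeric(ca[j, c("x", "y", "z")]), rmsd = 0)
  }
  structure(list(residues = residues, reference_chains = unique(ca$chain),
                 window = NA_integer_),
            class = "local_alignment")
}

#' Invert a local alignment
#'
#' @param alignment a \code{local_alignment}.
#' @return The alignment with every rigid transform inverted (the C-alpha
#'   anchor positions are moved to the other frame accordingly).
#' @export
invert_alignment <- function(alignment) {
  res <- lapply(names(alignment$residues), function(k) {
    r <- alignment$residues[[k]]
    Rinv <- t(r$rotation)
    tinv <- -as.vector(Rinv %*% r$translation)
    ca_mov <- as.vector(Rinv %*% (r$ca_ref - r$translation))
    list(rotation = Rinv, translation = tinv, ca_ref = ca_mov, rmsd = r$rmsd)
  })
  names(res) <- names(alignment$residues)
  structure(list(residues = res, reference_chains = alignment$reference_chains,
                 window = alignment$window),
            class = "local_alignment")
}

#' Warp a density map into the reference frame
#'
#' Each output voxel takes its value from the moving map, interpolated at
#' the position obtained by applying the inverse transform of the nearest
#' residue (by aligned C-alpha distance) to the voxel centre.  Voxels
#' farther than \code{max_dist} from every residue, or falling outside the
#' moving map's support, are marked missing (\code{NA}).
#'
#' @param map the moving dataset's \code{\link{density_map}}.
#' @param alignment a \code{local_alignment} of the moving model onto the
#'   reference (from \code{\link{flexible_alignment}}).
#' @param reference_grid a \code{\link{density_map}} (only its grid is
#'   used) defining the output grid.
#' @param max_dist maximum voxel-to-C-alpha distance (Angstrom, default 10)
#'   beyond which a voxel is marked missing.
#' @return A \code{\link{density_map}} on the reference grid.
#' @export
warp_map <- function(map, alignment, reference_grid, max_dist = 10) {
  stopifnot(inherits(map, "density_map"))
  plan <- warp_plan(alignment, reference_grid, max_dist)
  apply_warp_plan(map, plan)
}

#' Precompute the sampling positions for warping onto a reference grid
#'
#' For every voxel of the reference grid, the Cartesian position in the
#' moving frame at which the moving map must be sampled (the inverse
#' transform of the nearest aligned residue applied to the voxel centre).
#' Splitting this from \code{\link{warp_map}} lets one alignment warp a
#' dataset's map repeatedly (e.g. once per resolution bin) for the cost of
#' a single voxel-to-residue assignment.
#'
#' @param alignment a \code{local_alignment}.
#' @param reference_grid a \code{\link{density_map}} defining the grid.
#' @param max_dist voxels farther than this (Angstrom) from every aligned
#'   residue are marked missing.
#' @return A \code{warp_plan} (sampling positions with NA rows for
#'   out-of-range voxels, plus the grid).
#' @export
warp_plan <- function(alignment, reference_grid, max_dist = 10) {
  stopifnot(inherits(alignment, "local_alignment"),
            inherits(reference_grid, "density_map"))
  pos <- grid_positions(reference_grid)
  nres <- length(alignment$residues)
  if (nres == 0L) stop("alignment has no residues")
  best_d2 <- rep(Inf, nrow(pos))
  best_i <- rep(NA_integer_, nrow(pos))
  ca <- do.call(rbind, lapply(alignment$residues, `[[`, "ca_ref"))
  for (i in seq_len(nres)) {
    d2 <- (pos[, 1] - ca[i, 1])^2 + (pos[, 2] - ca[i, 2])^2 +
          (pos[, 3] - ca[i, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }
  sample_pos <- matrix(NA_real_, nrow(pos), 3L)
  inrange <- best_d2 <= max_dist^2
  for (i in seq_len(nres)) {
    sel <- which(inrange & best_i == i)
    if (!length(sel)) next
    r <- alignment$residues[[i]]
    # reference -> moving: x_mov = R^T (x_ref - t)
    sample_pos[sel, ] <- sweep(pos[sel, , drop = FALSE], 2L,
                               r$translation) %*% r$rotation
  }
  structure(list(sample_pos = sample_pos, grid = reference_grid),
            class = "warp_plan")
}

# interpolate a moving map at precomputed warp positions
apply_warp_plan <- function(map, plan) {
  out <- rep(NA_real_, nrow(plan$sample_pos))
  ok <- which(!is.na(plan$sample_pos[, 1]))
  if (length(ok))
    out[ok] <- interpolate_map(map, plan$sample_pos[ok, , drop = FALSE])
  density_map(array(out, dim = dim(plan$grid$values)),
              spacing = plan$grid$spacing,
              origin = plan$grid$origin,
              label = paste0(map$label, " [warped]"))
}
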