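# Multi-state ensemble bookkeeping and real-space validation.  A changed
# state at fractional occupancy is modelled jointly with the ground state:
# atoms shared by both states keep a blank altloc, state-specific (or
# moved) atoms get fresh conformer labels, and the two states' occupancies
# are constrained to sum to one.  The initial changed-state occupancy is
# q = 2 x (1 - BDC), clamped away from degenerate values.

#' Merge ground- and changed-state models into a refinable ensemble
#'
#' Atoms identical in both states (same chain/residue/atom key,
#' coordinates within \code{move_tol}) are kept once with blank altloc.
#' Ground-only or moved atoms get the first unused conformer label,
#' changed-only or moved atoms the second; each paired group's occupancies
#' sum to one: \code{occ(ground) = 1 - q}, \code{occ(changed) = q} with
#' \code{q = clamp(2 (1 - bdc), 0.05, 1)}.
#'
#' @param ground,changed \code{\link{structure_model}}s in the same
#'   (reference) frame.
#' @param bdc background density correction factor in [0, 1).
#' @param move_tol coordinate difference (Angstrom, default 0.1) above
#'   which a shared atom counts as moved.
#' @return An object of class \code{ensemble_model}: fields \code{model}
#'   (the merged \code{structure_model}), \code{q} (changed-state
#'   occupancy), \code{bdc}, \code{ground_conformer},
#'   \code{changed_conformer}.
#' @export
merge_ensemble <- function(ground, changed, bdc, move_tol = 0.1) {
  stopifnot(inherits(ground, "structure_model"),
            inherits(changed, "structure_model"))
  if (bdc < 0 || bdc >= 1) stop("bdc must lie in [0, 1)")
  if (nrow(ground) && nrow(changed)) {
    dcen <- sqrt(sum((colMeans(coords(ground)) -
                      colMeans(coords(changed)))^2))
    if (dcen > 20)
      stop("models appear to be in different frames (centroid distance ",
           round(dcen, 1), " A)")
  }
  used <- unique(c(ground$altloc, changed$altloc))
  free <- setdiff(LETTERS, used[used != ""])
  if (length(free) < 2L) stop("conformer namespace exhausted")
  conf_g <- free[1]; conf_c <- free[2]
  q <- min(max(2 * (1 - bdc), 0.05), 1.0)
  kg <- atom_key(ground, with_altloc = FALSE)
  kc <- atom_key(changed, with_altloc = FALSE)
  idx_c <- match(kg, kc)
  moved <- rep(TRUE, nrow(ground))
  paired <- !is.na(idx_c)
  if (any(paired)) {
    dd <- sqrt(rowSums((coords(ground)[paired, , drop = FALSE] -
                        coords(changed)[idx_c[paired], , drop = FALSE])^2))
    moved[paired] <- dd > move_tol
  }
  shared_g <- paired & !moved
  shared <- as.data.frame(ground[shared_g, , drop = FALSE])
  only_g <- as.data.frame(ground[!shared_g, , drop = FALSE])
  only_c <- as.data.frame(changed[!(kc %in% kg[shared_g]), , drop = FALSE])
  if (nrow(only_g)) {
    only_g$altloc <- conf_g
    only_g$occ <- 1 - q
  }
  if (nrow(only_c)) {
    only_c$altloc <- conf_c
    only_c$occ <- q
  }
  merged <- structure_model(rbind(shared, only_g, only_c))
  structure(list(model = merged, q = q, bdc = bdc,
                 ground_conformer = conf_g, changed_conformer = conf_c),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "ensemble_model: %d atoms (%d ground-only '%s', %d changed-only '%s'), q = %.3f\n",
    nrow(x$model), sum(x$model$altloc == x$ground_conformer),
    x$ground_conformer, sum(x$model$altloc == x$changed_conformer),
    x$changed_conformer, x$q))
  invisible(x)
}

#' Extract the changed-state model from an ensemble
#'
#' Removes the ground-only conformer; shared atoms plus changed-conformer
#' atoms remain, with the changed atoms' occupancies rescaled back to
#' full (the inverse of \code{\link{merge_ensemble}} up to labels).
#'
#' @param ensemble an \code{ensemble_model}.
#' @return A \code{\link{structure_model}} of the changed state.
#' @export
extract_changed_state <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  m <- ensemble$model
  keep <- m$altloc != ensemble$ground_conformer
  out <- as.data.frame(m[keep, , drop = FALSE])
  is_c <- out$altloc == ensemble$changed_conformer
  out$occ[is_c] <- pmin(out$occ[is_c] / ensemble$q, 1)
  out$altloc[is_c] <- ""
  structure_model(out)
}

# voxel mask within `radius` of any atom of `atoms`
atom_mask_voxels <- function(atoms, map, radius) {
  pos <- grid_positions(map)
  keep <- rep(FALSE, nrow(pos))
  xyz <- coords(atoms)
  for (i in seq_len(nrow(xyz))) {
    d2 <- (pos[, 1] - xyz[i, 1])^2 + (pos[, 2] - xyz[i, 2])^2 +
          (pos[, 3] - xyz[i, 3])^2
    keep <- keep | d2 <= radius^2
  }
  which(keep)
}

#' Real-space correlation coefficient (RSCC)
#'
#' Pearson correlation, over voxels within \code{radius} of any selected
#' atom, between the observed density and the model density (sum of
#' B-factor- and occupancy-scaled atom Gaussians).  Values above 0.7
#' indicate an acceptable fit of the atoms to the density.
#'
#' @param atoms \code{\link{structure_model}} subset to score.
#' @param observed observed \code{\link{density_map}}.
#' @param radius mask radius around atoms (Angstrom, default 1.5).
#' @param blur resolution blur passed to the model density (Angstrom).
#' @param model_density optional precomputed model \code{density_map}.
#' @return RSCC in [-1, 1].
#' @export
rscc <- function(atoms, observed, radius = 1.5, blur = 0,
                 model_density = NULL) {
  if (nrow(atoms) == 0L) stop("no atoms selected")
  if (is.null(model_density))
    model_density <- density_from_atoms(atoms, observed, blur = blur)
  check_same_grid(observed, model_density)
  vox <- atom_mask_voxels(atoms, observed, radius)
  x <- observed$values[vox]; y <- model_density$values[vox]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10L)
    stop("fewer than 10 map voxels support the selected atoms")
  stats::cor(x[ok], y[ok])
}

#' Real-space Z-difference score (RSZD surrogate)
#'
#' Standardizes the difference density (observed minus model) by the
#' supplied noise map and aggregates it per atom neighbourhood:
#' for each selected atom, \code{|mean(Z)| * sqrt(N)} over the voxels
#' within \code{radius}; the score is the maximum over atoms (and over the
#' positive and negative parts).  Under a correct model with correctly
#' estimated noise this is approximately the maximum of standard normal
#' magnitudes and stays below 3; residual difference density around a
#' mis- or unmodelled atom drives it far above 3.  This is a documented
#' surrogate for (and not numerically compatible with) the EDSTATS RSZD.
#'
#' @param atoms \code{\link{structure_model}} subset to score.
#' @param observed observed \code{\link{density_map}}.
#' @param model_density model \code{\link{density_map}} on the same grid.
#' @param sigma_map per-voxel noise sd: a \code{density_map} or a single
#'   number.
#' @param radius per-atom neighbourhood radius (Angstrom, default 1.5).
#' @return RSZD >= 0 (0 when observed equals the model exactly).
#' @export
rszd <- function(atoms, observed, model_density, sigma_map, radius = 1.5) {
  if (nrow(atoms) == 0L) stop("no atoms selected")
  check_same_grid(observed, model_density)
  sg <- if (inherits(sigma_map, "density_map")) sigma_map$values
        else array(sigma_map, dim = dim(observed$values))
  zv <- (observed$values - model_density$values) / sg
  xyz <- coords(atoms)
  pos <- grid_positions(observed)
  score <- 0
  for (i in seq_len(nrow(xyz))) {
    d2 <- (pos[, 1] - xyz[i, 1])^2 + (pos[, 2] - xyz[i, 2])^2 +
          (pos[, 3] - xyz[i, 3])^2
    vox <- which(d2 <= radius^2)
    zz <- zv[vox]; zz <- zz[!is.na(zz)]
    if (!length(zz)) next
    if (any(sg[vox] <= 0, na.rm = TRUE))
      stop("sigma_map must be positive over the atom mask")
    score <- max(score, abs(mean(zz)) * sqrt(length(zz)))
  }
  score
}

#' B-factor ratio of changed atoms to their protein environment
#'
#' Mean B of the changed (e.g. ligand) atoms divided by the mean B of all
#' side-chain atoms (protein atoms other than N, CA, C, O) within 4 A of
#' any changed atom.  Ratios above 3 reflect poor evidence for the model;
#' values above 1.5 indicate modelling or refinement problems.
#'
#' @param ligand \code{\link{structure_model}} subset of changed atoms.
#' @param environment \code{\link{structure_model}} of the surroundings.
#' @param radius environment search radius (Angstrom, default 4).
#' @return The ratio (> 0).
#' @export
bfactor_ratio <- function(ligand, environment, radius = 4) {
  if (nrow(ligand) == 0L) stop("no ligand atoms")
  side <- environment[!(environment$atom %in% c("N", "CA", "C", "O")), ,
                      drop = FALSE]
  if (nrow(side)) {
    lx <- coords(ligand); sx <- coords(side)
    near <- rep(FALSE, nrow(side))
    for (i in seq_len(nrow(lx))) {
      d2 <- (sx[, 1] - lx[i, 1])^2 + (sx[, 2] - lx[i, 2])^2 +
            (sx[, 3] - lx[i, 3])^2
      near <- near | d2 <= radius^2
    }
    side <- side[near, , drop = FALSE]
  }
  if (nrow(side) == 0L)
    stop("no side-chain atoms within ", radius,
         " A of the changed atoms (no environment)")
  mean(ligand$b) / mean(side$b)
}

#' Coordinate RMSD between two builds of the same atoms
#'
#' Root-mean-square deviation over atoms with matching keys (no
#' re-superposition; both models are assumed to share the crystal frame).
#' Hydrogens are excluded.
#'
#' @param before,after \code{\link{structure_model}}s.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(before, after) {
  b <- before[before$element != "H", , drop = FALSE]
  a <- after[after$element != "H", , drop = FALSE]
  idx <- match(atom_key(b), atom_key(a))
  ok <- !is.na(idx)
  if (!any(ok)) stop("no common atoms between the two models")
  d2 <- rowSums((coords(b)[ok, , drop = FALSE] -
                 coords(a)[idx[ok], , drop = FALSE])^2)
  sqrt(mean(d2))
}

#' Validate a modelled event
#'
#' Computes the four real-space validation scores for a changed-state
#' model and applies the standard thresholds: RSCC > 0.7 to pass, RSZD
#' < 3 to pass, B-factor ratio flagged above 1.5 (warn) and failed above
#' 3, coordinate RMSD (initial build vs refined) < 1 A to pass.  Metric
#' errors are collected per metric rather than aborting the report.
#'
#' @param atoms changed-state atoms to validate (a
#'   \code{\link{structure_model}}).
#' @param refined the same atoms after refinement (for RMSD); may be the
#'   same object when no refinement was run.
#' @param observed observed \code{\link{density_map}} (typically the event
#'   map).
#' @param model_density model density map for RSCC/RSZD.
#' @param sigma_map per-voxel noise sd (map or scalar) for RSZD.
#' @param environment \code{\link{structure_model}} of surrounding protein
#'   for the B-factor ratio.
#' @return A \code{validation_report}: the four scores, pass flags, and
#'   any per-metric error messages.
#' @export
validate_event <- function(atoms, refined, observed, model_density,
                           sigma_map, environment) {
  scores <- list(rscc = NA_real_, rszd = NA_real_, b_ratio = NA_real_,
                 rmsd = NA_real_)
  errors <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  scores$rscc <- grab("rscc",
    rscc(atoms, observed, model_density = model_density))
  scores$rszd <- grab("rszd",
    rszd(atoms, observed, model_density, sigma_map))
  scores$b_ratio <- grab("b_ratio", bfactor_ratio(atoms, environment))
  scores$rmsd <- grab("rmsd", coord_rmsd(atoms, refined))
  flags <- validation_flags(scores$rscc, scores$rszd, scores$b_ratio,
                            scores$rmsd)
  structure(c(scores, flags, list(errors = errors)),
            class = "validation_report")
}

#' Pass/fail flags for the four validation scores
#'
#' Pure threshold logic: RSCC passes strictly above 0.7, RSZD strictly
#' below 3, coordinate RMSD strictly below 1 Angstrom; the B-factor ratio
#' is \code{"ok"} below 1.5, \code{"warn"} from 1.5 to 3 (suggesting
#' refinement or modelling errors) and \code{"fail"} above 3 (poor
#' evidence for the model).
#'
#' @param rscc,rszd,b_ratio,rmsd the four scores (NA allowed).
#' @return List of \code{rscc_pass}, \code{rszd_pass},
#'   \code{b_ratio_flag}, \code{rmsd_pass}.
#' @export
validation_flags <- function(rscc, rszd, b_ratio, rmsd) {
  list(
    rscc_pass = isTRUE(rscc > 0.7),
    rszd_pass = isTRUE(rszd < 3),
    b_ratio_flag = if (is.na(b_ratio)) NA_character_
                   else if (b_ratio > 3) "fail"
                   else if (b_ratio >= 1.5) "warn"
                   else "ok",
    rmsd_pass = isTRUE(rmsd < 1))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("RSCC %.3f (%s)  RSZD %.2f (%s)  B-ratio %.2f (%s)  RMSD %.3f A (%s)\n",
              x$rscc, ifelse(x$rscc_pass, "pass", "FAIL"),
              x$rszd, ifelse(x$rszd_pass, "pass", "FAIL"),
              x$b_ratio, x$b_ratio_flag,
              x$rmsd, ifelse(x$rmsd_pass, "pass", "FAIL")))
  if (length(x$errors))
    cat("errors:", paste(names(x$errors), unlist(x$errors), sep = ": ",
                         collapse = "; "), "\n")
  invisible(x)
}

#' Distance-restraint table for ensemble stabilization
#'
#' Generic (program-agnostic) distance restraints between nearby atom
#' pairs within each conformer of an ensemble, for use as external
#' restraints during refinement of low-occupancy states.
#'
#' @param ensemble an \code{ensemble_model}.
#' @param max_dist pair distance cutoff (Angstrom, default 4).
#' @param sigma restraint sigma (Angstrom, default 0.1).
#' @param path optional CSV output path.
#' @return Data frame of atom-pair keys, target distances and sigmas.
#' @export
restraint_table <- function(ensemble, max_dist = 4, sigma = 0.1,
                            path = NULL) {
  m <- ensemble$model
  xyz <- coords(m)
  keys <- atom_key(m)
  rows <- list()
  for (i in seq_len(max(nrow(m) - 1L, 0L))) {
    d <- sqrt(rowSums(sweep(xyz[(i + 1L):nrow(m), , drop = FALSE], 2L,
                            xyz[i, ])^2))
    j <- which(d <= max_dist) + i
    ok <- m$altloc[j] == m$altloc[i] | m$altloc[j] == "" | m$altloc[i] == ""
    j <- j[ok]
    if (length(j))
      rows[[length(rows) + 1L]] <- data.frame(
        atom1 = keys[i], atom2 = keys[j],
        target = sqrt(rowSums(sweep(xyz[j, , drop = FALSE], 2L,
                                    xyz[i, ])^2)),
        sigma = sigma, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(atom1 = character(), atom2 = character(),
                        target = numeric(), sigma = numeric())
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
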