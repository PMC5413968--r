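# Event detection: connected clusters ("blobs") of significant Z-scores,
# background density correction (BDC) by contrast maximization, and event
# maps.  Default thresholds: contour Z = 2.5, minimum peak Z = 3, minimum
# volume 10 A^3 (about a third of a water molecule's volume), blobs closer
# than 5 A merged.  Components use 26-neighbour connectivity so that thin
# diagonal features are not split.

# 26-connected components of a logical 3D mask; returns a list of integer
# vectors of linear voxel indices.  Union-find over the masked voxels.
connected_components <- function(mask) {
  d <- dim(mask)
  w <- which(mask)
  m <- length(w)
  if (!m) return(list())
  coord <- arrayInd(w, d)
  lookup <- match(seq_len(prod(d)), w)   # linear index -> rank in w (or NA)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # forward half-space only (each pair touched once)
  keep <- offsets[, 3] > 0 | (offsets[, 3] == 0 & offsets[, 2] > 0) |
    (offsets[, 3] == 0 & offsets[, 2] == 0 & offsets[, 1] > 0)
  offsets <- offsets[keep, , drop = FALSE]
  for (o in seq_len(nrow(offsets))) {
    nb <- sweep(coord, 2L, -offsets[o, ])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    j <- lookup[lin]
    src <- which(ok)[!is.na(j)]
    dst <- j[!is.na(j)]
    for (k in seq_along(src)) {
      a <- find(src[k]); b <- find(dst[k])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  split(w, root)
}

# minimum pairwise distance between two sets of points
min_set_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

new_event <- function(dataset_id, voxels, z, grid) {
  pos <- index_to_position(grid, arrayInd(voxels, dim(grid$values)))
  structure(list(
    dataset_id = dataset_id,
    voxels = sort(voxels),
    centroid = colMeans(pos),
    peak_z = max(z[voxels]),
    volume = length(voxels) * grid$spacing^3,
    bdc = NA_real_,
    low_contrast = NA,
    event_map = NULL), class = "dd_event")
}

#' @export
print.dd_event <- function(x, ...) {
  cat(sprintf(
    "event [%s]: peak Z %.2f, volume %.1f A^3, centroid (%.1f, %.1f, %.1f)%s\n",
    x$dataset_id, x$peak_z, x$volume, x$centroid[1], x$centroid[2],
    x$centroid[3],
    if (is.na(x$bdc)) "" else sprintf(", BDC %.2f", x$bdc)))
  invisible(x)
}

#' Find significant blobs in a Z-map
#'
#' Connected components (26-neighbour) of voxels with Z at or above the
#' contour level are filtered by minimum peak Z and minimum volume, then
#' blobs whose minimum inter-voxel distance is below \code{merge_dist} are
#' merged iteratively until stable.  Events are returned sorted by peak Z,
#' descending.
#'
#' @param z a \code{\link{zmap}} (or any \code{density_map} of Z-scores).
#' @param contour contour level (default 2.5).
#' @param min_peak minimum peak Z for a blob to survive (default 3.0).
#' @param min_volume minimum blob volume in cubic Angstrom (default 10).
#' @param merge_dist blobs closer than this (Angstrom, default 5) merge.
#' @param dataset_id id recorded on the events.
#' @param negative also run a symmetric pass on -Z (density loss); off by
#'   default.
#' @return List of \code{dd_event} objects (possibly empty).
#' @export
find_blobs <- function(z, contour = 2.5, min_peak = 3.0, min_volume = 10,
                       merge_dist = 5, dataset_id = "", negative = FALSE) {
  stopifnot(inherits(z, "density_map"))
  if (contour > min_peak) stop("contour must be <= min_peak")
  if (contour <= 0 || min_volume <= 0 || merge_dist <= 0)
    stop("thresholds must be positive")
  zv <- z$values
  run_pass <- function(zz) {
    mask <- !is.na(zz) & zz >= contour
    comps <- connected_components(mask)
    comps <- Filter(function(vox) {
      max(zz[vox]) >= min_peak &&
        length(vox) * z$spacing^3 >= min_volume
    }, comps)
    comps
  }
  comps <- run_pass(zv)
  if (negative) comps <- c(comps, run_pass(-zv))
  if (!length(comps)) return(list())
  # iterative merge of blobs closer than merge_dist
  repeat {
    if (length(comps) < 2L) break
    pos <- lapply(comps, function(v)
      index_to_position(z, arrayInd(v, dim(zv))))
    merged <- FALSE
    for (i in seq_len(length(comps) - 1L)) {
      for (j in (i + 1L):length(comps)) {
        if (min_set_distance(pos[[i]], pos[[j]]) < merge_dist) {
          comps[[i]] <- c(comps[[i]], comps[[j]])
          comps[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  zabs <- if (negative) abs(zv) else zv
  events <- lapply(comps, function(v) new_event(dataset_id, v, zabs, z))
  events[order(-vapply(events, `[[`, numeric(1), "peak_z"))]
}

# voxel linear indices within `dist` Angstrom of any blob voxel
expand_voxel_set <- function(grid, voxels, dist) {
  d <- dim(grid$values)
  blob_pos <- index_to_position(grid, arrayInd(voxels, d))
  r <- ceiling(dist / grid$spacing)
  rng <- apply(arrayInd(voxels, d), 2L, range)
  lo <- pmax(rng[1, ] - r, 1L)
  hi <- pmin(rng[2, ] + r, d)
  cand <- as.matrix(expand.grid(seq(lo[1], hi[1]), seq(lo[2], hi[2]),
                                seq(lo[3], hi[3])))
  cpos <- index_to_position(grid, cand)
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(blob_pos))) {
    d2 <- (cpos[, 1] - blob_pos[i, 1])^2 + (cpos[, 2] - blob_pos[i, 2])^2 +
          (cpos[, 3] - blob_pos[i, 3])^2
    keep <- keep | d2 <= dist^2
  }
  sort(cand[keep, 1] + (cand[keep, 2] - 1L) * d[1] +
         (cand[keep, 3] - 1L) * d[1] * d[2])
}

#' Estimate the background density correction (BDC) factor for an event
#'
#' For each candidate fraction beta, the partial-difference density
#' \code{D_beta = map_i - beta * mu} is correlated with the mean map both
#' globally (all non-missing voxels outside the local region) and locally
#' (the blob expanded by \code{buffer} Angstrom).  Locally the dataset is
#' a superposition of ground state and something unrelated, so the local
#' correlation decays faster as beta grows; the BDC is the beta maximizing
#' global minus local correlation.  Ties break toward smaller beta.
#'
#' @param map_i the dataset's aligned \code{\link{density_map}}.
#' @param mu the ensemble mean map.
#' @param blob integer linear voxel indices of the event blob.
#' @param buffer blob expansion radius (Angstrom, default 1); grown in
#'   0.5 A steps until the local region holds >= 20 voxels.
#' @param beta_grid candidate fractions (default \code{seq(0, 0.99, 0.01)}).
#' @return List: \code{bdc}, \code{low_contrast} (TRUE when the maximal
#'   contrast is below 0.05, i.e. the site is barely distinguishable from
#'   ground), \code{curve} (data frame of beta, global and local
#'   correlations and their difference), \code{local_voxels}.
#' @export
estimate_bdc <- function(map_i, mu, blob, buffer = 1,
                         beta_grid = seq(0, 0.99, by = 0.01)) {
  check_same_grid(map_i, mu)
  if (!length(blob)) stop("empty blob")
  local_vox <- expand_voxel_set(map_i, blob, buffer)
  while (length(local_vox) < 20L) {
    buffer <- buffer + 0.5
    local_vox <- expand_voxel_set(map_i, blob, buffer)
  }
  x <- as.vector(map_i$values)
  g <- as.vector(mu$values)
  ok <- !is.na(x) & !is.na(g)
  is_local <- rep(FALSE, length(x)); is_local[local_vox] <- TRUE
  reg_stats <- function(sel) {
    xs <- x[sel]; gs <- g[sel]
    n <- length(xs)
    list(n = n, sxx = stats::var(gs), syy = stats::var(xs),
         sxy = stats::cov(xs, gs))
  }
  st_loc <- reg_stats(ok & is_local)
  st_glo <- reg_stats(ok & !is_local)
  corr_beta <- function(st, beta) {
    num <- st$sxy - beta * st$sxx
    den2 <- st$sxx * (st$syy - 2 * beta * st$sxy + beta^2 * st$sxx)
    ifelse(den2 <= 1e-24, NA_real_, num / sqrt(den2))
  }
  cg <- corr_beta(st_glo, beta_grid)
  cl <- corr_beta(st_loc, beta_grid)
  contrast <- cg - cl
  skipped <- is.na(contrast)
  if (any(skipped))
    warning(sum(skipped), " beta value(s) skipped (zero-variance region)")
  if (all(skipped)) stop("BDC estimation failed: all beta values degenerate")
  best <- which.max(ifelse(skipped, -Inf, contrast))  # first max: smallest beta
  list(bdc = beta_grid[best],
       low_contrast = max(contrast, na.rm = TRUE) < 0.05,
       curve = data.frame(beta = beta_grid, cor_global = cg,
                          cor_local = cl, contrast = contrast),
       local_voxels = local_vox)
}

#' Compute an event map
#'
#' \code{E = (map_i - bdc * mu) / (1 - bdc)}: the estimated changed-state
#' density after subtracting the BDC-weighted ground-state background.
#' \code{bdc = 0} returns the observed map unchanged; \code{bdc -> 1}
#' approaches a pure difference (Fo-Fo style) map and is excluded.
#'
#' @param map_i the dataset's aligned \code{\link{density_map}}.
#' @param mu the ensemble mean map.
#' @param bdc background density correction factor in [0, 1).
#' @return The event \code{\link{density_map}}.
#' @export
event_map <- function(map_i, mu, bdc) {
  check_same_grid(map_i, mu)
  if (!is.numeric(bdc) || length(bdc) != 1L || bdc < 0 || bdc >= 1)
    stop("bdc must be a single value in [0, 1)")
  density_map((map_i$values - bdc * mu$values) / (1 - bdc),
              spacing = map_i$spacing, origin = map_i$origin,
              label = sprintf("event map (BDC=%.2f): %s", bdc, map_i$label))
}

#' Tabulate events
#'
#' @param events list of \code{dd_event}s.
#' @param path optional CSV output path.
#' @return Data frame: dataset id, event index, centroid, peak Z, volume,
#'   BDC and 1-BDC.
#' @export
events_table <- function(events, path = NULL) {
  df <- if (!length(events)) {
    data.frame(dataset = character(), event = integer(), x = numeric(),
               y = numeric(), z = numeric(), peak_z = numeric(),
               volume = numeric(), bdc = numeric(), one_minus_bdc = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      dataset = vapply(events, `[[`, character(1), "dataset_id"),
      event = seq_along(events),
      x = vapply(events, function(e) e$centroid[1], numeric(1)),
      y = vapply(events, function(e) e$centroid[2], numeric(1)),
      z = vapply(events, function(e) e$centroid[3], numeric(1)),
      peak_z = vapply(events, `[[`, numeric(1), "peak_z"),
      volume = vapply(events, `[[`, numeric(1), "volume"),
      bdc = vapply(events, `[[`, numeric(1), "bdc"),
      one_minus_bdc = 1 - vapply(events, `[[`, numeric(1), "bdc"),
      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
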