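# Per-voxel normal-normal model of the ground-state density.  The observed
# density of dataset i at voxel m is modelled as
#
#   rho_{i,m} ~ N(mu_m, s_m^2 + sigma_i^2)
#
# where mu_m is the mean ground-state density, s_m the standard deviation
# of the "true" density across crystals (natural variation: crystal
# contacts, flexible loops), and sigma_i the measurement uncertainty of
# dataset i.  mu is the unweighted voxel mean; sigma_i is the central slope
# of a normal Q-Q plot of the dataset's mean-difference map; s_m is fitted
# by per-voxel maximum likelihood with sigma_i held fixed.  Standardized
# deviations Z = (rho - mu) / sqrt(sigma_i^2 + s_m^2) form the Z-map.

# Stack a list of maps (common grid) into an n_maps x n_voxels matrix.
map_stack <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  ref <- maps[[1]]
  for (m in maps) check_same_grid(ref, m)
  do.call(rbind, lapply(maps, function(m) as.vector(m$values)))
}

#' Voxel-wise unweighted mean of aligned maps
#'
#' Missing voxels are excluded per voxel; a voxel missing in more than half
#' of the maps is marked missing in the output.
#'
#' @param maps list of at least 2 \code{\link{density_map}}s on one grid.
#' @return The mean \code{\link{density_map}}.
#' @export
mean_map <- function(maps) {
  if (length(maps) < 2L) stop("mean_map needs at least 2 maps")
  X <- map_stack(maps)
  n_obs <- colSums(!is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  mu[n_obs <= length(maps) / 2] <- NA_real_
  mu[n_obs == 0L] <- NA_real_
  ref <- maps[[1]]
  density_map(array(mu, dim = dim(ref$values)), spacing = ref$spacing,
              origin = ref$origin, label = "mean map")
}

#' Dataset uncertainty from the central Q-Q slope of a difference map
#'
#' The difference map (dataset minus mean) is sorted and plotted against
#' standard-normal quantiles; the least-squares slope over the central
#' portion (theoretical quantiles in [-1.5, 1.5]) estimates the dataset's
#' per-voxel uncertainty sigma_i.  Using only the central quantiles makes
#' the estimate robust to the gross outliers (real signal) that motivate
#' the whole analysis.
#'
#' @param map_i the dataset's aligned \code{\link{density_map}}.
#' @param mu the mean map on the same grid.
#' @param qq_limit half-width of the central theoretical-quantile range
#'   (default 1.5).
#' @return The estimated sigma_i (same units as the map).
#' @export
estimate_sigma <- function(map_i, mu, qq_limit = 1.5) {
  check_same_grid(map_i, mu)
  d <- as.vector(map_i$values) - as.vector(mu$values)
  d <- d[!is.na(d)]
  if (length(d) < 1000L)
    stop("estimate_sigma needs >= 1000 non-missing voxels (got ",
         length(d), ")")
  q_theo <- stats::qnorm(stats::ppoints(length(d)))
  d <- sort(d)
  central <- abs(q_theo) <= qq_limit
  if (sum(central) < 100L)
    stop("fewer than 100 points in the central Q-Q region")
  x <- q_theo[central]; y <- d[central]
  # OLS slope with intercept
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# log-likelihood of s (sd of natural variation) given residuals and sigmas
loglik_s <- function(s, resid, sigma) {
  v <- s^2 + sigma^2
  -0.5 * sum(log(2 * pi * v) + resid^2 / v)
}

#' Maximum-likelihood natural variation at one voxel
#'
#' Maximizes the marginal likelihood of \code{s >= 0} in
#' \code{rho_i ~ N(mu_m, s^2 + sigma_i^2)} by bounded 1-D search; returns
#' 0 when the likelihood is maximized at the boundary (observed spread
#' fully explained by the per-dataset uncertainties).
#'
#' @param values densities of the characterization datasets at the voxel.
#' @param mu_m mean density at the voxel.
#' @param sigma per-dataset uncertainties, matching \code{values}.
#' @param tol convergence tolerance of the search (default 1e-6).
#' @return The ML estimate s_m >= 0.
#' @export
estimate_s <- function(values, mu_m, sigma, tol = 1e-6) {
  if (length(values) < 2L) stop("estimate_s needs >= 2 values")
  if (length(sigma) != length(values)) stop("sigma must match values")
  if (any(!is.finite(values)) || !is.finite(mu_m) || any(!is.finite(sigma)))
    stop("non-finite inputs to estimate_s")
  resid <- values - mu_m
  upper <- 10 * max(stats::sd(values), max(sigma), 1e-12)
  opt <- stats::optimize(function(s) loglik_s(s, resid, sigma),
                         interval = c(0, upper), maximum = TRUE, tol = tol)
  if (loglik_s(0, resid, sigma) >= opt$objective) 0 else opt$maximum
}

# Vectorized ML fit of s_m across all voxels.
# The stationarity condition in u = s^2 is
#   g(u) = sum_i [ (rho_i - mu)^2 - (u + sigma_i^2) ] / (u + sigma_i^2)^2 = 0 ;
# g(0) <= 0 means the boundary u = 0 is the maximum; otherwise the root is
# bracketed in [0, u_max] and found by vectorized bisection.
estimate_s_map <- function(X, mu, sigma, n_iter = 50L) {
  R2 <- sweep(X, 2L, mu)^2                    # squared residuals, n x V
  miss <- is.na(R2)
  R2[miss] <- 0
  sig2 <- sigma^2
  V <- ncol(R2)
  u_hat <- numeric(V)
  g0 <- gfun_subset(R2, miss, sig2, numeric(V), seq_len(V))
  active <- which(g0 > 0)
  if (length(active)) {
    lo <- numeric(length(active))
    # g(u) <= 0 once u >= max_i resid_i^2, so the column max brackets the root
    hi <- R2[1L, active]
    for (i in seq_len(nrow(R2))[-1L]) hi <- pmax(hi, R2[i, active])
    hi <- hi + 1e-12
    for (it in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      pos <- gfun_subset(R2, miss, sig2, mid, active) > 0
      lo[pos] <- mid[pos]
      hi[!pos] <- mid[!pos]
    }
    u_hat[active] <- (lo + hi) / 2
  }
  sqrt(pmax(u_hat, 0))
}

# One-step jackknife (leave-one-out) correction of the natural-variation
# fit.  When a dataset is standardized against an ensemble that includes
# itself, its own residuals enter the per-voxel variance estimate with
# weight 1/sigma_i^4; for low-noise datasets this couples s_m to the
# dataset's own noise and deflates its Z-scores (the classic argument for
# externally studentized residuals).  Removing dataset i's score term and
# taking one Newton step from the shared root gives u_{-i} at the cost of
# a single score evaluation.
estimate_s_loo <- function(X, mu, sigma, u_star) {
  R2 <- sweep(X, 2L, mu)^2
  miss <- is.na(R2)
  R2[miss] <- 0
  n <- nrow(R2); V <- ncol(R2)
  D <- matrix(u_star, n, V, byrow = TRUE) + sigma^2
  g_terms <- (R2 - D) / D^2
  gp_terms <- -(D + 2 * (R2 - D)) / D^3
  g_terms[miss] <- 0
  gp_terms[miss] <- 0
  G <- colSums(g_terms)        # ~0 at interior roots, <= 0 at the boundary
  Gp <- colSums(gp_terms)
  s_loo <- matrix(0, n, V)
  for (i in seq_len(n)) {
    H <- G - g_terms[i, ]
    Hp <- Gp - gp_terms[i, ]
    step <- ifelse(Hp < 0, H / Hp, 0)
    u_i <- u_star - step
    # boundary: no evidence of extra variance without dataset i
    u_i[u_star <= 0 & H <= 0] <- 0
    s_loo[i, ] <- sqrt(pmax(u_i, 0))
  }
  rownames(s_loo) <- rownames(X)
  s_loo
}

# g(u) restricted to a subset of voxels (keeps the bisection memory-lean)
gfun_subset <- function(R2, miss, sig2, u, cols) {
  R2s <- R2[, cols, drop = FALSE]
  ms <- miss[, cols, drop = FALSE]
  den <- matrix(u, nrow(R2s), length(u), byrow = TRUE) + sig2
  g <- (R2s - den) / den^2
  g[ms] <- 0
  colSums(g)
}

#' Fit the ensemble statistical model
#'
#' Estimates the mean map mu, per-dataset uncertainties sigma_i and the
#' natural-variation map s from a set of aligned characterization maps.
#'
#' @param maps named list of aligned \code{\link{density_map}}s (the
#'   characterization set; >= 2 maps).
#' @return An object of class \code{statistical_model} with fields
#'   \code{mu} (mean map), \code{s} (natural-variation sd map),
#'   \code{sigma} (named per-dataset uncertainties) and \code{n_char}.
#' @export
fit_statistical_model <- function(maps) {
  if (length(maps) < 2L)
    stop("the model is underdetermined with fewer than 2 maps")
  if (length(maps) < 30L)
    warning("only ", length(maps), " characterization datasets; ",
            "around 30 are typically required for full convergence ",
            "of the ensemble model")
  ids <- names(maps)
  if (is.null(ids)) ids <- as.character(seq_along(maps))
  mu <- mean_map(maps)
  sigma <- vapply(maps, function(m) estimate_sigma(m, mu), numeric(1))
  names(sigma) <- ids
  X <- map_stack(maps)
  rownames(X) <- ids
  muv <- as.vector(mu$values)
  ok <- !is.na(muv)
  s <- rep(NA_real_, length(muv))
  s[ok] <- estimate_s_map(X[, ok, drop = FALSE], muv[ok], sigma)
  smap <- density_map(array(s, dim = dim(mu$values)), spacing = mu$spacing,
                      origin = mu$origin, label = "natural variation (s)")
  # leave-one-out corrected s for standardizing ensemble members against
  # an ensemble that excludes themselves (externally studentized Z)
  s_loo <- matrix(NA_real_, length(maps), length(muv), dimnames =
                    list(ids, NULL))
  s_loo[, ok] <- estimate_s_loo(X[, ok, drop = FALSE], muv[ok], sigma,
                                s[ok]^2)
  structure(list(mu = mu, s = smap, sigma = sigma,
                 s_loo = s_loo,
                 n_char = length(maps)),
            class = "statistical_model")
}

#' @export
print.statistical_model <- function(x, ...) {
  cat(sprintf("statistical_model: %d characterization datasets\n", x$n_char))
  cat(sprintf("  sigma_i: %.4g - %.4g; s > 0 at %.1f%% of voxels\n",
              min(x$sigma), max(x$sigma),
              100 * mean(x$s$values > 1e-9, na.rm = TRUE)))
  invisible(x)
}

#' Z-map: standardized deviation of a dataset from the ensemble
#'
#' \code{Z_m = (rho_m - mu_m) / sqrt(sigma_i^2 + s_m^2)}.  Large |Z| marks
#' voxels where the dataset deviates significantly from the ground-state
#' ensemble.  Missing voxels propagate as missing.
#'
#' When the dataset is itself a member of the characterization ensemble
#' (its \code{id} is known to the model) the natural-variation term is, by
#' default, the leave-one-out corrected estimate that excludes the
#' dataset's own contribution: standardizing a dataset against statistics
#' it helped estimate deflates its own Z-scores, most visibly for the
#' lowest-noise dataset of the ensemble.
#'
#' @param map_i the dataset's aligned \code{\link{density_map}}.
#' @param model a \code{\link{fit_statistical_model}} result.
#' @param sigma_i the dataset's uncertainty; taken from \code{model$sigma}
#'   by \code{id} if omitted.
#' @param id dataset id; also selects the leave-one-out s estimate when
#'   the dataset belongs to the characterization ensemble.
#' @param exclude_self use the leave-one-out s for ensemble members
#'   (default TRUE; ignored when \code{id} is unknown to the model).
#' @return A \code{\link{density_map}} of Z-scores (class also
#'   \code{zmap}).
#' @export
zmap <- function(map_i, model, sigma_i = NULL, id = NULL,
                 exclude_self = TRUE) {
  stopifnot(inherits(model, "statistical_model"))
  check_same_grid(map_i, model$mu)
  if (is.null(sigma_i)) {
    if (is.null(id) || !id %in% names(model$sigma))
      stop("supply sigma_i or an id present in model$sigma")
    sigma_i <- model$sigma[[id]]
  }
  s2 <- model$s$values^2
  if (exclude_self && !is.null(id) && !is.null(model$s_loo) &&
      id %in% rownames(model$s_loo))
    s2 <- array(model$s_loo[id, ]^2, dim = dim(model$s$values))
  denom2 <- sigma_i^2 + s2
  observed <- !is.na(map_i$values) & !is.na(model$mu$values) &
    !is.na(denom2)
  if (any(denom2[observed] <= 0)) {
    vox <- which(denom2 <= 0 & observed)[1]
    stop("degenerate variance (sigma_i^2 + s_m^2 = 0) at voxel ",
         paste(arrayInd(vox, dim(map_i$values)), collapse = ","))
  }
  z <- (map_i$values - model$mu$values) / sqrt(denom2)
  out <- density_map(z, spacing = map_i$spacing, origin = map_i$origin,
                     label = paste0("Z-map: ", map_i$label))
  class(out) <- c("zmap", class(out))
  out
}

#' Check the normality calibration of a Z-map
#'
#' A correctly calibrated ground-state Z-map should be approximately
#' standard normal: mean near 0, sd near 1, and about 1.2 percent of
#' voxels beyond |Z| = 2.5.  Gross mis-calibration (e.g. maps produced
#' against a badly wrong reference) shows up as an inflated sd or a heavy
#' tail.
#'
#' @param z a \code{\link{zmap}}.
#' @param mean_tol,sd_lo,sd_hi,max_tail_frac calibration bounds (defaults
#'   0.05, 0.9, 1.1, 0.02).
#' @return List: \code{mean}, \code{sd}, \code{frac_extreme} (fraction
#'   with |Z| > 2.5) and \code{ok}.
#' @export
check_z_calibration <- function(z, mean_tol = 0.05, sd_lo = 0.9,
                                sd_hi = 1.1, max_tail_frac = 0.02) {
  v <- as.vector(z$values)
  v <- v[!is.na(v)]
  m <- mean(v); s <- stats::sd(v); fe <- mean(abs(v) > 2.5)
  list(mean = m, sd = s, frac_extreme = fe,
       ok = abs(m) <= mean_tol && s >= sd_lo && s <= sd_hi &&
         fe <= max_tail_frac)
}

#' Export the per-dataset uncertainty table
#'
#' @param model a \code{statistical_model}.
#' @param resolutions optional named resolutions to include.
#' @param path optional CSV output path.
#' @return Data frame with columns \code{id}, \code{resolution},
#'   \code{sigma}.
#' @export
sigma_table <- function(model, resolutions = NULL, path = NULL) {
  df <- data.frame(id = names(model$sigma),
                   resolution = if (is.null(resolutions)) NA_real_
                                else as.numeric(resolutions[names(model$sigma)]),
                   sigma = as.numeric(model$sigma),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
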