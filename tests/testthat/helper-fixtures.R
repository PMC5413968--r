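# Shared fixtures and independent oracles.  Oracles deliberately use
# different algorithms from the implementation they check (breadth-first
# flood fill vs union-find; Euler-angle search vs SVD; dense grid scan vs
# Brent search).

zero_map <- function(n = 16, spacing = 0.5, origin = c(0, 0, 0)) {
  density_map(array(0, rep(n, 3)), spacing, origin)
}

random_map <- function(n = 12, spacing = 0.5, na_frac = 0) {
  v <- array(rnorm(n^3), rep(n, 3))
  if (na_frac > 0) v[sample(length(v), round(na_frac * length(v)))] <- NA
  density_map(v, spacing, origin = runif(3, -5, 5))
}

# straight-ish CA chain along x with small wobble
toy_chain <- function(n = 12, chain = "A", wobble = 0.3, b = 20,
                      start = c(2, 8, 8)) {
  pos <- cbind(start[1] + 3.8 * (seq_len(n) - 1),
               start[2] + wobble * sin(seq_len(n)),
               start[3] + wobble * cos(seq_len(n)))
  structure_model(data.frame(
    chain = chain, resno = seq_len(n), resname = "ALA", atom = "CA",
    element = "C", altloc = "", x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occ = 1, b = b, stringsAsFactors = FALSE))
}

# compact alpha-helix-like CA chain (fits small grids)
toy_helix <- function(n = 10, centre = c(8, 8, 4), b = 20) {
  th <- (seq_len(n) - 1) * 100 * pi / 180
  structure_model(data.frame(
    chain = "A", resno = seq_len(n), resname = "ALA", atom = "CA",
    element = "C", altloc = "",
    x = centre[1] + 2.3 * cos(th),
    y = centre[2] + 2.3 * sin(th),
    z = centre[3] + 1.5 * (seq_len(n) - 1),
    occ = 1, b = b, stringsAsFactors = FALSE))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

transform_model <- function(model, R, t) {
  model[, c("x", "y", "z")] <- sweep(coords(model) %*% t(R), 2L, -t)
  model
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# oracle: best rigid-fit rmsd by direct search over Euler angles
# (coarse grid then Nelder-Mead), independent of the SVD route
oracle_superpose_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2L, colMeans(P)); Qc <- sweep(Q, 2L, colMeans(Q))
  rmsd_of <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 7),
                      c = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1L, rmsd_of)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, rmsd_of, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}

# oracle: 26-connected components by breadth-first flood fill
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  comps <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (start in which(mask)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    members <- integer()
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      ci <- arrayInd(cur, d)
      nb <- sweep(offs, 2L, -as.vector(ci))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
      lin <- lin[mask[lin] & !visited[lin]]
      visited[lin] <- TRUE
      queue <- c(queue, lin)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# canonical form for comparing component partitions
canonical_components <- function(comps) {
  comps <- lapply(unname(comps), function(x) as.integer(sort(unname(x))))
  comps[order(vapply(comps, `[`, integer(1), 1))]
}

# oracle: dense grid scan of the s log-likelihood
oracle_s_grid <- function(values, mu, sigma, n_grid = 1000) {
  resid <- values - mu
  upper <- 10 * max(sd(values), max(sigma), 1e-12)
  ss <- seq(0, upper, length.out = n_grid)
  ll <- vapply(ss, function(s) {
    v <- s^2 + sigma^2
    -0.5 * sum(log(2 * pi * v) + resid^2 / v)
  }, numeric(1))
  ss[which.max(ll)]
}

# small synthetic screen shared by several tests
small_screen <- function(n_ground = 12, n = 32, events = list(), seed = 42,
                         resolution = c(1.8, 1.8), ...) {
  simulate_screen(synthetic_config(
    n_ground = n_ground, grid_dim = rep(n, 3), spacing = 0.6,
    resolution_range = resolution, events = events, seed = seed, ...))
}

# oracle min distance between point sets (plain double loop)
min_set_distance_oracle <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sum((A[i, ] - B[j, ])^2))
  sqrt(best)
}
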