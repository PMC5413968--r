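# Synthetic screen generator: the fixtures must actually have the
# statistical structure the ensemble model assumes.

test_that("density from atoms: empty model, unit integral, linearity", {
  grid <- zero_map(24, spacing = 0.4)
  expect_true(all(density_from_atoms(structure_model(), grid)$values == 0))
  one <- structure_model(data.frame(
    chain = "A", resno = 1, resname = "ALA", atom = "CA", element = "C",
    altloc = "", x = 4.8, y = 4.8, z = 4.8, occ = 1, b = 25,
    stringsAsFactors = FALSE))
  m1 <- density_from_atoms(one, grid)
  expect_equal(sum(m1$values) * voxel_volume(m1), 6, tolerance = 0.01)
  two <- one
  two$x <- 3.0; two$resno <- 2
  m2 <- density_from_atoms(two, grid)
  both <- structure_model(rbind(as.data.frame(one), as.data.frame(two)))
  m12 <- density_from_atoms(both, grid)
  expect_lt(max(abs(m12$values - (m1$values + m2$values))), 1e-10)
  # occupancy scales amplitude
  half <- one; half$occ <- 0.5
  expect_equal(density_from_atoms(half, grid)$values, m1$values / 2,
               tolerance = 1e-12)
  outside <- one; outside$x <- 100
  expect_error(density_from_atoms(outside, grid), "outside")
})

test_that("the same seed reproduces the screen bit for bit", {
  cfg <- synthetic_config(n_ground = 3, grid_dim = c(16, 16, 16),
                          events = list(event_spec(0.5)), seed = 9)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  for (i in seq_along(a$datasets))
    expect_identical(a$datasets[[i]]$map$values, b$datasets[[i]]$map$values)
  expect_identical(a$truth$sigma, b$truth$sigma)
  # and a different seed does not
  cfg2 <- synthetic_config(n_ground = 3, grid_dim = c(16, 16, 16),
                           events = list(event_spec(0.5)), seed = 10)
  c <- simulate_screen(cfg2)
  expect_false(identical(a$datasets[[1]]$map$values,
                         c$datasets[[1]]$map$values))
})

test_that("in the noise-free limit all ground maps equal the truncated mu", {
  cfg <- synthetic_config(n_ground = 3, grid_dim = c(20, 20, 20),
                          sigma_range = c(1e-9, 1.1e-9),
                          resolution_range = c(1.8, 1.8),
                          n_variable_regions = 0, seed = 12)
  sim <- simulate_screen(cfg)
  mu_trunc <- lowpass_truncate(sim$truth$mu, 1.8)
  for (ds in sim$datasets)
    expect_lt(max(abs(ds$map$values - mu_trunc$values)), 1e-6)
})

test_that("an event map mixes ground and changed density by occupancy", {
  cfg <- synthetic_config(n_ground = 2, grid_dim = c(20, 20, 20),
                          sigma_range = c(1e-9, 1.1e-9),
                          resolution_range = c(1.8, 1.8),
                          n_variable_regions = 0,
                          events = list(event_spec(0.4)), seed = 13)
  sim <- simulate_screen(cfg)
  ev <- sim$truth$events[[1]]
  ds <- sim$datasets[[3]]
  expect_equal(ds$id, ev$dataset_id)
  expect_equal(ds$role, "changed")
  mix <- 0.6 * sim$truth$mu$values + 0.4 * ev$nu$values
  mixed <- density_map(mix, 0.6)
  expect_lt(max(abs(ds$map$values - lowpass_truncate(mixed, 1.8)$values)),
            1e-6)
})

test_that("empirical voxel variance matches the model marginal", {
  cfg <- synthetic_config(n_ground = 60, grid_dim = c(20, 20, 20),
                          sigma_range = c(0.1, 0.1001),
                          resolution_range = c(1.8, 1.8),
                          n_variable_regions = 1, s_value = 0.3,
                          s_radius = 2.5, seed = 14)
  sim <- simulate_screen(cfg)
  X <- sapply(sim$datasets, function(d) as.vector(d$map$values))
  v <- apply(X, 1L, var)
  s_vox <- as.vector(sim$truth$s$values)
  sig_eff <- mean(sim$truth$sigma)   # all equal by construction
  # outside variable regions the marginal variance is sigma_eff^2
  outside <- s_vox == 0
  expect_equal(mean(v[outside]), sig_eff^2, tolerance = 0.05)
  # inside, the natural variation adds (also band-limited by truncation)
  inside <- s_vox > 0
  expect_gt(mean(v[inside]), 2 * mean(v[outside]))
})

test_that("the Q-Q estimator recovers each dataset's effective noise", {
  sim <- small_screen(n_ground = 20, n = 24, seed = 15,
                      n_variable_regions = 0)
  maps <- lapply(sim$datasets, function(d) d$map)
  names(maps) <- names(sim$truth$sigma)
  model <- suppressWarnings(fit_statistical_model(maps))
  rel_err <- abs(model$sigma - sim$truth$sigma) / sim$truth$sigma
  expect_lt(max(rel_err), 0.10)
})

test_that("an injected 0.4-occupancy event is detected at the true site", {
  sim <- small_screen(n_ground = 40, n = 32, seed = 16,
                      events = list(event_spec(0.4)))
  maps <- lapply(sim$datasets, function(d) d$map)
  names(maps) <- vapply(sim$datasets, `[[`, character(1), "id")
  truth_ev <- sim$truth$events[[1]]
  ground_ids <- setdiff(names(maps), truth_ev$dataset_id)
  model <- suppressWarnings(fit_statistical_model(maps[ground_ids]))
  z <- zmap(maps[[truth_ev$dataset_id]], model,
            sigma_i = estimate_sigma(maps[[truth_ev$dataset_id]], model$mu))
  evs <- find_blobs(z, dataset_id = truth_ev$dataset_id)
  expect_gte(length(evs), 1)
  found <- evs[[1]]$voxels
  true_vox <- which(truth_ev$blob_mask)
  jaccard <- length(intersect(found, true_vox)) /
    length(union(found, true_vox))
  expect_gt(jaccard, 0.3)
})

test_that("rigid jitter moves model and map consistently", {
  cfg <- synthetic_config(n_ground = 4, grid_dim = c(28, 28, 28),
                          sigma_range = c(0.01, 0.0101),
                          resolution_range = c(1.8, 1.8),
                          n_variable_regions = 0,
                          jitter_translation = 0.4, jitter_rotation = 2,
                          seed = 17)
  sim <- simulate_screen(cfg)
  for (ds in sim$datasets) {
    dens <- density_from_atoms(ds$model, ds$map, blur = resolution_blur(1.8))
    dens <- lowpass_truncate(dens, 1.8)
    keep <- dens$values > 0.2 * max(dens$values)
    expect_gt(cor(ds$map$values[keep], dens$values[keep]), 0.98)
  }
})

test_that("degrading with zero jitter or weight is the identity", {
  sim <- small_screen(n_ground = 3, n = 16, seed = 18)
  same <- degrade_reference(sim$datasets, jitter = 0)
  expect_identical(same[[1]]$map$values, sim$datasets[[1]]$map$values)
  same2 <- degrade_reference(sim$datasets, jitter = 1, weight = 0)
  expect_identical(same2[[2]]$map$values, sim$datasets[[2]]$map$values)
})

test_that("moderate degradation keeps the event detectable while the raw
           model-difference map no longer isolates it", {
  sim <- small_screen(n_ground = 15, n = 32, seed = 19,
                      events = list(event_spec(0.5)))
  deg <- degrade_reference(sim$datasets, jitter = 0.4, weight = 0.3,
                           seed = 19)
  maps <- lapply(deg, function(d) d$map)
  names(maps) <- vapply(deg, `[[`, character(1), "id")
  truth_ev <- sim$truth$events[[1]]
  ground_ids <- setdiff(names(maps), truth_ev$dataset_id)
  model <- suppressWarnings(fit_statistical_model(maps[ground_ids]))
  mi <- maps[[truth_ev$dataset_id]]
  z <- zmap(mi, model, sigma_i = estimate_sigma(mi, model$mu))
  evs <- find_blobs(z, dataset_id = truth_ev$dataset_id)
  expect_gte(length(evs), 1)
  true_vox <- which(truth_ev$blob_mask)
  expect_gt(length(intersect(evs[[1]]$voxels, true_vox)), 0)
  # arm 2: the plain difference against the degraded model density is a
  # much poorer detector: its strongest deviations are not at the event
  bad_dens <- density_from_atoms(deg[[1]]$model, mi,
                                 blur = resolution_blur(1.8))
  raw_diff <- abs(mi$values - bad_dens$values)
  top <- order(raw_diff, decreasing = TRUE)[seq_along(true_vox)]
  frac_at_event <- length(intersect(top, true_vox)) / length(true_vox)
  expect_lt(frac_at_event, 0.5)
})

test_that("severe degradation is caught by the Z calibration check", {
  sim <- small_screen(n_ground = 8, n = 24, seed = 20)
  deg <- degrade_reference(sim$datasets, jitter = 1.5, weight = 1, seed = 20)
  # maps replaced by a wrong model's density: compare against the honest
  # ensemble of the *original* screen
  maps <- lapply(sim$datasets, function(d) d$map)
  names(maps) <- vapply(sim$datasets, `[[`, character(1), "id")
  model <- suppressWarnings(fit_statistical_model(maps))
  bad <- deg[[1]]$map
  z <- zmap(bad, model, sigma_i = model$sigma[[1]])
  expect_false(check_z_calibration(z)$ok)
})
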