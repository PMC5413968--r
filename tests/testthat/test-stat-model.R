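# Ensemble statistical model: mean map, Q-Q sigma estimator, ML natural
# variation, Z-maps.

make_maps <- function(n, nvox = 16, mu_fun = function(v) 0, sigma = 0.1,
                      spacing = 0.5) {
  base <- array(mu_fun(seq_len(nvox^3)), rep(nvox, 3))
  lapply(seq_len(n), function(i)
    density_map(base + array(rnorm(nvox^3, sd = sigma), rep(nvox, 3)),
                spacing))
}

test_that("mean of identical maps is any input; simple averages are exact", {
  m <- random_map(8)
  expect_equal(mean_map(list(m, m, m))$values, m$values)
  z <- zero_map(8); two <- zero_map(8); two$values[] <- 2
  expect_equal(mean_map(list(z, two))$values, array(1, c(8, 8, 8)))
  expect_error(mean_map(list(m)), "at least 2")
})

test_that("voxels missing in more than half the maps go missing; others
           average the observed values", {
  m1 <- zero_map(8); m2 <- zero_map(8); m3 <- zero_map(8)
  m1$values[1, 1, 1] <- NA; m2$values[1, 1, 1] <- NA
  m2$values[2, 2, 2] <- NA
  m1$values[3, 3, 3] <- 3
  mu <- mean_map(list(m1, m2, m3))
  expect_true(is.na(mu$values[1, 1, 1]))     # missing in 2/3
  expect_equal(mu$values[2, 2, 2], 0)        # missing in 1/3: mean of rest
  expect_equal(mu$values[3, 3, 3], 1)
})

test_that("the voxel mean concentrates on truth at the CLT rate", {
  set.seed(30)
  sigma <- 0.2
  maps <- make_maps(40, nvox = 20, mu_fun = function(v) sin(v / 1000),
                    sigma = sigma)
  mu <- mean_map(maps)
  truth <- array(sin(seq_len(20^3) / 1000), rep(20, 3))
  frac_in <- mean(abs(mu$values - truth) <= 3 * sigma / sqrt(40))
  expect_gte(frac_in, 0.99)
})

test_that("sigma of a dataset equal to the mean is zero", {
  m <- random_map(12)
  expect_equal(estimate_sigma(m, m), 0)
})

test_that("the Q-Q slope recovers a known normal noise sd", {
  set.seed(31)
  mu <- zero_map(64, spacing = 0.5)
  mi <- density_map(array(rnorm(64^3, sd = 0.25), rep(64, 3)), 0.5)
  expect_equal(estimate_sigma(mi, mu), 0.25, tolerance = 0.01 / 0.25)
})

test_that("the central-quantile slope resists gross outliers where the
           naive sd does not", {
  set.seed(32)
  n <- 48^3
  d <- rnorm(n)
  out <- sample(n, round(0.01 * n))
  d[out] <- sample(c(-10, 10), length(out), replace = TRUE)
  mu <- zero_map(48, spacing = 0.5)
  mi <- density_map(array(d, rep(48, 3)), 0.5)
  s_qq <- estimate_sigma(mi, mu)
  expect_lt(abs(s_qq - 1), 0.05)
  expect_gt(sd(d), 1.35)   # the naive estimator is badly inflated
})

test_that("estimate_sigma enforces its minimum data requirements", {
  small <- density_map(array(0, c(5, 5, 5)), 1)
  expect_error(estimate_sigma(small, small), "1000")
})

test_that("homoscedastic ML natural variation matches the closed form", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    sigma <- runif(1, 0.05, 0.5)
    vals <- rnorm(n, sd = runif(1, 0.1, 1))
    mu <- mean(vals)
    closed <- sqrt(max(0, mean((vals - mu)^2) - sigma^2))
    est <- estimate_s(vals, mu, rep(sigma, n))
    expect_equal(est, closed, tolerance = 1e-6 + 1e-6 * max(closed, 1))
  }
})

test_that("spread fully explained by dataset uncertainty gives s = 0", {
  vals <- c(-0.05, 0.02, 0.01, -0.03, 0.05)
  expect_identical(estimate_s(vals, mean(vals), rep(0.5, 5)), 0)
})

test_that("the bounded search agrees with a dense likelihood grid scan", {
  set.seed(34)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    sigma <- runif(n, 0.05, 0.4)
    s_true <- runif(1, 0, 0.8)
    vals <- rnorm(n, sd = sqrt(s_true^2 + sigma^2))
    est <- estimate_s(vals, 0, sigma)
    grid <- oracle_s_grid(vals, 0, sigma)
    # grid resolution limits the oracle itself; allow one grid step
    step <- 10 * max(sd(vals), max(sigma)) / 999
    expect_lt(abs(est - grid), step + 1e-4)
  }
})

test_that("heteroscedastic ML recovers the true s on average", {
  set.seed(35)
  s_true <- 0.5
  ests <- replicate(200, {
    sigma <- runif(30, 0.1, 0.4)
    vals <- rnorm(30, sd = sqrt(s_true^2 + sigma^2))
    estimate_s(vals, 0, sigma)
  })
  expect_lt(abs(mean(ests) - s_true) / s_true, 0.25)
})

test_that("whole-map s fit agrees with the per-voxel scalar search", {
  set.seed(36)
  n <- 12; V <- 200
  sigma <- runif(n, 0.05, 0.3)
  s_field <- c(rep(0, V / 2), runif(V / 2, 0.1, 0.6))
  X <- sapply(seq_len(V), function(v)
    rnorm(n, sd = sqrt(s_field[v]^2 + sigma^2)))
  shat_map <- densdelta:::estimate_s_map(X, rep(0, V), sigma)
  shat_scalar <- vapply(seq_len(V), function(v)
    estimate_s(X[, v], 0, sigma), numeric(1))
  expect_lt(max(abs(shat_map - shat_scalar)), 1e-4)
})

test_that("Z of the mean itself is zero and simple Z values are exact", {
  maps <- make_maps(5, nvox = 12, sigma = 0.2)
  model <- suppressWarnings(fit_statistical_model(maps))
  z0 <- zmap(model$mu, model, sigma_i = 1)
  expect_lt(max(abs(z0$values), na.rm = TRUE), 1e-12)
  # rho - mu = 1, sigma = 1, s = 0 -> Z = 1
  one <- model$mu; one$values <- one$values + 1
  model0 <- model; model0$s$values[] <- 0
  z1 <- zmap(one, model0, sigma_i = 1)
  expect_equal(max(abs(z1$values - 1)), 0, tolerance = 1e-12)
})

test_that("degenerate zero variance raises an error naming the voxel", {
  maps <- make_maps(4, nvox = 12, sigma = 0.1)
  model <- suppressWarnings(fit_statistical_model(maps))
  model$s$values[] <- 0
  expect_error(zmap(maps[[1]], model, sigma_i = 0), "degenerate|voxel")
})

test_that("adding a constant to every map shifts mu only", {
  set.seed(37)
  maps <- make_maps(8, nvox = 12, sigma = 0.15)
  model <- suppressWarnings(fit_statistical_model(maps))
  shifted <- lapply(maps, function(m) {
    m$values <- m$values + 2.5
    m
  })
  model2 <- suppressWarnings(fit_statistical_model(shifted))
  expect_equal(model2$mu$values, model$mu$values + 2.5, tolerance = 1e-9)
  expect_equal(model2$sigma, model$sigma, tolerance = 1e-9)
  expect_equal(model2$s$values, model$s$values, tolerance = 1e-6)
  z1 <- zmap(maps[[1]], model, sigma_i = model$sigma[[1]])
  z2 <- zmap(shifted[[1]], model2, sigma_i = model2$sigma[[1]])
  expect_equal(z2$values, z1$values, tolerance = 1e-6)
})

test_that("ground-state Z-maps are calibrated and outlier-sparse", {
  sim <- small_screen(n_ground = 40, n = 24, seed = 55)
  maps <- lapply(sim$datasets, function(d) d$map)
  names(maps) <- vapply(sim$datasets, `[[`, character(1), "id")
  model <- suppressWarnings(fit_statistical_model(maps))
  fracs <- vapply(names(maps)[1:5], function(id) {
    z <- zmap(maps[[id]], model, id = id)
    chk <- check_z_calibration(z)
    expect_true(chk$ok)
    chk$frac_extreme
  }, numeric(1))
  expect_true(all(fracs <= 0.02))
})

test_that("sigma estimates converge as the ensemble grows", {
  set.seed(38)
  sigma_true <- 0.2
  med_err <- vapply(c(5, 10, 20, 40), function(n) {
    maps <- make_maps(n, nvox = 14, sigma = sigma_true)
    mu <- mean_map(maps)
    errs <- vapply(maps, function(m)
      abs(estimate_sigma(m, mu) - sigma_true), numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("the model refuses underdetermined input and warns when small", {
  expect_error(fit_statistical_model(list(random_map(8))), "2")
  maps <- make_maps(3, nvox = 12)
  expect_warning(fit_statistical_model(maps), "30")
})
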