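# Ensemble merging, changed-state extraction, validation metrics.

lig_model <- function(n = 4, centre = c(6, 6, 6), b = 20, spread = 1.2) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  structure_model(data.frame(
    chain = "L", resno = 1, resname = "LIG", atom = paste0("C", seq_len(n)),
    element = "C", altloc = "",
    x = centre[1] + spread * cos(th), y = centre[2] + spread * sin(th),
    z = centre[3] + 0.2 * seq_len(n), occ = 1, b = b,
    stringsAsFactors = FALSE))
}

test_that("merging identical states yields only shared atoms", {
  g <- toy_chain(8)
  ens <- merge_ensemble(g, g, bdc = 0.7)
  expect_true(all(ens$model$altloc == ""))
  expect_equal(nrow(ens$model), nrow(g))
})

test_that("q follows 2*(1 - BDC) with the documented clamp", {
  g <- toy_chain(8)
  ens <- merge_ensemble(g, g, bdc = 0.8)
  expect_equal(ens$q, 0.4)
  expect_equal(merge_ensemble(g, g, bdc = 0.99)$q, 0.05)  # clamp low
  expect_equal(merge_ensemble(g, g, bdc = 0.3)$q, 1.0)    # clamp high
})

test_that("a water replaced by a ligand atom splits into paired conformers
           whose occupancies sum to one", {
  g <- toy_chain(6)
  wat <- data.frame(chain = "S", resno = 100, resname = "HOH", atom = "O",
                    element = "O", altloc = "", x = 10, y = 8, z = 8,
                    occ = 1, b = 30, stringsAsFactors = FALSE)
  ground <- structure_model(rbind(as.data.frame(g), wat))
  lig <- data.frame(chain = "L", resno = 1, resname = "LIG", atom = "C1",
                    element = "C", altloc = "", x = 10.2, y = 8, z = 8,
                    occ = 1, b = 25, stringsAsFactors = FALSE)
  changed <- structure_model(rbind(as.data.frame(g), lig))
  ens <- merge_ensemble(ground, changed, bdc = 0.8)
  m <- ens$model
  w <- m[m$resname == "HOH", ]
  l <- m[m$resname == "LIG", ]
  expect_equal(w$altloc, ens$ground_conformer)
  expect_equal(l$altloc, ens$changed_conformer)
  expect_equal(w$occ + l$occ, 1, tolerance = 1e-9)
  expect_equal(l$occ, ens$q)
})

test_that("moved atoms get both conformers; occupancy always sums to one", {
  set.seed(50)
  for (bdc in c(0.1, 0.5, 0.75, 0.9)) {
    g <- toy_chain(10)
    ch <- g
    ch[3, c("x", "y", "z")] <- ch[3, c("x", "y", "z")] + 0.5  # moved
    ch[7, c("x", "y", "z")] <- ch[7, c("x", "y", "z")] + 0.05 # within tol
    ens <- merge_ensemble(g, ch, bdc = bdc)
    m <- ens$model
    gc <- m[m$altloc == ens$ground_conformer, ]
    cc <- m[m$altloc == ens$changed_conformer, ]
    expect_equal(nrow(gc), 1)   # residue 3 only
    expect_equal(nrow(cc), 1)
    expect_equal(gc$occ + cc$occ, 1, tolerance = 1e-9)
    expect_equal(sum(m$altloc == ""), 9)
  }
})

test_that("merge then extract returns the changed model", {
  g <- toy_chain(8)
  ch <- g
  ch[2, c("x", "y", "z")] <- ch[2, c("x", "y", "z")] + 1.0
  full_ch <- structure_model(rbind(as.data.frame(ch),
                                   as.data.frame(lig_model())))
  ens <- merge_ensemble(g, full_ch, bdc = 0.6)
  back <- extract_changed_state(ens)
  idx <- match(atom_key(full_ch, with_altloc = FALSE),
               atom_key(back, with_altloc = FALSE))
  expect_false(anyNA(idx))
  expect_lt(max(abs(coords(full_ch) - coords(back)[idx, ])), 1e-6)
  expect_equal(back$occ[idx], full_ch$occ)   # occupancies rescaled back
  # counting: |extract| = |shared| + |changed conformer|
  expect_equal(nrow(back),
               sum(ens$model$altloc == "") +
                 sum(ens$model$altloc == ens$changed_conformer))
})

test_that("extraction of a shared-only ensemble is the identity", {
  g <- toy_chain(8)
  ens <- merge_ensemble(g, g, bdc = 0.5)
  back <- extract_changed_state(ens)
  expect_equal(nrow(back), nrow(g))
  expect_lt(max(abs(coords(back) - coords(g))), 1e-12)
})

test_that("models in different frames are rejected", {
  g <- toy_chain(8)
  far <- g
  far[, c("x", "y", "z")] <- coords(far) + 50
  expect_error(merge_ensemble(g, far, bdc = 0.5), "frames")
})

test_that("RSCC is 1 for a perfect model and high under moderate noise", {
  set.seed(51)
  lig <- lig_model(5, centre = c(5, 5, 5))
  grid <- zero_map(20, spacing = 0.5)
  dens <- density_from_atoms(lig, grid, blur = 0.4)
  expect_equal(rscc(lig, dens, blur = 0.4), 1, tolerance = 1e-9)
  # noise at half the local model sd attenuates corr to ~1/sqrt(1.25)
  vox <- densdelta:::atom_mask_voxels(lig, grid, 1.5)
  noisy <- dens
  noisy$values <- noisy$values +
    rnorm(length(noisy$values), sd = 0.5 * sd(dens$values[vox]))
  expect_gt(rscc(lig, noisy, blur = 0.4), 0.85)
})

test_that("RSCC against pure noise is small", {
  set.seed(52)
  lig <- lig_model(5, centre = c(5, 5, 5))
  grid <- zero_map(20, spacing = 0.5)
  vals <- replicate(30, {
    noise <- grid
    noise$values[] <- rnorm(length(noise$values))
    rscc(lig, noise, blur = 0.4)
  })
  expect_lt(quantile(abs(vals), 0.99), 0.25)
})

test_that("RSZD is zero for an exact model and calibrated under the null", {
  set.seed(53)
  lig <- lig_model(4, centre = c(5, 5, 5))
  grid <- zero_map(20, spacing = 0.5)
  dens <- density_from_atoms(lig, grid, blur = 0.4)
  expect_equal(rszd(lig, dens, dens, sigma_map = 0.1), 0)
  below3 <- replicate(200, {
    obs <- dens
    obs$values <- obs$values + rnorm(length(obs$values), sd = 0.1)
    rszd(lig, obs, dens, sigma_map = 0.1) < 3
  })
  expect_gte(mean(below3), 0.95)
})

test_that("an unmodelled atom drives RSZD far above 3", {
  lig <- lig_model(4, centre = c(5, 5, 5))
  extra <- lig_model(5, centre = c(5, 5, 5))
  grid <- zero_map(20, spacing = 0.5)
  dens_model <- density_from_atoms(lig, grid, blur = 0.4)
  dens_obs <- density_from_atoms(extra, grid, blur = 0.4)
  sigma <- 0.1 * max(dens_obs$values)
  set.seed(54)
  dens_obs$values <- dens_obs$values +
    rnorm(length(dens_obs$values), sd = sigma)
  expect_gt(rszd(extra, dens_obs, dens_model, sigma_map = sigma), 3)
})

test_that("B-factor ratio selects side chains within 4 A and flags ratios", {
  env_df <- data.frame(
    chain = "A", resno = 1:4, resname = "ALA",
    atom = c("CB", "CB", "N", "CA"), element = c("C", "C", "N", "C"),
    altloc = "", x = c(7, 30, 7.2, 7.3), y = 6, z = 6, occ = 1,
    b = c(20, 99, 50, 50), stringsAsFactors = FALSE)
  env <- structure_model(env_df)
  lig <- lig_model(3, centre = c(6, 6, 6), b = 20)
  # only the CB at x=7 is side chain within 4 A: mean env B = 20
  expect_equal(bfactor_ratio(lig, env), 1.0)
  lig60 <- lig_model(3, centre = c(6, 6, 6), b = 60)
  r <- bfactor_ratio(lig60, env)
  expect_equal(r, 3.0)
  expect_equal(validation_flags(0.9, 1, r, 0.5)$b_ratio_flag, "warn")
  expect_equal(validation_flags(0.9, 1, 3.01, 0.5)$b_ratio_flag, "fail")
  # backbone-only environment is no environment at all
  bb <- structure_model(env_df[3:4, ])
  expect_error(bfactor_ratio(lig, bb), "side-chain|environment")
})

test_that("coordinate RMSD matches hand-computed and distributional cases", {
  m <- lig_model(4)
  expect_equal(coord_rmsd(m, m), 0)
  moved <- m
  moved[1, c("x", "y", "z")] <- moved[1, c("x", "y", "z")] + c(2, 0, 0)
  expect_equal(coord_rmsd(m, moved), 1.0)   # sqrt(4/4)
  set.seed(55)
  big <- toy_chain(200)
  pert <- big
  pert[, c("x", "y", "z")] <- coords(big) +
    matrix(rnorm(3 * nrow(big), sd = 0.1), ncol = 3)
  expect_equal(coord_rmsd(big, pert), 0.1 * sqrt(3), tolerance = 0.1)
})

test_that("validation thresholds follow strict boundary semantics", {
  f <- validation_flags(0.7, 3, 1.0, 1.0)
  expect_false(f$rscc_pass)   # 0.7 is not > 0.7
  expect_false(f$rszd_pass)   # 3 is not < 3
  expect_false(f$rmsd_pass)   # 1 is not < 1
  g <- validation_flags(0.701, 2.999, 1.49, 0.999)
  expect_true(g$rscc_pass && g$rszd_pass && g$rmsd_pass)
  expect_equal(g$b_ratio_flag, "ok")
  expect_equal(validation_flags(1, 0, 1.5, 0)$b_ratio_flag, "warn")
})

test_that("a perfect synthetic ligand passes validation end to end", {
  set.seed(56)
  lig <- lig_model(5, centre = c(5, 5, 5))
  env <- structure_model(data.frame(
    chain = "A", resno = 1, resname = "ALA", atom = "CB", element = "C",
    altloc = "", x = 7, y = 5, z = 5, occ = 1, b = 20,
    stringsAsFactors = FALSE))
  grid <- zero_map(20, spacing = 0.5)
  dens <- density_from_atoms(lig, grid, blur = 0.4)
  obs <- dens
  obs$values <- obs$values + rnorm(length(obs$values), sd = 0.02)
  rep <- validate_event(lig, lig, obs, dens, sigma_map = 0.02,
                        environment = env)
  expect_true(rep$rscc_pass)
  expect_true(rep$rmsd_pass)
  expect_equal(rep$b_ratio_flag, "ok")
  expect_equal(rep$rmsd, 0)
})

test_that("a ligand built into noise fails RSCC; inflated B fails the
           ratio while other scores hold", {
  set.seed(57)
  lig <- lig_model(5, centre = c(5, 5, 5))
  env <- structure_model(data.frame(
    chain = "A", resno = 1, resname = "ALA", atom = "CB", element = "C",
    altloc = "", x = 7, y = 5, z = 5, occ = 1, b = 20,
    stringsAsFactors = FALSE))
  grid <- zero_map(20, spacing = 0.5)
  dens <- density_from_atoms(lig, grid, blur = 0.4)
  noise <- grid
  noise$values[] <- rnorm(length(noise$values), sd = 1)
  rep_noise <- validate_event(lig, lig, noise, dens, sigma_map = 1,
                              environment = env)
  expect_false(rep_noise$rscc_pass)
  hot <- lig
  hot$b <- 70   # 3.5x the environment
  dens_hot <- density_from_atoms(hot, grid, blur = 0.4)
  obs <- dens_hot
  obs$values <- obs$values + rnorm(length(obs$values), sd = 0.01)
  rep_hot <- validate_event(hot, hot, obs, dens_hot, sigma_map = 0.01,
                            environment = env)
  expect_equal(rep_hot$b_ratio_flag, "fail")
  expect_true(rep_hot$rscc_pass)
  expect_true(rep_hot$rmsd_pass)
})

test_that("restraint tables pair nearby atoms within matching conformers", {
  g <- toy_chain(6)
  ch <- g
  ch[2, c("x", "y", "z")] <- ch[2, c("x", "y", "z")] + 1.0
  ens <- merge_ensemble(g, ch, bdc = 0.6)
  tab <- restraint_table(ens, max_dist = 4)
  expect_true(all(tab$target <= 4))
  expect_true(all(tab$sigma > 0))
})
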