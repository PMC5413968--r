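# Synthetic multi-dataset screens with known ground truth.  The generator
# draws maps from exactly the statistical structure the ensemble model
# assumes: observed = (true density draw) + iid noise, where the true draw
# is mu plus zero-mean natural variation (nonzero s only inside designated
# "variable regions"), and event datasets superpose a changed-state density
# at fractional occupancy before noise.  Maps are then low-pass truncated
# to each dataset's sampled resolution, and the model may be rigidly
# jittered (map regenerated consistently) to emulate small non-isomorphism.

ELECTRON_COUNTS <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

element_electrons <- function(element) {
  ne <- ELECTRON_COUNTS[toupper(element)]
  ne[is.na(ne)] <- 6  # unknown elements counted as carbon
  as.numeric(ne)
}

# preserve the caller's RNG stream around seeded simulation
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Model density: sum of atom-centred Gaussians
#'
#' Each atom contributes an isotropic Gaussian with variance
#' \code{B/(8 pi^2) + blur^2} (Angstrom^2) and total integral
#' \code{occupancy x electron count}, so the map integrates to the
#' selection's electron count.  Linear in the atom list.
#'
#' @param atoms a \code{\link{structure_model}} (or atom data frame).
#' @param grid a \code{\link{density_map}} defining the output grid.
#' @param blur extra Gaussian blur sd (Angstrom) emulating finite
#'   resolution; \code{resolution_blur(d)} gives a conventional value.
#' @param margin atoms farther than this outside the grid (Angstrom,
#'   default 5) raise a placement error.
#' @return A \code{\link{density_map}} of the model density.
#' @export
density_from_atoms <- function(atoms, grid, blur = 0, margin = 5) {
  stopifnot(inherits(grid, "density_map"))
  d <- dim(grid$values)
  out <- array(0, dim = d)
  if (nrow(atoms) == 0L)
    return(density_map(out, grid$spacing, grid$origin, "model density"))
  lo_bound <- grid$origin - margin
  hi_bound <- grid$origin + (d - 1) * grid$spacing + margin
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(sweep(xyz, 2L, lo_bound) < 0) || any(sweep(xyz, 2L, hi_bound) > 0))
    stop("atom outside grid bounds + ", margin, " A margin")
  ax <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing
  ay <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing
  az <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing
  ne <- element_electrons(atoms$element)
  for (a in seq_len(nrow(atoms))) {
    v <- atoms$b[a] / (8 * pi^2) + blur^2
    if (v <= 0) v <- 1e-4
    amp <- atoms$occ[a] * ne[a] / (2 * pi * v)^1.5
    cut <- 5 * sqrt(v)
    ix <- which(abs(ax - xyz[a, 1]) <= cut)
    iy <- which(abs(ay - xyz[a, 2]) <= cut)
    iz <- which(abs(az - xyz[a, 3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax[ix] - xyz[a, 1])^2 / (2 * v))
    gy <- exp(-(ay[iy] - xyz[a, 2])^2 / (2 * v))
    gz <- exp(-(az[iz] - xyz[a, 3])^2 / (2 * v))
    out[ix, iy, iz] <- out[ix, iy, iz] +
      amp * (gx %o% gy %o% gz)
  }
  density_map(out, grid$spacing, grid$origin, "model density")
}

#' Conventional resolution blur
#'
#' Gaussian blur sd (Angstrom) emulating the finite-resolution smearing of
#' a map at resolution \code{d}; the d/4 rule keeps atom images comparable
#' to what a map at that resolution shows.
#'
#' @param d nominal resolution (Angstrom).
#' @return Blur sd in Angstrom.
#' @export
resolution_blur <- function(d) d / 4

#' Random pseudo-protein for synthetic screens
#'
#' A self-avoiding random walk of C-alpha pseudo-atoms at 3.8 A steps,
#' confined to the grid interior, with a CB "side-chain" atom attached to
#' \code{n_side_chains} designated residues (targets for shift events).
#'
#' @param grid a \code{\link{density_map}} defining the bounding volume.
#' @param n_atoms number of residues; by default scaled to the grid
#'   volume (about one per 60 cubic Angstrom, at most 60).
#' @param n_side_chains number of residues given a CB atom (default 3).
#' @param b B-factor given to every atom (Angstrom^2, default 20).
#' @param margin border (Angstrom, default 6) kept free around the walk.
#' @return A \code{\link{structure_model}}.
#' @export
make_pseudo_protein <- function(grid, n_atoms = NULL, n_side_chains = 3,
                                b = 20, margin = 6) {
  d <- dim(grid$values)
  extent <- (d - 1) * grid$spacing
  margin <- min(margin, min(extent) / 3)
  if (is.null(n_atoms))   # about one residue per 60 A^3 of box, capped
    n_atoms <- min(60L, max(6L, round(prod(extent) / 60)))
  n_side_chains <- min(n_side_chains, max(1L, n_atoms - 2L))
  lo <- grid$origin + margin
  hi <- grid$origin + (d - 1) * grid$spacing - margin
  if (any(hi <= lo)) stop("grid too small for the requested margin")
  pos <- matrix(NA_real_, n_atoms, 3L)
  pos[1, ] <- lo + (hi - lo) * stats::runif(3)
  for (i in seq_len(n_atoms)[-1L]) {
    for (try in 1:200) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1L, ] + 3.8 * u
      if (any(cand < lo) || any(cand > hi)) next
      prev <- pos[seq_len(i - 2L), , drop = FALSE]
      if (nrow(prev) &&
          min(rowSums(sweep(prev, 2L, cand)^2)) < 3^2) next
      pos[i, ] <- cand
      break
    }
    if (anyNA(pos[i, ])) {  # restart from a fresh random point
      pos[i, ] <- lo + (hi - lo) * stats::runif(3)
    }
  }
  atoms <- data.frame(chain = "A", resno = seq_len(n_atoms), resname = "ALA",
                      atom = "CA", element = "C", altloc = "",
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      occ = 1, b = b, stringsAsFactors = FALSE)
  sc <- sort(sample(2:(n_atoms - 1L), n_side_chains))
  for (r in sc) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    cb <- pmin(pmax(pos[r, ] + 1.5 * u, lo), hi)
    atoms <- rbind(atoms, data.frame(
      chain = "A", resno = r, resname = "ALA", atom = "CB", element = "C",
      altloc = "", x = cb[1], y = cb[2], z = cb[3], occ = 1, b = b,
      stringsAsFactors = FALSE))
  }
  structure_model(atoms)
}

#' Synthetic screen configuration
#'
#' Defaults emulate a small, well-behaved fragment screen: 40 ground-state
#' datasets on a 48^3 grid at 0.6 A spacing, per-dataset map noise sd drawn
#' from U(0.03, 0.08) map units (a few percent of a typical atom peak),
#' resolutions from U(1.6, 2.0) A, one naturally variable region, and no
#' rigid non-isomorphism (crystals from a single well-behaved form;
#' jitter can be switched on explicitly).
#'
#' @param n_ground number of ground-state datasets (>= 2).
#' @param grid_dim grid shape (length-3 integer).
#' @param spacing voxel size (Angstrom).
#' @param sigma_range per-dataset noise sd range (map units).
#' @param resolution_range per-dataset resolution range (Angstrom).
#' @param n_variable_regions spherical regions given nonzero natural
#'   variation.
#' @param s_value natural-variation sd inside variable regions (map units).
#' @param s_radius radius of variable regions (Angstrom).
#' @param events list of event specs from \code{\link{event_spec}}.
#' @param jitter_translation,jitter_rotation rigid non-isomorphism
#'   magnitudes (Angstrom / degrees; default 0).
#' @param protein optional \code{\link{structure_model}}; generated when
#'   NULL.
#' @param seed integer RNG seed.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_ground = 40, grid_dim = c(48, 48, 48),
                             spacing = 0.6,
                             sigma_range = c(0.03, 0.08),
                             resolution_range = c(1.6, 2.0),
                             n_variable_regions = 1, s_value = 0.06,
                             s_radius = 3, events = list(),
                             jitter_translation = 0, jitter_rotation = 0,
                             protein = NULL, seed = 1) {
  stopifnot(n_ground >= 2, spacing > 0, all(sigma_range > 0),
            all(resolution_range >= 2 * spacing))
  for (ev in events)
    if (ev$occupancy <= 0 || ev$occupancy > 1)
      stop("event occupancy must lie in (0, 1]")
  structure(list(n_ground = n_ground, grid_dim = as.integer(grid_dim),
                 spacing = spacing, sigma_range = sigma_range,
                 resolution_range = resolution_range,
                 n_variable_regions = n_variable_regions,
                 s_value = s_value, s_radius = s_radius, events = events,
                 jitter_translation = jitter_translation,
                 jitter_rotation = jitter_rotation,
                 protein = protein, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Specify an injected binding event
#'
#' @param occupancy changed-state occupancy in (0, 1].
#' @param n_ligand_atoms atoms in the pseudo-ligand (default 8).
#' @param shift_side_chain move one designated side-chain atom by this
#'   distance (Angstrom, default 1.5) in the changed state; 0 disables.
#' @return An \code{event_spec} list.
#' @export
event_spec <- function(occupancy, n_ligand_atoms = 8, shift_side_chain = 1.5) {
  structure(list(occupancy = occupancy, n_ligand_atoms = n_ligand_atoms,
                 shift_side_chain = shift_side_chain), class = "event_spec")
}

random_rotation <- function(angle_deg) {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# place a compact random pseudo-ligand near a protein surface site
make_ligand <- function(protein, grid, n_atoms, b = 20) {
  d <- dim(grid$values)
  extent <- (d - 1) * grid$spacing
  margin <- min(4, min(extent) / 4)
  offset <- min(4.5, max(2.5, min(extent) / 5))
  clearance <- min(3.5, offset - 0.5)
  lo <- grid$origin + margin
  hi <- grid$origin + (d - 1) * grid$spacing - margin
  prot_xyz <- coords(protein)
  for (try in 1:500) {
    anchor <- prot_xyz[sample(nrow(prot_xyz), 1L), ]
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    centre <- anchor + offset * u
    if (any(centre < lo) || any(centre > hi)) next
    if (min(rowSums(sweep(prot_xyz, 2L, centre)^2)) < clearance^2) next
    pos <- matrix(rep(centre, each = n_atoms), n_atoms, 3L)
    pos <- pos + matrix(stats::rnorm(3 * n_atoms, sd = 1.1), n_atoms, 3L)
    atoms <- data.frame(chain = "L", resno = 1L, resname = "LIG",
                        atom = paste0("C", seq_len(n_atoms)), element = "C",
                        altloc = "", x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        occ = 1, b = b, stringsAsFactors = FALSE)
    return(structure_model(atoms))
  }
  stop("could not place a ligand clear of the protein")
}

#' Simulate a synthetic fragment screen
#'
#' Generates \code{n_ground} ground-state datasets plus one dataset per
#' entry of \code{config$events}, each with a map drawn from the ensemble
#' model's assumed structure (see the package vignette), truncated to its
#' sampled resolution and optionally rigidly jittered, together with the
#' hidden truth for recovery tests.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return A list with \code{datasets} (list of \code{\link{dd_dataset}};
#'   event datasets carry role \code{"changed"}) and \code{truth}: true
#'   \code{mu} and \code{s} maps, injected noise sd \code{sigma_injected},
#'   effective post-truncation noise sd \code{sigma} (the marginal sd
#'   actually present in each delivered map), per-dataset resolutions, and
#'   per-event truth (\code{ligand} model, occupancy, changed-state
#'   density \code{nu}, geometric \code{blob_mask}).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    grid <- density_map(array(0, config$grid_dim), config$spacing,
                        origin = c(0, 0, 0), label = "grid")
    protein <- config$protein
    if (is.null(protein)) protein <- make_pseudo_protein(grid)
    blur <- resolution_blur(mean(config$resolution_range))
    # natural-variation field: spheres centred on random protein atoms
    s_field <- array(0, config$grid_dim)
    pos <- grid_positions(grid)
    region_centres <- NULL
    if (config$n_variable_regions > 0) {
      prot_xyz <- coords(protein)
      idx <- sample(nrow(prot_xyz), config$n_variable_regions)
      region_centres <- prot_xyz[idx, , drop = FALSE]
      for (k in seq_len(nrow(region_centres))) {
        d2 <- (pos[, 1] - region_centres[k, 1])^2 +
              (pos[, 2] - region_centres[k, 2])^2 +
              (pos[, 3] - region_centres[k, 3])^2
        s_field[d2 <= config$s_radius^2] <- config$s_value
      }
    }
    s_true <- density_map(s_field, config$spacing, grid$origin, "true s")
    n_events <- length(config$events)
    n_total <- config$n_ground + n_events
    resolutions <- stats::runif(n_total, config$resolution_range[1],
                                config$resolution_range[2])
    sigma_inj <- stats::runif(n_total, config$sigma_range[1],
                              config$sigma_range[2])
    ids <- sprintf("ds%03d", seq_len(n_total))
    # Ligands and the ordered waters they displace.  Fragments bind in
    # occupied pockets: the ground state carries ordered solvent at every
    # future binding site, which the changed state displaces.  Without
    # this the local region has no ground density to subtract and the
    # background correction is ill-determined.
    ligands <- list()
    site_waters <- list()
    for (e in seq_len(n_events)) {
      lig <- make_ligand(protein, grid, config$events[[e]]$n_ligand_atoms)
      ligands[[e]] <- lig
      anchor <- coords(lig)[sample(nrow(lig), min(2L, nrow(lig))), ,
                            drop = FALSE]
      wpos <- anchor + matrix(stats::rnorm(length(anchor), sd = 0.4),
                              nrow(anchor))
      site_waters[[e]] <- structure_model(data.frame(
        chain = "W", resno = 500L + 10L * e + seq_len(nrow(wpos)),
        resname = "HOH", atom = "O", element = "O", altloc = "",
        x = wpos[, 1], y = wpos[, 2], z = wpos[, 3], occ = 1, b = 30,
        stringsAsFactors = FALSE))
    }
    ground_model <- protein
    if (n_events > 0)
      ground_model <- structure_model(
        do.call(rbind, c(list(as.data.frame(protein)),
                         lapply(site_waters, as.data.frame))))
    mu_true <- density_from_atoms(ground_model, grid, blur = blur)
    mu_true$label <- "true mu"
    # event truths (changed densities: site waters out, ligand in)
    event_truth <- list()
    changed_density <- list()
    changed_models <- list()
    for (e in seq_len(n_events)) {
      ev <- config$events[[e]]
      lig <- ligands[[e]]
      changed <- ground_model[!(atom_key(ground_model) %in%
                                  atom_key(site_waters[[e]])), ,
                              drop = FALSE]
      changed <- structure_model(as.data.frame(changed))
      moved_atom <- NULL
      if (ev$shift_side_chain > 0) {
        cb <- which(changed$atom == "CB")
        if (length(cb)) {
          moved_atom <- cb[1 + (e - 1L) %% length(cb)]
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          changed[moved_atom, c("x", "y", "z")] <-
            changed[moved_atom, c("x", "y", "z")] + ev$shift_side_chain * u
        }
      }
      full_changed <- structure_model(rbind(as.data.frame(changed),
                                            as.data.frame(lig)))
      nu <- density_from_atoms(full_changed, grid, blur = blur)
      # truth mask: where the changed-state density differs materially
      # from the ground state (above 10% of the peak absolute difference)
      dmap <- abs(nu$values - mu_true$values)
      inmask <- dmap > 0.1 * max(dmap)
      event_truth[[e]] <- list(ligand = lig, occupancy = ev$occupancy,
                               nu = nu,
                               blob_mask = array(inmask, config$grid_dim),
                               dataset_id = ids[config$n_ground + e])
      changed_density[[e]] <- nu
      changed_models[[e]] <- full_changed
    }
    datasets <- vector("list", n_total)
    sigma_eff <- numeric(n_total)
    for (i in seq_len(n_total)) {
      is_event <- i > config$n_ground
      true_draw <- mu_true$values + s_field * stats::rnorm(length(s_field))
      if (is_event) {
        e <- i - config$n_ground
        o <- config$events[[e]]$occupancy
        true_draw <- (1 - o) * true_draw + o * changed_density[[e]]$values
      }
      vals <- true_draw +
        stats::rnorm(length(true_draw), sd = sigma_inj[i])
      m <- density_map(vals, config$spacing, grid$origin, ids[i])
      keep_frac <- mean(resolution_mask(m, resolutions[i]))
      m <- lowpass_truncate(m, resolutions[i])
      sigma_eff[i] <- sigma_inj[i] * sqrt(keep_frac)
      model <- ground_model
      if (config$jitter_translation > 0 || config$jitter_rotation > 0) {
        R <- random_rotation(stats::runif(1, 0, config$jitter_rotation))
        centre <- colMeans(coords(ground_model))
        tr <- stats::rnorm(3)
        tr <- tr / sqrt(sum(tr^2)) *
          stats::runif(1, 0, config$jitter_translation)
        xyz <- sweep(coords(ground_model), 2L, centre) %*% t(R)
        xyz <- sweep(xyz, 2L, -(centre + tr))
        model <- ground_model
        model[, c("x", "y", "z")] <- xyz
        # regenerate the map consistently in the jittered frame
        jlig <- if (is_event) {
          e <- i - config$n_ground
          cm <- changed_models[[e]]
          cxyz <- sweep(coords(cm), 2L, centre) %*% t(R)
          cm[, c("x", "y", "z")] <- sweep(cxyz, 2L, -(centre + tr))
          cm
        } else NULL
        jmu <- density_from_atoms(model, grid, blur = blur)
        true_draw <- jmu$values + s_field * stats::rnorm(length(s_field))
        if (is_event) {
          o <- config$events[[i - config$n_ground]]$occupancy
          jnu <- density_from_atoms(jlig, grid, blur = blur)
          true_draw <- (1 - o) * true_draw + o * jnu$values
        }
        vals <- true_draw + stats::rnorm(length(true_draw), sd = sigma_inj[i])
        m <- density_map(vals, config$spacing, grid$origin, ids[i])
        m <- lowpass_truncate(m, resolutions[i])
      }
      datasets[[i]] <- dd_dataset(ids[i], m, model, resolutions[i],
                                  role = if (is_event) "changed" else "ground")
    }
    truth <- list(mu = mu_true, s = s_true,
                  sigma_injected = stats::setNames(sigma_inj, ids),
                  sigma = stats::setNames(sigma_eff, ids),
                  resolutions = stats::setNames(resolutions, ids),
                  protein = ground_model,
                  region_centres = region_centres,
                  events = event_truth)
    list(datasets = datasets, truth = truth)
  })
}

#' Two dissimilar one-dimensional density profiles
#'
#' Fixed sums of Gaussians emulating a dominant (ground) and a largely
#' dissimilar minor (changed) state along one axis, for worked
#' demonstrations of background density correction: a population-weighted
#' superposition of the two is resolved by the event-map scan.
#'
#' @param n number of samples along the profile (default 256).
#' @return List with numeric vectors \code{major} and \code{minor}.
#' @export
two_state_profiles <- function(n = 256) {
  x <- seq(0, 10, length.out = n)
  gauss <- function(c, w, a) a * exp(-(x - c)^2 / (2 * w^2))
  major <- gauss(2.0, 0.5, 1.0) + gauss(4.2, 0.7, 0.8) +
    gauss(6.0, 0.4, 1.2) + gauss(8.3, 0.6, 0.6)
  minor <- gauss(1.2, 0.4, 0.7) + gauss(3.1, 0.5, 1.1) +
    gauss(5.2, 0.8, 0.5) + gauss(7.2, 0.35, 1.3) + gauss(9.0, 0.5, 0.9)
  list(major = major, minor = minor)
}

#' Embed a 1D profile as a density map
#'
#' Replicates a profile along a thin 2 x 2 cross-section so the 1D worked
#' examples can flow through the 3D map operations unchanged.
#'
#' @param profile numeric vector.
#' @param spacing voxel size (Angstrom, default 0.25).
#' @return A \code{\link{density_map}} of dimension \code{length(profile)
#'   x 2 x 2}.
#' @export
profile_as_map <- function(profile, spacing = 0.25) {
  density_map(array(rep(profile, 4), c(length(profile), 2, 2)), spacing,
              label = "1D profile")
}

#' Degrade datasets with a sabotaged reference model
#'
#' Emulates phase error from refining against a deliberately perturbed
#' reference: one reference model is jittered once, and every dataset's
#' map is blended toward the perturbed model's density.  The recorded
#' truth is untouched.
#'
#' @param datasets list of \code{\link{dd_dataset}}s.
#' @param jitter per-coordinate sd (Angstrom) of the reference
#'   perturbation; 0 returns the datasets unchanged.
#' @param weight blending weight in [0, 1] toward the perturbed-model
#'   density (default 0.3); 1 replaces the map entirely.
#' @param seed RNG seed for the perturbation.
#' @return The degraded dataset list.
#' @export
degrade_reference <- function(datasets, jitter, weight = 0.3, seed = 1) {
  stopifnot(jitter >= 0, weight >= 0, weight <= 1)
  if (jitter == 0 || weight == 0) return(datasets)
  with_seed(seed, {
    ref_model <- datasets[[1]]$model
    ref_model[, c("x", "y", "z")] <- coords(ref_model) +
      matrix(stats::rnorm(3 * nrow(ref_model), sd = jitter),
             ncol = 3L)
    lapply(datasets, function(ds) {
      bad <- density_from_atoms(ref_model, ds$map,
                                blur = resolution_blur(ds$resolution))
      ds$map$values <- (1 - weight) * ds$map$values + weight * bad$values
      ds
    })
  })
}
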