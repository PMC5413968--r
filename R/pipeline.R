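# End-to-end orchestration: read datasets, align everything onto the
# highest-resolution ground-state reference, schedule resolution bins, fit
# the ensemble model per bin on that bin's characterization set, compute
# Z-maps and events for that bin's analysis set, estimate BDC and write
# event maps and reports.  Individual dataset failures are quarantined
# (excluded and logged) rather than aborting the run.

#' Pipeline configuration
#'
#' @param bins explicit bin ceilings (Angstrom) or NULL for automatic
#'   0.1 A steps spanning the observed resolutions.
#' @param bin_step step for automatic bin ceilings (default 0.1 A).
#' @param contour,min_peak,min_volume,merge_dist blob thresholds (defaults
#'   2.5, 3.0, 10 A^3, 5 A).
#' @param bdc_buffer blob expansion for the local BDC region (1 A).
#' @param beta_step BDC grid step (0.01).
#' @param alignment_window flexible-alignment window (7 residues).
#' @param max_voxel_residue_distance voxels farther than this from every
#'   residue are treated as missing after warping (10 A).
#' @param ground_only use only datasets labelled ground-state for
#'   characterization (default FALSE: all datasets in a bin's
#'   characterization set contribute, since true hits are rare).
#' @param negative_events also detect density-loss (negative Z) events.
#' @param reference_id dataset id to use as reference; NULL picks the
#'   highest-resolution ground-state dataset.
#' @param spacing reference grid spacing (Angstrom); NULL keeps the
#'   reference map's own grid.
#' @param seed integer seed recorded with the run.
#' @param write_zmaps write per-dataset Z-maps when an output directory is
#'   given (default FALSE).
#' @return A \code{run_config} list.
#' @export
run_config <- function(bins = NULL, bin_step = 0.1, contour = 2.5,
                       min_peak = 3.0, min_volume = 10, merge_dist = 5,
                       bdc_buffer = 1, beta_step = 0.01,
                       alignment_window = 7L,
                       max_voxel_residue_distance = 10,
                       ground_only = FALSE, negative_events = FALSE,
                       reference_id = NULL, spacing = NULL, seed = 1L,
                       write_zmaps = FALSE) {
  stopifnot(contour > 0, min_peak >= contour, min_volume > 0,
            merge_dist > 0, beta_step > 0, bdc_buffer > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Read a dataset manifest
#'
#' @param path CSV with columns \code{id}, \code{map_path},
#'   \code{model_path}, \code{resolution}, \code{role} (paths relative to
#'   the manifest's directory are resolved against it).
#' @return List of \code{\link{dd_dataset}}s.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "map_path", "model_path", "resolution", "role")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  lapply(seq_len(nrow(df)), function(i) {
    dd_dataset(df$id[i],
               read_map(resolve(df$map_path[i])),
               read_model(resolve(df$model_path[i])),
               df$resolution[i],
               role = df$role[i])
  })
}

#' Run the full multi-dataset analysis
#'
#' @param datasets list of \code{\link{dd_dataset}}s, or a manifest CSV
#'   path.
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory; when given, the mean and
#'   natural-variation maps, the sigma table, the events table, per-event
#'   event maps and a JSON run summary are written there.
#' @param verbose print per-stage progress.
#' @return A \code{run_summary}: events (list and table), the per-bin
#'   statistical models, the analysis plan, alignments, quarantined
#'   datasets and stage counts.
#' @export
run_analysis <- function(datasets, config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(datasets)) datasets <- read_manifest(datasets)
  if (length(datasets) < 2L)
    stop("at least 2 usable datasets are required")
  say <- function(...) if (verbose) message(sprintf(...))
  ids <- vapply(datasets, `[[`, character(1), "id")
  names(datasets) <- ids
  resolutions <- vapply(datasets, `[[`, numeric(1), "resolution")
  roles <- vapply(datasets, `[[`, character(1), "role")

  # reference: highest-resolution ground-state dataset unless pinned
  ref_id <- config$reference_id
  if (is.null(ref_id)) {
    cand <- ids[roles == "ground"]
    if (!length(cand)) cand <- ids
    ref_id <- cand[which.min(resolutions[cand])]
  }
  ref <- datasets[[ref_id]]
  say("reference: %s (%.2f A)", ref_id, ref$resolution)
  ref_grid <- ref$map
  if (!is.null(config$spacing) &&
      abs(config$spacing - ref$map$spacing) > 1e-9) {
    d_old <- dim(ref$map$values)
    extent <- (d_old - 1) * ref$map$spacing
    d_new <- pmax(floor(extent / config$spacing) + 1, 2)
    ref_grid <- density_map(array(0, d_new), config$spacing,
                            ref$map$origin, "reference grid")
  }

  # alignment; failures quarantined.  Maps are truncated (complete, in
  # their own frame) before warping, so only the sampling plan is built
  # here and reused across bins.
  quarantine <- character()
  plans <- list()
  alignments <- list()
  for (id in ids) {
    ds <- datasets[[id]]
    res <- tryCatch({
      al <- if (id == ref_id) identity_alignment(ref$model)
            else flexible_alignment(ds$model, ref$model,
                                    window = config$alignment_window)
      list(al = al,
           plan = warp_plan(al, ref_grid,
                            max_dist = config$max_voxel_residue_distance))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("dataset ", id, " quarantined at alignment: ",
              conditionMessage(res))
      quarantine <- c(quarantine, id)
    } else {
      alignments[[id]] <- res$al
      plans[[id]] <- res$plan
    }
  }
  usable <- setdiff(ids, quarantine)
  if (length(usable) < 2L) stop("fewer than 2 usable datasets after alignment")

  bins <- config$bins
  if (is.null(bins))
    bins <- default_bin_ceilings(resolutions[usable], config$bin_step)
  plan <- assign_bins(resolutions[usable], bins)

  events <- list()
  models <- list()
  sigma_all <- list()
  dataset_rows <- list()
  for (b in plan$bins) {
    if (!length(b$analysis)) next
    say("bin <= %.2f A: %d characterization, %d analysis",
        b$ceiling, length(b$characterization), length(b$analysis))
    char_ids <- b$characterization
    if (config$ground_only) {
      keep <- roles[char_ids] == "ground"
      # analysis datasets must still be standardizable; model needs grounds
      char_ids <- char_ids[keep]
    }
    if (length(char_ids) < 2L) {
      warning("bin ", b$ceiling, " A skipped: fewer than 2 characterization ",
              "datasets")
      next
    }
    trunc_maps <- lapply(char_ids, function(id)
      apply_warp_plan(lowpass_truncate(datasets[[id]]$map, b$ceiling),
                      plans[[id]]))
    names(trunc_maps) <- char_ids
    model <- withCallingHandlers(
      fit_statistical_model(trunc_maps),
      warning = function(w) {
        say("  %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (model$n_char < 30)
      say("  note: %d characterization datasets (< 30); model may not be fully converged",
          model$n_char)
    models[[as.character(b$ceiling)]] <- model
    sigma_all[[as.character(b$ceiling)]] <- model$sigma
    for (id in b$analysis) {
      m_i <- if (id %in% names(trunc_maps)) trunc_maps[[id]]
             else apply_warp_plan(lowpass_truncate(datasets[[id]]$map,
                                                   b$ceiling),
                                  plans[[id]])
      sig_i <- if (id %in% names(model$sigma)) model$sigma[[id]]
               else estimate_sigma(m_i, model$mu)
      z <- zmap(m_i, model, sigma_i = sig_i, id = id)
      evs <- find_blobs(z, contour = config$contour,
                        min_peak = config$min_peak,
                        min_volume = config$min_volume,
                        merge_dist = config$merge_dist,
                        dataset_id = id,
                        negative = config$negative_events)
      for (k in seq_along(evs)) {
        bd <- tryCatch(
          estimate_bdc(m_i, model$mu, evs[[k]]$voxels,
                       buffer = config$bdc_buffer,
                       beta_grid = seq(0, 0.99, by = config$beta_step)),
          error = function(e) NULL)
        if (!is.null(bd)) {
          evs[[k]]$bdc <- bd$bdc
          evs[[k]]$low_contrast <- bd$low_contrast
          evs[[k]]$event_map <- event_map(m_i, model$mu, bd$bdc)
          evs[[k]]$bin <- b$ceiling
        }
      }
      events <- c(events, evs)
      dataset_rows[[id]] <- data.frame(
        id = id, resolution = resolutions[[id]], bin = b$ceiling,
        role = roles[[id]], sigma = sig_i, n_events = length(evs),
        max_peak_z = if (length(evs)) max(vapply(evs, `[[`, numeric(1),
                                                 "peak_z")) else NA_real_,
        bdc = if (length(evs)) evs[[1]]$bdc else NA_real_,
        stringsAsFactors = FALSE)
      if (!is.null(out_dir) && config$write_zmaps) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_map(z, file.path(out_dir, paste0("zmap_", id, ".ccp4")))
      }
    }
  }
  if (length(dataset_rows)) {
    dataset_table <- do.call(rbind, c(dataset_rows,
                                      list(make.row.names = FALSE)))
    dataset_table <- dataset_table[order(dataset_table$id), , drop = FALSE]
    rownames(dataset_table) <- NULL
  } else {
    dataset_table <- data.frame(id = character(), resolution = numeric(),
                                bin = numeric(), role = character(),
                                sigma = numeric(), n_events = integer(),
                                max_peak_z = numeric(), bdc = numeric())
  }
  summary <- structure(list(
    reference_id = ref_id,
    n_datasets = length(datasets),
    n_usable = length(usable),
    quarantined = quarantine,
    plan = plan,
    models = models,
    events = events,
    events_table = events_table(events),
    dataset_table = dataset_table,
    seed = config$seed,
    config = config), class = "run_summary")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(models)) {
      write_map(models[[nm]]$mu,
                file.path(out_dir, sprintf("mean_%sA.ccp4", nm)))
      write_map(models[[nm]]$s,
                file.path(out_dir, sprintf("svar_%sA.ccp4", nm)))
    }
    sig_df <- do.call(rbind, lapply(names(sigma_all), function(nm)
      data.frame(bin = nm, id = names(sigma_all[[nm]]),
                 sigma = as.numeric(sigma_all[[nm]]),
                 stringsAsFactors = FALSE)))
    utils::write.csv(sig_df, file.path(out_dir, "sigma.csv"),
                     row.names = FALSE)
    events_table(events, path = file.path(out_dir, "events.csv"))
    utils::write.csv(dataset_table, file.path(out_dir, "datasets.csv"),
                     row.names = FALSE)
    for (k in seq_along(events)) {
      if (!is.null(events[[k]]$event_map))
        write_map(events[[k]]$event_map,
                  file.path(out_dir, sprintf("event_%03d_%s.ccp4", k,
                                             events[[k]]$dataset_id)))
    }
    jsonlite::write_json(report_json(summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary
}

# machine-readable summary
report_json <- function(summary) {
  list(
    reference = summary$reference_id,
    n_datasets = summary$n_datasets,
    n_usable = summary$n_usable,
    quarantined = as.list(summary$quarantined),
    seed = summary$seed,
    bins = lapply(summary$plan$bins, function(b)
      list(ceiling = b$ceiling, n_analysis = length(b$analysis),
           n_characterization = length(b$characterization))),
    n_events = length(summary$events))
}

#' Human-readable run report
#'
#' @param summary a \code{run_summary} from \code{\link{run_analysis}}.
#' @return Invisibly, the per-dataset table; prints a formatted report.
#' @export
report <- function(summary) {
  stopifnot(inherits(summary, "run_summary"))
  cat(sprintf("Analysis of %d datasets (reference %s); %d usable, %d events\n",
              summary$n_datasets, summary$reference_id, summary$n_usable,
              length(summary$events)))
  for (b in summary$plan$bins) {
    if (!length(b$analysis)) next
    cat(sprintf("  bin <= %.2f A: %d characterization, %d analysed\n",
                b$ceiling, length(b$characterization), length(b$analysis)))
  }
  if (length(summary$quarantined))
    cat("  quarantined:", paste(summary$quarantined, collapse = ", "), "\n")
  cat("\nPer-dataset summary:\n")
  print(summary$dataset_table, digits = 4)
  invisible(summary$dataset_table)
}

#' @export
print.run_summary <- function(x, ...) {
  report(x)
  invisible(x)
}
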