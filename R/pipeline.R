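#' Pipeline run configuration
#'
#' Assembles the parameter blocks of every stage with a single seed and an
#' output directory. All numeric defaults of the generator, the detector and
#' the truncation model can be overridden per block; the configuration is
#' echoed verbatim into the run manifest so a run is reproducible from its
#' outputs.
#'
#' @param out_dir Output directory of the run.
#' @param seed Integer master seed; each stage derives its own sub-stream
#'   from it by a fixed label, so toggling one stage never changes another
#'   stage's draws.
#' @param stages Character vector of enabled stages, in dependency order,
#'   among `"simulate"`, `"detect"`, `"metrics"`, `"topography"`, `"pairs"`,
#'   `"truncation"`.
#' @param n_cells Cohort size for the simulate stage.
#' @param grid Named list of [grid_spec()] overrides.
#' @param pattern Named list of [pattern_params()] overrides.
#' @param noise Named list of [noise_model()] overrides.
#' @param acquisition Named list: sampling_rate_hz, trace_len_ms,
#'   stim_onset_ms.
#' @param detect Named list of [build_maps()] overrides (threshold_sd,
#'   window_ms, baseline_ms, mean_mode, boxcar_ms).
#' @param truncation Named list of [truncation_config()] overrides.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = "lspsmap_run", seed = 1L,
                       stages = c("simulate", "detect", "metrics",
                                  "topography", "pairs", "truncation"),
                       n_cells = 20L, grid = list(), pattern = list(),
                       noise = list(), acquisition = list(),
                       detect = list(), truncation = list()) {
  known <- c("simulate", "detect", "metrics", "topography", "pairs",
             "truncation")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  acq <- utils::modifyList(list(sampling_rate_hz = 10000, trace_len_ms = 550,
                                stim_onset_ms = 100), acquisition)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, n_cells = as.integer(n_cells),
                 grid = grid, pattern = pattern, noise = noise,
                 acquisition = acq, detect = detect, truncation = truncation),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file may set any argument of [run_config()]; unset blocks keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  keep <- intersect(names(y), names(formals(run_config)))
  do.call(run_config, y[keep])
}

#' Run the full mapping pipeline
#'
#' Executes the enabled stages in dependency order:
#' simulate (cohort + sweeps, bundle written with truth), detect (input and
#' connectivity maps), metrics (per-cell pattern table), topography (centers
#' of mass, cohort correlation, projection-zone widths), pairs (same-slice
#' heterogeneity), truncation (Monte-Carlo synapse-loss estimate). A failing
#' stage aborts the run with the stage named. Outputs land under
#' `config$out_dir` together with `manifest.json` (inputs, outputs, seed,
#' package version, verbatim config echo).
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the per-stage results (cohort, maps,
#'   metrics, topography, pairs, truncation) and the manifest.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(s) if (!quiet)
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), s))
  in_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- do.call(grid_spec, config$grid)
  pattern <- do.call(pattern_params, config$pattern)
  noise <- do.call(noise_model, config$noise)
  res <- list()
  outputs <- character(0)

  if ("simulate" %in% config$stages) {
    log_stage("simulate")
    res$cohort <- in_stage("simulate", {
      co <- generate_cohort_truth(config$n_cells, grid, pattern, config$seed)
      co$sweeps <- stats::setNames(lapply(co$cells$cell_id, function(id)
        simulate_sweepset(co$truths[[id]], noise, grid,
                          seed = config$seed,
                          sampling_rate_hz = config$acquisition$sampling_rate_hz,
                          trace_len_ms = config$acquisition$trace_len_ms,
                          stim_onset_ms = config$acquisition$stim_onset_ms)),
        co$cells$cell_id)
      co
    })
    bundle_dir <- file.path(config$out_dir, "bundle")
    in_stage("simulate", write_bundle(
      experiment_bundle(grid, res$cohort$cells, res$cohort$truths,
                        res$cohort$sweeps),
      bundle_dir, overwrite = TRUE))
    outputs <- c(outputs, bundle_dir)
  }

  if ("detect" %in% config$stages) {
    log_stage("detect")
    if (is.null(res$cohort)) stop("stage 'detect' failed: no simulated cohort")
    res$maps <- in_stage("detect", stats::setNames(
      lapply(res$cohort$cells$cell_id, function(id)
        do.call(build_maps, c(list(res$cohort$sweeps[[id]]), config$detect))),
      res$cohort$cells$cell_id))
  }

  if ("metrics" %in% config$stages) {
    log_stage("metrics")
    if (is.null(res$maps)) stop("stage 'metrics' failed: no maps")
    res$metrics <- in_stage("metrics", do.call(rbind, lapply(
      res$cohort$cells$cell_id, function(id)
        cell_metrics(res$maps[[id]]$input,
                     res$cohort$cells[res$cohort$cells$cell_id == id, ]))))
    f <- file.path(config$out_dir, "metrics.csv")
    utils::write.csv(res$metrics, f, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  if ("topography" %in% config$stages) {
    log_stage("topography")
    if (is.null(res$metrics)) stop("stage 'topography' failed: no metrics")
    res$topography <- in_stage("topography", {
      m <- res$metrics
      summ <- topography_summary(m$lateral_pos_um, m$connectivity_cm_um,
                                 m$synaptic_cm_um)
      cmaps <- lapply(res$maps, `[[`, "connectivity")
      nonempty <- vapply(cmaps, function(x) sum(x$connected) > 0, logical(1))
      pz <- projection_zone_width(cmaps[nonempty],
                                  m$lateral_pos_um[nonempty])
      list(summary = summ, projection_zone = pz)
    })
    f <- file.path(config$out_dir, "topography.csv")
    utils::write.csv(res$topography$projection_zone, f, row.names = FALSE)
    fj <- file.path(config$out_dir, "topography.json")
    jsonlite::write_json(res$topography$summary[c("n", "pearson_r",
                                                  "spearman_r", "slope",
                                                  "intercept",
                                                  "mean_abs_residual_um",
                                                  "mean_abs_residual2_um")],
                         fj, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f, fj)
  }

  if ("pairs" %in% config$stages) {
    log_stage("pairs")
    if (is.null(res$maps)) stop("stage 'pairs' failed: no maps")
    res$pairs <- in_stage("pairs", cohort_pairs(
      lapply(res$maps, `[[`, "connectivity"), res$cohort$cells))
    f <- file.path(config$out_dir, "pairs.csv")
    utils::write.csv(res$pairs, f, row.names = FALSE)
    outputs <- c(outputs, f)
    if (nrow(res$pairs)) {
      res$pair_summary <- cohort_pair_summary(res$pairs)
      f2 <- file.path(config$out_dir, "pair_summary.csv")
      utils::write.csv(res$pair_summary, f2, row.names = FALSE)
      outputs <- c(outputs, f2)
    }
  }

  if ("truncation" %in% config$stages) {
    log_stage("truncation")
    res$truncation <- in_stage("truncation", {
      tc <- do.call(truncation_config, config$truncation)
      est <- estimate_truncation_loss(tc, seed = config$seed)
      c(est, list(config = tc[c("dendritic_radius_um", "frac_dendritic",
                                "soma_depth_um", "n_synapses")]))
    })
    f <- file.path(config$out_dir, "truncation.json")
    jsonlite::write_json(res$truncation, f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
  }

  manifest <- list(
    package = "lspsmap",
    version = as.character(utils::packageVersion("lspsmap")),
    seed = config$seed, stages = config$stages,
    config = unclass(config), outputs = outputs,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$manifest <- manifest
  invisible(res)
}
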