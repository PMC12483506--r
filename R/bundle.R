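#' Experiment bundle container
#'
#' In-memory form of one mapping experiment: the grid, per-cell metadata,
#' and optionally ground truth (for synthetic cohorts), raw sweeps, and
#' derived maps. Written to and read from a plain-text directory layout by
#' [write_bundle()] / [read_bundle()]; the roundtrip is lossless (numeric
#' fields are serialized with 17 significant digits, enough to restore every
#' double bit-for-bit).
#'
#' @param grid A [grid_spec()].
#' @param cells Data.frame with at least cell_id, slice_id, lateral_pos_um,
#'   depth_um, subtype (zero rows allowed).
#' @param truths Optional named list of `ground_truth` objects.
#' @param sweeps Optional named list of `sweep_set`s.
#' @param maps Optional named list of `list(input =, connectivity =)` pairs.
#' @return An object of class `experiment_bundle`.
#' @export
experiment_bundle <- function(grid, cells, truths = NULL, sweeps = NULL,
                              maps = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.data.frame(cells))
  need <- c("cell_id", "slice_id", "lateral_pos_um", "depth_um", "subtype")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells is missing field(s): ", paste(miss, collapse = ", "))
  for (nm in names(truths)) stopifnot(inherits(truths[[nm]], "ground_truth"))
  for (nm in names(sweeps)) stopifnot(inherits(sweeps[[nm]], "sweep_set"))
  for (nm in names(maps)) stopifnot(inherits(maps[[nm]]$input, "input_map"),
                                    inherits(maps[[nm]]$connectivity,
                                             "connectivity_map"))
  structure(list(grid = grid, cells = cells, truths = truths,
                 sweeps = sweeps, maps = maps),
            class = "experiment_bundle")
}

# full-precision text helpers -------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_txt <- function(m, path) {
  lines <- if (nrow(m) == 0L) character(0)
  else do.call(paste, c(asplit(matrix(fmt_num(m), nrow(m)), 2), sep = ","))
  writeLines(c(paste(ncol(m)), lines), path)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  nc <- as.integer(lines[1])
  body <- lines[-1]
  if (!length(body)) return(matrix(numeric(0), 0, nc))
  matrix(as.numeric(unlist(strsplit(body, ",", fixed = TRUE))),
         nrow = length(body), ncol = nc, byrow = TRUE)
}

#' Write an experiment bundle to disk
#'
#' Plain-text directory layout:
#' `grid.json`, `cells.csv`, `truth/<cell_id>.json`,
#' `sweeps/<cell_id>.csv` (+ `sweeps/<cell_id>_meta.json`),
#' `maps/<cell_id>_input.txt` and `maps/<cell_id>_connectivity.txt`,
#' and a `bundle.json` manifest.
#'
#' @param bundle An [experiment_bundle()].
#' @param path Directory to create (must not already contain a bundle unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing bundle directory.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, overwrite = FALSE) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (dir.exists(path)) {
    if (!overwrite && file.exists(file.path(path, "bundle.json")))
      stop("bundle already exists at ", path, " (use overwrite = TRUE)")
  } else dir.create(path, recursive = TRUE)
  g <- bundle$grid
  jsonlite::write_json(list(format = "lspsmap-bundle", version = 1L,
                            cell_ids = bundle$cells$cell_id,
                            truth_ids = names(bundle$truths),
                            sweep_ids = names(bundle$sweeps),
                            map_ids = names(bundle$maps),
                            has_truth = !is.null(bundle$truths),
                            has_sweeps = !is.null(bundle$sweeps),
                            has_maps = !is.null(bundle$maps)),
                       file.path(path, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(g), file.path(path, "grid.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$cells, file.path(path, "cells.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$truths)) {
    dir.create(file.path(path, "truth"), showWarnings = FALSE)
    for (id in names(bundle$truths)) {
      tr <- bundle$truths[[id]]
      jsonlite::write_json(list(cell_id = tr$cell_id, sources = tr$sources,
                                cluster_plan = tr$cluster_plan,
                                n_clusters_drawn = tr$n_clusters_drawn,
                                target_um = tr$target_um, clipped = tr$clipped),
                           file.path(path, "truth", paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }
  if (!is.null(bundle$sweeps)) {
    dir.create(file.path(path, "sweeps"), showWarnings = FALSE)
    for (id in names(bundle$sweeps)) {
      ss <- bundle$sweeps[[id]]
      jsonlite::write_json(list(cell_id = ss$cell_id, n_reps = ss$n_reps,
                                sampling_rate_hz = ss$sampling_rate_hz,
                                stim_onset_ms = ss$stim_onset_ms,
                                trace_len_ms = ss$trace_len_ms),
                           file.path(path, "sweeps", paste0(id, "_meta.json")),
                           auto_unbox = TRUE, digits = NA)
      hdr <- paste0("site_row,site_col,rep,n_samples=", ncol(ss$traces))
      body <- do.call(paste, c(list(ss$index$site_row, ss$index$site_col,
                                    ss$index$rep),
                               asplit(matrix(fmt_num(ss$traces),
                                             nrow(ss$traces)), 2),
                               sep = ","))
      writeLines(c(hdr, body), file.path(path, "sweeps", paste0(id, ".csv")))
    }
  }
  if (!is.null(bundle$maps)) {
    dir.create(file.path(path, "maps"), showWarnings = FALSE)
    for (id in names(bundle$maps)) {
      write_matrix_txt(bundle$maps[[id]]$input$amplitudes,
                       file.path(path, "maps", paste0(id, "_input.txt")))
      write_matrix_txt(bundle$maps[[id]]$connectivity$connected + 0,
                       file.path(path, "maps", paste0(id, "_connectivity.txt")))
    }
  }
  invisible(path)
}

#' Read an experiment bundle from disk
#'
#' Inverse of [write_bundle()]. A malformed bundle raises an error naming
#' the missing file or field.
#'
#' @param path Bundle directory.
#' @return An [experiment_bundle()].
#' @export
read_bundle <- function(path) {
  need_file <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("malformed bundle: missing ", f)
    p
  }
  man <- jsonlite::read_json(need_file("bundle.json"), simplifyVector = TRUE)
  if (!identical(man$format, "lspsmap-bundle"))
    stop("malformed bundle: bundle.json lacks format 'lspsmap-bundle'")
  gj <- jsonlite::read_json(need_file("grid.json"), simplifyVector = TRUE)
  for (f in c("n_cols", "n_rows", "spacing_um", "refhor_col_offset_um",
              "l5a_row", "layer_scheme"))
    if (is.null(gj[[f]])) stop("malformed bundle: grid.json missing field ", f)
  grid <- grid_spec(gj$n_cols, gj$n_rows, gj$spacing_um,
                    gj$refhor_col_offset_um, gj$l5a_row, gj$layer_scheme)
  cells <- utils::read.csv(need_file("cells.csv"), stringsAsFactors = FALSE,
                           colClasses = c(cell_id = "character",
                                          slice_id = "character",
                                          subtype = "character"))
  truths <- sweeps <- maps <- NULL
  if (isTRUE(man$has_truth)) {
    ids <- as.character(man$truth_ids)
    truths <- stats::setNames(lapply(ids, function(id) {
      tj <- jsonlite::read_json(need_file(file.path("truth", paste0(id, ".json"))),
                                simplifyVector = TRUE)
      src <- as.data.frame(tj$sources)
      if (nrow(src) == 0L)
        src <- data.frame(row = integer(0), col = integer(0),
                          n_presyn = integer(0), mean_amp_pA = numeric(0))
      plan <- as.data.frame(tj$cluster_plan)
      if (nrow(plan) == 0L)
        plan <- data.frame(start_col = integer(0), end_col = integer(0))
      structure(list(cell_id = tj$cell_id, sources = src, cluster_plan = plan,
                     n_clusters_drawn = tj$n_clusters_drawn,
                     target_um = tj$target_um, clipped = tj$clipped),
                class = "ground_truth")
    }), ids)
  }
  if (isTRUE(man$has_sweeps)) {
    ids <- as.character(man$sweep_ids)
    sweeps <- stats::setNames(lapply(ids, function(id) {
      mj <- jsonlite::read_json(
        need_file(file.path("sweeps", paste0(id, "_meta.json"))),
        simplifyVector = TRUE)
      dt <- data.table::fread(need_file(file.path("sweeps", paste0(id, ".csv"))),
                              header = FALSE, skip = 1L, sep = ",")
      idx <- data.frame(site_row = as.integer(dt[[1]]),
                        site_col = as.integer(dt[[2]]),
                        rep = as.integer(dt[[3]]))
      tr <- as.matrix(dt[, -(1:3)])
      dimnames(tr) <- NULL
      structure(list(cell_id = mj$cell_id, grid = grid, traces = tr,
                     index = idx, n_reps = mj$n_reps,
                     sampling_rate_hz = mj$sampling_rate_hz,
                     stim_onset_ms = mj$stim_onset_ms,
                     trace_len_ms = mj$trace_len_ms),
                class = "sweep_set")
    }), ids)
  }
  if (isTRUE(man$has_maps)) {
    ids <- as.character(man$map_ids)
    maps <- stats::setNames(lapply(ids, function(id) {
      am <- read_matrix_txt(need_file(file.path("maps", paste0(id, "_input.txt"))))
      cm <- read_matrix_txt(need_file(file.path("maps",
                                                paste0(id, "_connectivity.txt"))))
      list(input = input_map(am, grid),
           connectivity = connectivity_map(cm > 0, grid))
    }), ids)
  }
  experiment_bundle(grid, cells, truths, sweeps, maps)
}
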