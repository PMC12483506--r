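#' Collapse a connectivity map and find its clusters
#'
#' The connectivity map is collapsed along the vertical (laminar) axis: a
#' column is connected iff any of its rows is. A cluster is a maximal run of
#' consecutive connected columns framed by unconnected ones (or the grid
#' edge); it may combine inputs from different layers. `ConsSites`
#' (`n_sites`) is the run length; a barrel column in the slice is ~150 um,
#' i.e. two sites, so each cluster accounts for `ceiling(n_sites / 2)`
#' cortical columns.
#'
#' @param cmap A [connectivity_map()].
#' @return A list with `profile` (logical per-column vector) and `clusters`
#'   (data.frame: start_col, end_col, n_sites, width_um, column_count; zero
#'   rows for an empty map).
#' @export
collapse_and_clusters <- function(cmap) {
  stopifnot(inherits(cmap, "connectivity_map"))
  profile <- apply(cmap$connected, 2, any)
  list(profile = profile, clusters = profile_clusters(profile, cmap$grid))
}

# maximal runs of TRUE in a collapsed profile
profile_clusters <- function(profile, grid) {
  r <- rle(as.logical(profile))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cl <- data.frame(start_col = starts[keep], end_col = ends[keep])
  cl$n_sites <- cl$end_col - cl$start_col + 1L
  cl$width_um <- cl$n_sites * grid$spacing_um
  cl$column_count <- ceiling(cl$n_sites / 2)
  cl
}

#' Number of cortical columns represented in a cluster set
#'
#' `sum(ceiling(ConsSites / 2))` over clusters: the estimated count of
#' ~150 um barrel columns providing input.
#'
#' @param clusters Cluster data.frame from [collapse_and_clusters()].
#' @return Integer column count (0 for an empty cluster set).
#' @export
column_count <- function(clusters) {
  if (nrow(clusters) == 0L) return(0L)
  as.integer(sum(ceiling(clusters$n_sites / 2)))
}

#' Input-field geometry of one cell
#'
#' The input field spans from the first to the last connected column; its
#' width counts the inclusive site extent (`(last - first + 1) * spacing`),
#' so a single connected site has width one spacing, not zero. Gaps are the
#' unconnected columns inside the field; `gap_fraction_pct` is their
#' percentage of the field, and `cluster_spacings_um` the gap run lengths
#' between consecutive clusters.
#'
#' @param clusters Cluster data.frame from [collapse_and_clusters()] (>= 1
#'   cluster).
#' @param grid The map's [grid_spec()].
#' @return An `input_field`: first_col, last_col, width_um, n_clusters,
#'   total_columns, gap_fraction_pct, cluster_spacings_um.
#' @export
field_metrics <- function(clusters, grid) {
  if (nrow(clusters) == 0L)
    stop("field metrics are undefined for an empty connectivity map")
  clusters <- clusters[order(clusters$start_col), , drop = FALSE]
  first <- clusters$start_col[1]
  last <- clusters$end_col[nrow(clusters)]
  span <- last - first + 1L
  n_conn <- sum(clusters$n_sites)
  spacings <- if (nrow(clusters) > 1L)
    (clusters$start_col[-1L] - clusters$end_col[-nrow(clusters)] - 1L) *
      grid$spacing_um
  else numeric(0)
  structure(list(first_col = first, last_col = last,
                 width_um = span * grid$spacing_um,
                 n_clusters = nrow(clusters),
                 total_columns = column_count(clusters),
                 gap_fraction_pct = 100 * (span - n_conn) / span,
                 cluster_spacings_um = spacings),
            class = "input_field")
}

#' Layer-wise EPSC totals of an input map
#'
#' For every cortical layer of the grid: whether the cell receives input from
#' it, the number of connected sites, the summed EPSC amplitude (`EPSC^T`),
#' and the mean amplitude per connected site. Layer totals sum to the
#' whole-map EPSC sum.
#'
#' @param imap An [input_map()].
#' @return Data.frame with one row per layer (in laminar order):
#'   layer, connected, n_sites, epsc_total_pA, mean_amp_pA.
#' @export
layer_summary <- function(imap) {
  stopifnot(inherits(imap, "input_map"))
  grid <- imap$grid
  layers <- unique(grid$layer_scheme)
  out <- do.call(rbind, lapply(layers, function(L) {
    a <- imap$amplitudes[grid$layer_scheme == L, , drop = FALSE]
    n <- sum(a > 0)
    data.frame(layer = L, connected = n > 0L, n_sites = n,
               epsc_total_pA = sum(a),
               mean_amp_pA = if (n > 0) sum(a) / n else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dominance of the strongest connectivity cluster
#'
#' For cells with at least two clusters: each cluster's EPSC sum is the total
#' map amplitude over its columns (all rows); the ratio divides the largest
#' cluster sum by the mean of the remaining cluster sums
#' (`mode = "mean"`, the default) or by their total (`mode = "sum"`).
#'
#' @param imap An [input_map()].
#' @param clusters Cluster data.frame from [collapse_and_clusters()] of the
#'   map's connectivity support.
#' @param mode How the other clusters are aggregated in the denominator.
#' @return Ratio >= 1 under `mode = "mean"` when the map is non-trivial.
#' @export
dominant_cluster_ratio <- function(imap, clusters, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(imap, "input_map"))
  if (nrow(clusters) < 2L)
    stop("dominant-cluster ratio is defined only for cells with >= 2 clusters")
  sums <- vapply(seq_len(nrow(clusters)), function(k)
    sum(imap$amplitudes[, clusters$start_col[k]:clusters$end_col[k]]),
    numeric(1))
  top <- which.max(sums)
  others <- sums[-top]
  sums[top] / if (mode == "mean") mean(others) else sum(others)
}

#' Per-cell connectivity-pattern metrics row
#'
#' One row of the cohort metrics table: cluster counts, column count, field
#' width and gap fraction, mean cluster width, whole-map and per-layer EPSC
#' sums, and the dominant-cluster ratio (NA for cells with fewer than two
#' clusters). Cells with empty connectivity maps get NA pattern metrics and
#' `n_clusters = 0`; they are reported but excluded from pattern summaries.
#'
#' @param imap An [input_map()].
#' @param cell Optional one-row data.frame (or list) with cell_id, subtype,
#'   lateral_pos_um; carried into the output.
#' @param ratio_mode Passed to [dominant_cluster_ratio()].
#' @return A one-row data.frame.
#' @export
cell_metrics <- function(imap, cell = NULL, ratio_mode = "mean") {
  cmap <- as_connectivity_map(imap)
  cc <- collapse_and_clusters(cmap)
  grid <- imap$grid
  ls <- layer_summary(imap)
  base <- data.frame(
    cell_id = if (!is.null(cell)) cell$cell_id else NA_character_,
    subtype = if (!is.null(cell) && !is.null(cell$subtype)) cell$subtype else NA_character_,
    lateral_pos_um = if (!is.null(cell) && !is.null(cell$lateral_pos_um))
      cell$lateral_pos_um else NA_real_,
    stringsAsFactors = FALSE)
  if (nrow(cc$clusters) == 0L) {
    out <- cbind(base, data.frame(
      n_connected_sites = 0L, n_clusters = 0L, total_columns = 0L,
      field_width_um = NA_real_, gap_pct = NA_real_,
      mean_cluster_width_um = NA_real_, epsc_sum_pA = 0,
      connectivity_cm_um = NA_real_, synaptic_cm_um = NA_real_,
      dominant_ratio = NA_real_))
  } else {
    fm <- field_metrics(cc$clusters, grid)
    out <- cbind(base, data.frame(
      n_connected_sites = sum(cmap$connected),
      n_clusters = fm$n_clusters, total_columns = fm$total_columns,
      field_width_um = fm$width_um, gap_pct = fm$gap_fraction_pct,
      mean_cluster_width_um = mean(cc$clusters$width_um),
      epsc_sum_pA = sum(imap$amplitudes),
      connectivity_cm_um = connectivity_cm(cmap),
      synaptic_cm_um = synaptic_cm(imap),
      dominant_ratio = if (fm$n_clusters >= 2)
        dominant_cluster_ratio(imap, cc$clusters, ratio_mode) else NA_real_))
  }
  for (L in unique(grid$layer_scheme)) {
    nm <- paste0("epsc_", gsub("[^A-Za-z0-9]", "", L), "_pA")
    out[[nm]] <- ls$epsc_total_pA[ls$layer == L]
  }
  out
}
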