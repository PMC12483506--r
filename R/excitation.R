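#' Excitation profile container
#'
#' AP-count map of one cortical neuron under grid uncaging in current clamp,
#' with derived totals: `total_spikes`, `sap` (number of firing sites at the
#' profile's grid spacing, called sAP_50 on the standard 50 um calibration
#' grid), `spikes_per_firing_site`, and `sap_75` - the firing-site count
#' converted to the 75 um mapping grid with [convert_site_count()].
#'
#' @param ap_counts Integer matrix of AP counts per site (>= 0).
#' @param soma_site Length-2 (row, col) of the soma site.
#' @param grid The profile's [grid_spec()] (typically [excitation_grid()]).
#' @param cell_type Free-text type label (e.g., "L5A_RS"); metadata only.
#' @return An object of class `excitation_profile`.
#' @export
excitation_profile <- function(ap_counts, soma_site, grid = excitation_grid(),
                               cell_type = "unknown") {
  ap_counts <- as.matrix(ap_counts)
  if (!all(dim(ap_counts) == c(grid$n_rows, grid$n_cols)))
    stop("ap_counts must be ", grid$n_rows, " x ", grid$n_cols)
  if (anyNA(ap_counts) || any(ap_counts < 0) || any(ap_counts != round(ap_counts)))
    stop("ap_counts must be non-negative integers")
  soma_site <- as.integer(soma_site)
  stopifnot(length(soma_site) == 2L,
            soma_site[1] >= 1L, soma_site[1] <= grid$n_rows,
            soma_site[2] >= 1L, soma_site[2] <= grid$n_cols)
  storage.mode(ap_counts) <- "integer"
  sap <- sum(ap_counts >= 1L)
  structure(list(grid = grid, ap_counts = ap_counts, soma_site = soma_site,
                 cell_type = cell_type,
                 total_spikes = sum(ap_counts), sap = sap,
                 spikes_per_firing_site = if (sap > 0) sum(ap_counts) / sap
                 else NA_real_,
                 sap_75 = convert_site_count(sap, grid$spacing_um, 75)),
            class = "excitation_profile")
}

#' @export
print.excitation_profile <- function(x, ...) {
  cat(sprintf("Excitation profile (%s): %d spikes on %d sites (%.2f/site), sAP75 = %.2f\n",
              x$cell_type, x$total_spikes, x$sap,
              if (x$sap > 0) x$total_spikes / x$sap else NA, x$sap_75))
  invisible(x)
}

#' AP metrics from counts or membrane-potential traces
#'
#' Builds an [excitation_profile()] either directly from a per-site AP-count
#' matrix or from raw current-clamp traces, in which case APs are counted as
#' upward crossings of `spike_threshold_mv` (default 0 mV).
#'
#' @param x AP-count matrix, or a list of numeric traces (mV) arranged
#'   site-by-site in column-major grid order.
#' @param soma_site (row, col) of the soma site.
#' @param grid The profile's [grid_spec()].
#' @param cell_type Type label, metadata only.
#' @param spike_threshold_mv Crossing level used when traces are given.
#' @return An `excitation_profile`.
#' @export
ap_metrics <- function(x, soma_site, grid = excitation_grid(),
                       cell_type = "unknown", spike_threshold_mv = 0) {
  if (is.list(x)) {
    if (length(x) != grid$n_rows * grid$n_cols)
      stop("need one trace per grid site (", grid$n_rows * grid$n_cols, ")")
    counts <- matrix(vapply(x, count_spikes, integer(1),
                            threshold = spike_threshold_mv),
                     grid$n_rows, grid$n_cols)
  } else {
    counts <- as.matrix(x)
  }
  excitation_profile(counts, soma_site, grid, cell_type)
}

#' Count action potentials in a membrane-potential trace
#'
#' Number of upward crossings of the threshold.
#'
#' @param trace Numeric membrane potential (mV).
#' @param threshold Crossing level, default 0 mV.
#' @return Integer spike count.
#' @export
count_spikes <- function(trace, threshold = 0) {
  if (!all(is.finite(trace))) stop("non-finite samples in trace")
  above <- trace > threshold
  sum(diff(above) == 1L) + as.integer(above[1])
}

#' Convert a firing-site count between grid spacings
#'
#' Area-preserving rescaling of the number of sites with APs: one site on a
#' grid of spacing `s` stands for an area of `s^2`, so the same excitable
#' territory covers `sap * (spacing_from / spacing_to)^2` sites at the new
#' spacing. Converting the 50 um calibration grids to the 75 um mapping grid
#' therefore multiplies by (50/75)^2 = 4/9. (The reciprocal ratio sometimes
#' quoted for this conversion is a typo: it would inflate, not conserve, the
#' excited area.)
#'
#' @param sap Firing-site count at `spacing_from_um`.
#' @param spacing_from_um,spacing_to_um Grid spacings in um.
#' @return Converted (fractional) site count.
#' @export
convert_site_count <- function(sap, spacing_from_um, spacing_to_um) {
  stopifnot(spacing_from_um > 0, spacing_to_um > 0, all(sap >= 0))
  sap * (spacing_from_um / spacing_to_um)^2
}

#' Excitation radius of a profile
#'
#' Maximal Euclidean distance from the soma site to any firing site (0 when
#' only the somatic site fires, error when no site fires).
#'
#' @param profile An [excitation_profile()].
#' @return Radius in um.
#' @export
excitation_radius <- function(profile) {
  stopifnot(inherits(profile, "excitation_profile"))
  idx <- which(profile$ap_counts >= 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no firing site: excitation radius is undefined")
  d <- profile$grid$spacing_um *
    sqrt((idx[, 1] - profile$soma_site[1])^2 + (idx[, 2] - profile$soma_site[2])^2)
  max(d)
}
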