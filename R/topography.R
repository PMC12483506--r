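#' Connectivity center of mass
#'
#' Lateral center of mass of the binary map: each column is weighted by its
#' vertical count of connected sites,
#' `sum(count_col * lateral_um) / sum(count_col)`. Equivalent to the mean
#' lateral position over all connected sites.
#'
#' @param cmap A [connectivity_map()] with at least one connected site.
#' @return Lateral position in um from Ref_hor.
#' @export
connectivity_cm <- function(cmap) {
  stopifnot(inherits(cmap, "connectivity_map"))
  cnt <- colSums(cmap$connected)
  if (sum(cnt) == 0)
    stop("center of mass is undefined for an empty connectivity map")
  pos <- site_lateral_um(seq_len(cmap$grid$n_cols), cmap$grid)
  sum(cnt * pos) / sum(cnt)
}

#' Synaptic-input center of mass
#'
#' Amplitude-weighted lateral center of mass of the thresholded input map:
#' each column is weighted by the mean EPSC amplitude over its connected
#' sites (zeros excluded - including them would re-weight columns by their
#' depth coverage), `sum(mean_vert_EPSC * lateral_um) / sum(mean_vert_EPSC)`.
#'
#' @param imap An [input_map()] with at least one nonzero site.
#' @return Lateral position in um from Ref_hor.
#' @export
synaptic_cm <- function(imap) {
  stopifnot(inherits(imap, "input_map"))
  a <- imap$amplitudes
  n <- colSums(a > 0)
  if (sum(n) == 0)
    stop("center of mass is undefined for an empty input map")
  w <- ifelse(n > 0, colSums(a) / pmax(n, 1L), 0)
  pos <- site_lateral_um(seq_len(imap$grid$n_cols), imap$grid)
  sum(w * pos) / sum(w)
}

#' Cohort topography summary
#'
#' Correlates the cells' centers of mass in the cortex with their lateral
#' positions in the striatum (descriptive Pearson and Spearman R), fits the
#' least-squares line, and reports signed per-cell residuals. When both the
#' connectivity and the synaptic-input CM are supplied, their residual
#' magnitudes are compared descriptively.
#'
#' @param lateral_pos_um Cell positions (um from Ref_hor).
#' @param cm_um Matching centers of mass (um); NA cells are dropped.
#' @param cm2_um Optional second CM set (e.g., synaptic-input CM) for the
#'   residual comparison.
#' @return A list: n, pearson_r, spearman_r, slope, intercept, residuals_um,
#'   and (with `cm2_um`) residuals2_um and mean_abs_residual_um per CM.
#' @export
topography_summary <- function(lateral_pos_um, cm_um, cm2_um = NULL) {
  ok <- is.finite(lateral_pos_um) & is.finite(cm_um)
  x <- lateral_pos_um[ok]; y <- cm_um[ok]
  if (length(x) < 3L)
    stop("topography summary needs >= 3 cells with a defined center of mass")
  fit <- stats::lm(y ~ x)
  out <- list(n = length(x),
              pearson_r = stats::cor(x, y),
              spearman_r = stats::cor(x, y, method = "spearman"),
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              residuals_um = unname(stats::residuals(fit)),
              mean_abs_residual_um = mean(abs(stats::residuals(fit))))
  if (!is.null(cm2_um)) {
    y2 <- cm2_um[ok]
    fit2 <- stats::lm(y2 ~ x)
    out$residuals2_um <- unname(stats::residuals(fit2))
    out$mean_abs_residual2_um <- mean(abs(stats::residuals(fit2)))
  }
  out
}

#' Width of the projection zone per cortical bin
#'
#' For every `bin_um` bin of the cortical lateral axis (anchored at
#' Ref_hor), collects the cells with at least one connected site whose column
#' falls in the bin, and reports the maximal pairwise distance between those
#' cells' positions in the striatum - the striatal extent innervated by one
#' cortical locus. Bins with fewer than two cells are NA.
#'
#' @param cmaps List of [connectivity_map()]s (shared alignment).
#' @param lateral_pos_um Matching cell positions (um).
#' @param bin_um Bin width on the cortical axis, default 150 um.
#' @return Data.frame: bin_lo_um, bin_hi_um, n_cells, max_spn_distance_um.
#' @export
projection_zone_width <- function(cmaps, lateral_pos_um, bin_um = 150) {
  stopifnot(length(cmaps) == length(lateral_pos_um), length(cmaps) >= 2L)
  grid <- cmaps[[1]]$grid
  pos_cols <- site_lateral_um(seq_len(grid$n_cols), grid)
  site_bin <- floor(pos_cols / bin_um)
  bins <- sort(unique(site_bin))
  per_cell_bins <- lapply(cmaps, function(cm) {
    cols <- which(apply(cm$connected, 2, any))
    unique(site_bin[cols])
  })
  out <- do.call(rbind, lapply(bins, function(b) {
    inb <- vapply(per_cell_bins, function(bb) b %in% bb, logical(1))
    p <- lateral_pos_um[inb]
    data.frame(bin_lo_um = b * bin_um, bin_hi_um = (b + 1) * bin_um,
               n_cells = length(p),
               max_spn_distance_um = if (length(p) >= 2)
                 max(p) - min(p) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
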