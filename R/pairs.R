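#' Pairwise map comparison for two cells of one slice
#'
#' Heterogeneity statistics for two SPNs recorded in the same slice (shared
#' grid alignment):
#' * `field_overlap_um` - inclusive intersection length of the two input
#'   fields' column intervals (0 when disjoint);
#' * `aligned_pct` - a connected site is "vertically aligned" when its column
#'   contains at least one connected site of the other map; the percentage is
#'   pooled over both maps, `100 * (alignedA + alignedB) / (|A| + |B|)`;
#' * `overlap_pct` - exact (row, col) coincidence,
#'   `100 * 2|A intersect B| / (|A| + |B|)`.
#' Per-map fractions are also reported for transparency. Site matching is
#' strict same-column; no tolerance for the ~75 um excitation resolution.
#'
#' @param cmap_a,cmap_b [connectivity_map()]s of the two cells, each with at
#'   least one connected site.
#' @param pos_a_um,pos_b_um Lateral cell positions (um from Ref_hor).
#' @param slice_a,slice_b Optional slice ids; if given they must match.
#' @return A `pair_metrics` list: spn_distance_um, field_overlap_um,
#'   aligned_pct, overlap_pct, aligned_pct_a/b, overlap_pct_a/b, n_a, n_b.
#' @export
pair_metrics <- function(cmap_a, cmap_b, pos_a_um = NA_real_,
                         pos_b_um = NA_real_, slice_a = NULL, slice_b = NULL) {
  stopifnot(inherits(cmap_a, "connectivity_map"),
            inherits(cmap_b, "connectivity_map"))
  if (!is.null(slice_a) && !is.null(slice_b) && !identical(slice_a, slice_b))
    stop("pair metrics are defined only for cells recorded in the same slice")
  if (!same_grid(cmap_a$grid, cmap_b$grid))
    stop("the two maps must share one grid alignment")
  A <- cmap_a$connected; B <- cmap_b$connected
  nA <- sum(A); nB <- sum(B)
  if (nA == 0L || nB == 0L)
    stop("pair metrics need >= 1 connected site in each map")
  colsA <- apply(A, 2, any); colsB <- apply(B, 2, any)
  ivA <- range(which(colsA)); ivB <- range(which(colsB))
  ov_cols <- min(ivA[2], ivB[2]) - max(ivA[1], ivB[1]) + 1L
  spacing <- cmap_a$grid$spacing_um
  alignedA <- sum(A[, colsB, drop = FALSE])
  alignedB <- sum(B[, colsA, drop = FALSE])
  inter <- sum(A & B)
  structure(list(
    spn_distance_um = abs(pos_a_um - pos_b_um),
    field_overlap_um = max(0L, ov_cols) * spacing,
    aligned_pct = 100 * (alignedA + alignedB) / (nA + nB),
    overlap_pct = 100 * 2 * inter / (nA + nB),
    aligned_pct_a = 100 * alignedA / nA,
    aligned_pct_b = 100 * alignedB / nB,
    overlap_pct_a = 100 * inter / nA,
    overlap_pct_b = 100 * inter / nB,
    n_a = nA, n_b = nB), class = "pair_metrics")
}

#' All same-slice pair metrics of a cohort
#'
#' @param cmaps Named list of [connectivity_map()]s (names = cell ids).
#' @param cells Data.frame with cell_id, slice_id, lateral_pos_um.
#' @return Data.frame with one row per unordered same-slice pair (cells with
#'   empty maps are skipped).
#' @export
cohort_pairs <- function(cmaps, cells) {
  stopifnot(all(c("cell_id", "slice_id", "lateral_pos_um") %in% names(cells)))
  keep <- vapply(cells$cell_id, function(id)
    !is.null(cmaps[[id]]) && sum(cmaps[[id]]$connected) > 0, logical(1))
  cells <- cells[keep, , drop = FALSE]
  rows <- list()
  for (sl in unique(cells$slice_id)) {
    ids <- cells$cell_id[cells$slice_id == sl]
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      a <- ids[i]; b <- ids[j]
      pm <- pair_metrics(cmaps[[a]], cmaps[[b]],
                         cells$lateral_pos_um[cells$cell_id == a],
                         cells$lateral_pos_um[cells$cell_id == b],
                         sl, sl)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_a = a, cell_b = b, slice_id = sl,
        spn_distance_um = pm$spn_distance_um,
        field_overlap_um = pm$field_overlap_um,
        aligned_pct = pm$aligned_pct, overlap_pct = pm$overlap_pct,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cell_a = character(0), cell_b = character(0),
                      slice_id = character(0), spn_distance_um = numeric(0),
                      field_overlap_um = numeric(0), aligned_pct = numeric(0),
                      overlap_pct = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance-binned summary of pairwise heterogeneity
#'
#' Pairs are binned by inter-soma distance into half-open bins
#' `[k*bin_um, (k+1)*bin_um)`. Per bin: the fraction of pairs whose input
#' fields overlap at all, the mean overlap width, and the mean aligned and
#' overlap percentages. Bins without pairs are reported as NA (lack of
#' data), not zero.
#'
#' @param pairs Data.frame from [cohort_pairs()] (or [pair_metrics()] rows).
#' @param bin_um Distance bin width, default 100 um.
#' @param max_um Upper edge of the last bin; defaults to cover the largest
#'   observed distance.
#' @return Data.frame: bin_lo_um, bin_hi_um, n_pairs, frac_with_overlap,
#'   mean_overlap_um, mean_aligned_pct, mean_overlap_pct.
#' @export
cohort_pair_summary <- function(pairs, bin_um = 100, max_um = NULL) {
  if (nrow(pairs) == 0L) stop("no pairs to summarize")
  d <- pairs$spn_distance_um
  if (is.null(max_um)) max_um <- (floor(max(d) / bin_um) + 1) * bin_um
  edges <- seq(0, max_um, by = bin_um)
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(k) {
    inb <- d >= edges[k] & d < edges[k + 1L]
    if (!any(inb)) {
      data.frame(bin_lo_um = edges[k], bin_hi_um = edges[k + 1L], n_pairs = 0L,
                 frac_with_overlap = NA_real_, mean_overlap_um = NA_real_,
                 mean_aligned_pct = NA_real_, mean_overlap_pct = NA_real_)
    } else {
      p <- pairs[inb, , drop = FALSE]
      data.frame(bin_lo_um = edges[k], bin_hi_um = edges[k + 1L],
                 n_pairs = sum(inb),
                 frac_with_overlap = mean(p$field_overlap_um > 0),
                 mean_overlap_um = mean(p$field_overlap_um),
                 mean_aligned_pct = mean(p$aligned_pct),
                 mean_overlap_pct = mean(p$overlap_pct))
    }
  }))
  rownames(out) <- NULL
  out
}
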