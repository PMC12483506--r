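#' Stimulation grid specification
#'
#' Describes the LSPS uncaging grid: its dimensions, inter-site spacing, how
#' its columns are positioned relative to the horizontal anatomical reference
#' (`Ref_hor`, the junction of dorsal striatum, GPe and internal capsule), and
#' which cortical layer each row belongs to. The default is the standard
#' mapping grid: 29 columns by 16 rows at 75 um spacing, with row 1 nearest
#' the pia, layer 5a on row 10, and the layer scheme
#' L2/3 = rows 1-6, L4 = 7-9, L5a = 10, L5b = 11-13, L6 = 14-16.
#'
#' @param n_cols,n_rows Grid dimensions (columns increase laterally, rows
#'   increase with cortical depth).
#' @param spacing_um Inter-site distance in micrometers.
#' @param refhor_col_offset_um Signed lateral position of grid column 1
#'   relative to `Ref_hor`, in micrometers. Alignment across slices is pure
#'   metadata: maps are never resampled, each slice just carries its own
#'   offset (and `l5a_row` for the vertical reference).
#' @param l5a_row Row index of layer 5a, the vertical alignment reference.
#' @param layer_scheme Character vector of length `n_rows` giving the layer
#'   label of every row. Must cover each row exactly once.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' assign_layer(10, g)       # "L5a"
#' site_lateral_um(2, g)     # 75
#' @export
grid_spec <- function(n_cols = 29L, n_rows = 16L, spacing_um = 75,
                      refhor_col_offset_um = 0, l5a_row = 10L,
                      layer_scheme = default_layer_scheme(n_rows)) {
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  stopifnot(n_cols >= 1L, n_rows >= 1L, spacing_um > 0,
            is.numeric(refhor_col_offset_um), length(refhor_col_offset_um) == 1L)
  if (length(layer_scheme) != n_rows)
    stop("layer_scheme must label every row exactly once (length ", n_rows, ")")
  if (anyNA(layer_scheme))
    stop("layer_scheme must not contain NA")
  l5a_row <- as.integer(l5a_row)
  stopifnot(l5a_row >= 1L, l5a_row <= n_rows)
  structure(
    list(n_cols = n_cols, n_rows = n_rows, spacing_um = spacing_um,
         refhor_col_offset_um = refhor_col_offset_um, l5a_row = l5a_row,
         layer_scheme = as.character(layer_scheme)),
    class = "grid_spec")
}

#' Default cortical layer scheme by grid row
#'
#' Row 1 is nearest the pia. For the standard 16-row grid the scheme is
#' L2/3: rows 1-6, L4: 7-9, L5a: 10, L5b: 11-13, L6: 14-16. Other row counts
#' must be labelled explicitly by the caller.
#'
#' @param n_rows Number of grid rows.
#' @return Character vector of layer labels, one per row.
#' @export
default_layer_scheme <- function(n_rows = 16L) {
  if (n_rows != 16L)
    stop("no default layer scheme for n_rows != 16; supply layer_scheme")
  c(rep("L2/3", 6), rep("L4", 3), "L5a", rep("L5b", 3), rep("L6", 3))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("LSPS grid: %d cols x %d rows, %g um spacing\n",
              x$n_cols, x$n_rows, x$spacing_um))
  cat(sprintf("  column 1 at %g um from Ref_hor; L5a on row %d\n",
              x$refhor_col_offset_um, x$l5a_row))
  invisible(x)
}

#' Cortical layer of a grid row
#'
#' @param row Grid row index (1-based, row 1 nearest the pia).
#' @param grid A [grid_spec()].
#' @return The layer label of that row.
#' @export
assign_layer <- function(row, grid = grid_spec()) {
  row <- as.integer(row)
  if (any(row < 1L | row > grid$n_rows))
    stop("row index out of range 1..", grid$n_rows)
  grid$layer_scheme[row]
}

#' Lateral position of a grid column
#'
#' Position of a column's sites relative to the horizontal anatomical
#' reference `Ref_hor`, in micrometers:
#' `refhor_col_offset_um + (col - 1) * spacing_um`.
#'
#' @param col Grid column index (1-based).
#' @param grid A [grid_spec()].
#' @return Lateral position in um (vectorized over `col`).
#' @export
site_lateral_um <- function(col, grid = grid_spec()) {
  col <- as.integer(col)
  if (any(col < 1L | col > grid$n_cols))
    stop("column index out of range 1..", grid$n_cols)
  grid$refhor_col_offset_um + (col - 1) * grid$spacing_um
}

#' Synaptic input map
#'
#' Grid of mean evoked-EPSC amplitudes per stimulation site, in pA. All
#' entries are finite and non-negative; 0 means "not connected". Rows index
#' cortical depth, columns the lateral axis, as in the parent [grid_spec()].
#'
#' @param amplitudes Numeric `n_rows x n_cols` matrix of non-negative pA
#'   magnitudes.
#' @param grid A [grid_spec()] with matching dimensions.
#' @return An object of class `input_map`.
#' @export
input_map <- function(amplitudes, grid = grid_spec()) {
  amplitudes <- as.matrix(amplitudes)
  if (!all(dim(amplitudes) == c(grid$n_rows, grid$n_cols)))
    stop("amplitudes must be ", grid$n_rows, " x ", grid$n_cols)
  if (!all(is.finite(amplitudes)) || any(amplitudes < 0))
    stop("amplitudes must be finite and >= 0 (positive EPSC magnitudes)")
  dimnames(amplitudes) <- NULL
  structure(list(grid = grid, amplitudes = amplitudes), class = "input_map")
}

#' Binary connectivity map
#'
#' The support of an input map: TRUE where stimulation evoked EPSCs meeting
#' the detection and repetition-consistency rules.
#'
#' @param connected Logical `n_rows x n_cols` matrix.
#' @param grid A [grid_spec()] with matching dimensions.
#' @return An object of class `connectivity_map`.
#' @export
connectivity_map <- function(connected, grid = grid_spec()) {
  connected <- as.matrix(connected)
  if (!all(dim(connected) == c(grid$n_rows, grid$n_cols)))
    stop("connected must be ", grid$n_rows, " x ", grid$n_cols)
  if (anyNA(connected)) stop("connected must not contain NA")
  storage.mode(connected) <- "logical"
  dimnames(connected) <- NULL
  structure(list(grid = grid, connected = connected), class = "connectivity_map")
}

#' Derive the connectivity map from an input map
#'
#' @param imap An [input_map()].
#' @return The [connectivity_map()] with `connected = amplitudes > 0`.
#' @export
as_connectivity_map <- function(imap) {
  stopifnot(inherits(imap, "input_map"))
  connectivity_map(imap$amplitudes > 0, imap$grid)
}

#' @export
print.input_map <- function(x, ...) {
  cat(sprintf("Input map (%d x %d): %d connected sites, EPSC sum %.1f pA\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$amplitudes > 0),
              sum(x$amplitudes)))
  invisible(x)
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("Connectivity map (%d x %d): %d connected sites\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$connected)))
  invisible(x)
}

# internal: equality of two grid specs (alignment check for pair analysis)
same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("n_cols", "n_rows", "spacing_um")],
                   b[c("n_cols", "n_rows", "spacing_um")]))
}
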