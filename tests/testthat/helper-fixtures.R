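# shared fixtures: hand-built truths, random maps, and independent oracles

# a ground_truth with explicit source sites (cluster plan derived from them)
make_truth <- function(sources, grid, cell_id = "cellX") {
  sources <- as.data.frame(sources)
  if (is.null(sources$n_presyn)) sources$n_presyn <- 1L
  if (is.null(sources$mean_amp_pA)) sources$mean_amp_pA <- 40
  cols <- sort(unique(sources$col))
  if (length(cols)) {
    br <- c(0L, which(diff(cols) > 1L), length(cols))
    plan <- data.frame(start_col = cols[br[-length(br)] + 1L],
                       end_col = cols[br[-1L]])
  } else {
    plan <- data.frame(start_col = integer(0), end_col = integer(0))
  }
  structure(list(cell_id = cell_id, sources = sources, cluster_plan = plan,
                 n_clusters_drawn = nrow(plan), target_um = NA_real_,
                 clipped = FALSE),
            class = "ground_truth")
}

empty_truth <- function(cell_id = "null") {
  make_truth(data.frame(row = integer(0), col = integer(0),
                        n_presyn = integer(0), mean_amp_pA = numeric(0)),
             grid_spec(), cell_id)
}

# small grid for fast sweep-level tests
small_grid <- function(n = 6L) {
  grid_spec(n_cols = n, n_rows = n, l5a_row = 1L, layer_scheme = rep("x", n))
}

random_cmap <- function(grid, p = 0.08) {
  connectivity_map(matrix(stats::runif(grid$n_rows * grid$n_cols) < p,
                          grid$n_rows, grid$n_cols), grid)
}

# brute-force run-length oracle for clusters on a collapsed profile
oracle_clusters <- function(profile) {
  out <- list()
  start <- NA
  for (i in seq_along(profile)) {
    if (profile[i] && is.na(start)) start <- i
    if (!profile[i] && !is.na(start)) {
      out[[length(out) + 1L]] <- c(start, i - 1L)
      start <- NA
    }
  }
  if (!is.na(start)) out[[length(out) + 1L]] <- c(start, length(profile))
  if (!length(out)) return(data.frame(start_col = integer(0), end_col = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start_col = m[, 1], end_col = m[, 2])
}

# direct per-site evaluation of the connectivity CM
oracle_connectivity_cm <- function(cmap) {
  idx <- which(cmap$connected, arr.ind = TRUE)
  mean(site_lateral_um(idx[, 2], cmap$grid))
}

# direct evaluation of the column-mean-weighted synaptic CM
oracle_synaptic_cm <- function(imap) {
  g <- imap$grid
  w <- pos <- numeric(0)
  for (cc in seq_len(g$n_cols)) {
    a <- imap$amplitudes[, cc]
    if (any(a > 0)) {
      w <- c(w, mean(a[a > 0]))
      pos <- c(pos, site_lateral_um(cc, g))
    }
  }
  sum(w * pos) / sum(w)
}

# deterministic sweep matrix: flat baseline pattern with sd ~3 pA plus an
# optional square 5 ms pulse of -amp at +10 ms in selected repetitions
pulse_sweeps <- function(amp_pA, reps_with_pulse, n_reps = 2L, fs = 1000) {
  n <- round(0.2 * fs)           # 200 ms trace, onset at 100 ms
  onset <- round(0.1 * fs)
  tr <- matrix(rep(c(3, -3), length.out = n), n_reps, n, byrow = TRUE)
  tr[, (onset + 1):n] <- 0
  for (r in reps_with_pulse) {
    j <- (onset + round(0.010 * fs) + 1):(onset + round(0.015 * fs))
    tr[r, j] <- -amp_pA
  }
  tr
}
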