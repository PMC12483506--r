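#' Recording noise and EPSC kinetics model
#'
#' Parameters of the synthetic sweep generator. Defaults emulate the
#' recordings the pipeline was designed for: white Gaussian baseline noise
#' whose 3-SD level is ~9.2 pA (sd 3.07 pA; an autocorrelated option
#' exists), spontaneous EPSCs of 10-20 pA at a low Poisson rate, and evoked
#' EPSCs with short latency and AMPA-like difference-of-exponentials
#' kinetics (rise 1 ms, decay 10 ms).
#'
#' The spontaneous-event rate controls the false-positive pressure on the
#' 3-SD + two-repetition detection rule: a spontaneous event falling in the
#' 50 ms response window of >= 2 of `n_reps` sweeps is indistinguishable from
#' an evoked response. The default 0.75 Hz keeps the site-level
#' false-positive probability below 1 percent at the default 3 repetitions
#' (see the methods vignette for the budget); it is a free parameter of the
#' emulated preparation, not a measured quantity.
#'
#' @param baseline_sd_pA Stationary SD of the baseline current noise (pA).
#' @param noise_corr_ms Autocorrelation time of the baseline noise (ms);
#'   0 gives white noise at the sample level.
#' @param spont_rate_hz Poisson rate of spontaneous EPSCs over the whole trace.
#' @param spont_amp_range_pA Length-2 range of spontaneous EPSC amplitudes (pA).
#' @param evoked_latency_mean_ms,evoked_latency_sd_ms Gaussian latency of the
#'   evoked EPSC peak onset after the uncaging pulse (clipped to stay inside
#'   the 50 ms detection window).
#' @param rise_tau_ms,decay_tau_ms EPSC kernel time constants.
#' @param amp_cv Trial-to-trial coefficient of variation of the per-synapse
#'   evoked amplitude.
#' @param n_reps Number of map repetitions (2-4).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_sd_pA = 3.07, noise_corr_ms = 0,
                        spont_rate_hz = 0.75, spont_amp_range_pA = c(10, 20),
                        evoked_latency_mean_ms = 7, evoked_latency_sd_ms = 2,
                        rise_tau_ms = 1, decay_tau_ms = 10,
                        amp_cv = 0.2, n_reps = 3L) {
  n_reps <- as.integer(n_reps)
  stopifnot(baseline_sd_pA >= 0, noise_corr_ms >= 0, spont_rate_hz >= 0,
            length(spont_amp_range_pA) == 2L, all(spont_amp_range_pA > 0),
            spont_amp_range_pA[1] <= spont_amp_range_pA[2],
            evoked_latency_mean_ms > 0, evoked_latency_sd_ms >= 0,
            rise_tau_ms > 0, decay_tau_ms > rise_tau_ms,
            amp_cv >= 0, n_reps >= 2L, n_reps <= 4L)
  structure(as.list(environment()), class = "noise_model")
}

#' Noise-free generator preset
#'
#' The deterministic regime used for exact pipeline-recovery checks: no
#' baseline noise, no spontaneous events, no amplitude or latency
#' variability. With it, detection must recover planted sources
#' site-for-site.
#'
#' @param ... Overrides passed to [noise_model()].
#' @return A `noise_model`.
#' @export
noise_free <- function(...) {
  noise_model(baseline_sd_pA = 0, spont_rate_hz = 0, amp_cv = 0,
              evoked_latency_sd_ms = 0, ...)
}

#' Connectivity-pattern parameters for cohort generation
#'
#' Distributions from which ground-truth connectivity patterns are drawn.
#' Defaults emulate the vibrissal corticostriatal projection: ~1.9 clusters
#' per cell on average, clusters mostly 1-2 columns wide (one barrel column
#' is ~150 um = 2 sites), inter-cluster spacings averaging ~260 um, a loose
#' lateromedial topography, and per-site evoked amplitudes log-normal around
#' 40 pA produced by 1-5 presynaptic cells per connected site.
#'
#' The topographic scatter `jitter_sd_um` sets the cohort correlation between
#' the connectivity center of mass and the cell position: with positions
#' uniform over `pos_range_um` (sd = range/sqrt(12)) the expected Pearson R
#' is `slope*sd(pos) / sqrt(slope^2*sd(pos)^2 + jitter_sd_um^2 + s_place^2)`,
#' where `s_place` (~150 um) is the scatter added by discrete cluster
#' placement. The default 550 um targets R ~ 0.6.
#'
#' @param n_cluster_probs Probabilities of 1, 2, ... clusters per cell
#'   (default mean 1.9).
#' @param width_probs Probabilities of cluster widths 1, 2, ... columns.
#' @param gap_mean_cols Mean inter-cluster gap in columns
#'   (gap = 1 + Poisson(gap_mean_cols - 1); default mean 3.5 columns
#'   ~ 260 um spacing).
#' @param slope,intercept_um Linear map from cell lateral position (um from
#'   Ref_hor in the striatum) to the target cortical center of mass.
#' @param jitter_sd_um Gaussian scatter of the target center of mass (um).
#' @param pos_range_um Range of cell lateral positions (um).
#' @param pos_on_lattice If TRUE, cell positions are snapped to site lateral
#'   positions so that with `jitter_sd_um = 0` and single-column clusters the
#'   realized center of mass equals the cell position exactly.
#' @param layer_probs Named probabilities that a connected site falls in each
#'   layer (names must match the grid's layer labels).
#' @param rows_per_col_probs Probabilities of 1, 2, ... connected rows within
#'   a connected column.
#' @param n_presyn_probs Probabilities of 1..5 presynaptic cells at a source.
#' @param mean_amp_pA Population mean evoked amplitude per connected site (pA).
#' @param amp_sdlog Log-scale SD of the per-site mean amplitude (log-normal,
#'   mean-corrected so the population mean stays `mean_amp_pA`).
#' @param subtype_probs Named probabilities of SPN subtypes.
#' @param cells_per_slice Cells recorded per slice (same-slice cells share a
#'   grid alignment and enter the pairwise analysis).
#' @param depth_range_um Soma depth below the slice surface (um).
#' @return An object of class `pattern_params`.
#' @export
pattern_params <- function(n_cluster_probs = c(0.45, 0.30, 0.15, 0.10),
                           width_probs = c(0.6, 0.3, 0.1),
                           gap_mean_cols = 3.5,
                           slope = 1, intercept_um = 0,
                           jitter_sd_um = 550,
                           pos_range_um = c(300, 1800),
                           pos_on_lattice = FALSE,
                           layer_probs = c("L2/3" = 0.10, "L4" = 0.15,
                                           "L5a" = 0.35, "L5b" = 0.25,
                                           "L6" = 0.15),
                           rows_per_col_probs = c(0.50, 0.35, 0.15),
                           n_presyn_probs = c(0.50, 0.25, 0.12, 0.08, 0.05),
                           mean_amp_pA = 40, amp_sdlog = 0.5,
                           subtype_probs = c(D1 = 0.5, D2 = 0.5),
                           cells_per_slice = 2L,
                           depth_range_um = c(80, 120)) {
  stopifnot(all(n_cluster_probs >= 0), sum(n_cluster_probs) > 0,
            all(width_probs >= 0), sum(width_probs) > 0,
            gap_mean_cols >= 1,
            length(pos_range_um) == 2L, pos_range_um[1] <= pos_range_um[2],
            jitter_sd_um >= 0, all(layer_probs >= 0), sum(layer_probs) > 0,
            all(rows_per_col_probs >= 0), all(n_presyn_probs >= 0),
            length(n_presyn_probs) <= 5L,
            mean_amp_pA > 0, amp_sdlog >= 0, cells_per_slice >= 1L)
  structure(as.list(environment()), class = "pattern_params")
}

#' Generate a cohort with known ground-truth connectivity
#'
#' Draws, for each cell, a lateral position in the striatum, a topographic
#' target center of mass in the cortex, a set of connectivity clusters placed
#' around that target, connected rows within each cluster column (weighted by
#' layer), and per-source amplitudes and presynaptic counts. The realized
#' cluster plan (after clipping to the grid and merging of touching clusters)
#' is stored with each truth so downstream recovery can be checked exactly.
#'
#' @param n_cells Number of cells.
#' @param grid A [grid_spec()].
#' @param pattern A [pattern_params()].
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return A list with `cells` (data.frame: cell_id, slice_id, lateral_pos_um,
#'   depth_um, subtype) and `truths` (named list of `ground_truth` objects:
#'   cell_id, sources data.frame (row, col, n_presyn, mean_amp_pA),
#'   cluster_plan data.frame (start_col, end_col), clipped flag).
#' @export
generate_cohort_truth <- function(n_cells, grid = grid_spec(),
                                  pattern = pattern_params(), seed = 1L) {
  stopifnot(n_cells >= 1)
  p <- pattern
  layer_w <- per_row_weights(grid, p$layer_probs)
  with_seed(derive_seed(seed, "cohort_truth"), {
    ids <- sprintf("cell%04d", seq_len(n_cells))
    slice <- sprintf("slice%03d", (seq_len(n_cells) - 1L) %/% p$cells_per_slice + 1L)
    pos <- stats::runif(n_cells, p$pos_range_um[1], p$pos_range_um[2])
    if (p$pos_on_lattice) {
      col0 <- pmin(pmax(round((pos - grid$refhor_col_offset_um) /
                                grid$spacing_um) + 1, 1), grid$n_cols)
      pos <- site_lateral_um(col0, grid)
    }
    depth <- stats::runif(n_cells, p$depth_range_um[1], p$depth_range_um[2])
    subtype <- sample(names(p$subtype_probs), n_cells, replace = TRUE,
                      prob = p$subtype_probs)
    cells <- data.frame(cell_id = ids, slice_id = slice,
                        lateral_pos_um = pos, depth_um = depth,
                        subtype = subtype, stringsAsFactors = FALSE)
    truths <- vector("list", n_cells)
    names(truths) <- ids
    for (i in seq_len(n_cells)) {
      target_um <- p$intercept_um + p$slope * pos[i] +
        (if (p$jitter_sd_um > 0) stats::rnorm(1, 0, p$jitter_sd_um) else 0)
      truths[[i]] <- draw_truth(ids[i], target_um, grid, p, layer_w)
    }
    list(cells = cells, truths = truths)
  })
}

# spread each layer's probability evenly over its rows
per_row_weights <- function(grid, layer_probs) {
  lab <- grid$layer_scheme
  missing <- setdiff(unique(lab), names(layer_probs))
  if (length(missing))
    stop("layer_probs has no entry for layer(s): ", paste(missing, collapse = ", "))
  w <- layer_probs[lab] / as.vector(table(lab)[lab])
  as.numeric(w / sum(w))
}

draw_truth <- function(cell_id, target_um, grid, p, layer_w) {
  n_cl <- sample.int(length(p$n_cluster_probs), 1L, prob = p$n_cluster_probs)
  widths <- sample.int(length(p$width_probs), n_cl, replace = TRUE,
                       prob = p$width_probs)
  target_col <- round((target_um - grid$refhor_col_offset_um) /
                        grid$spacing_um) + 1
  clipped <- FALSE
  # first cluster centred on the target column; later clusters pushed out on
  # alternating random sides, separated by >= 1 unconnected column
  start1 <- target_col - (widths[1] - 1L) %/% 2L
  iv <- matrix(c(start1, start1 + widths[1] - 1L), nrow = 1)
  if (n_cl > 1) {
    side <- sample(c(-1, 1), 1)
    for (k in 2:n_cl) {
      gap <- 1L + stats::rpois(1L, p$gap_mean_cols - 1)
      if (side > 0) {
        s <- max(iv[, 2]) + gap + 1L
        iv <- rbind(iv, c(s, s + widths[k] - 1L))
      } else {
        e <- min(iv[, 1]) - gap - 1L
        iv <- rbind(iv, c(e - widths[k] + 1L, e))
      }
      side <- -side
    }
  }
  if (any(iv < 1 | iv > grid$n_cols)) clipped <- TRUE
  cols <- sort(unique(unlist(lapply(seq_len(nrow(iv)), function(k)
    seq(max(1L, iv[k, 1]), min(grid$n_cols, iv[k, 2]))))))
  cols <- cols[cols >= 1 & cols <= grid$n_cols]
  # realized plan: maximal runs of the clipped/merged column set
  br <- c(0L, which(diff(cols) > 1L), length(cols))
  plan <- data.frame(
    start_col = cols[br[-length(br)] + 1L],
    end_col   = cols[br[-1L]])
  src <- do.call(rbind, lapply(cols, function(cc) {
    k <- sample.int(length(p$rows_per_col_probs), 1L,
                    prob = p$rows_per_col_probs)
    rows <- sample.int(grid$n_rows, min(k, grid$n_rows), prob = layer_w)
    data.frame(row = sort(rows), col = cc)
  }))
  n_src <- nrow(src)
  src$n_presyn <- sample.int(length(p$n_presyn_probs), n_src, replace = TRUE,
                             prob = p$n_presyn_probs)
  if (p$amp_sdlog > 0) {
    src$mean_amp_pA <- stats::rlnorm(n_src,
                                     log(p$mean_amp_pA) - p$amp_sdlog^2 / 2,
                                     p$amp_sdlog)
  } else {
    src$mean_amp_pA <- rep(p$mean_amp_pA, n_src)
  }
  rownames(src) <- NULL
  structure(list(cell_id = cell_id, sources = src, cluster_plan = plan,
                 n_clusters_drawn = n_cl, target_um = target_um,
                 clipped = clipped),
            class = "ground_truth")
}

#' Ground-truth connectivity map
#'
#' The binary map a perfect detector would recover from a `ground_truth`.
#'
#' @param truth A `ground_truth` from [generate_cohort_truth()].
#' @param grid The matching [grid_spec()].
#' @return A [connectivity_map()].
#' @export
truth_connectivity_map <- function(truth, grid = grid_spec()) {
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (nrow(truth$sources))
    m[cbind(truth$sources$row, truth$sources$col)] <- TRUE
  connectivity_map(m, grid)
}

# normalized difference-of-exponentials EPSC kernel (peak = 1) sampled at fs,
# truncated where the decay tail becomes negligible
epsc_kernel <- function(rise_ms, decay_ms, fs_hz, len_ms = 8 * decay_ms) {
  t <- seq(0, len_ms, by = 1000 / fs_hz)
  k <- exp(-t / decay_ms) - exp(-t / rise_ms)
  tp <- log(decay_ms / rise_ms) * rise_ms * decay_ms / (decay_ms - rise_ms)
  k / (exp(-tp / decay_ms) - exp(-tp / rise_ms))
}

# add `amp` (positive pA, drawn inward/negative) times the kernel at sample
# `at` of trace row `i` of matrix `tr`
add_event <- function(tr, i, at, amp, kern) {
  n <- ncol(tr)
  if (at > n) return(tr)
  j <- at:min(n, at + length(kern) - 1L)
  tr[i, j] <- tr[i, j] - amp * kern[seq_along(j)]
  tr
}

#' Simulate all sweeps of one cell
#'
#' Produces, for every grid site and repetition, a voltage-clamp current
#' trace (pA, inward negative) containing band-limited Gaussian baseline
#' noise, Poisson spontaneous EPSCs, and - at ground-truth source sites - an
#' evoked EPSC whose amplitude is the sum of `n_presyn` per-synapse draws
#' around `mean_amp_pA / n_presyn` and whose peak latency is Gaussian within
#' the detection window. Deterministic for a fixed seed.
#'
#' @param truth A `ground_truth`.
#' @param noise A [noise_model()].
#' @param grid The matching [grid_spec()].
#' @param seed Integer seed.
#' @param sampling_rate_hz Sampling rate of the synthetic traces. The
#'   acquisition rate is a free parameter of the emulated rig and is always
#'   stored with the sweeps.
#' @param trace_len_ms Trace duration; must cover the 100 ms baseline plus
#'   the 50 ms response window.
#' @param stim_onset_ms Uncaging time from trace start (default 100 ms
#'   baseline).
#' @return A `sweep_set`: traces matrix (`n_sites*n_reps` rows, one sample per
#'   column), an index data.frame (site_row, site_col, rep), and acquisition
#'   metadata.
#' @export
simulate_sweepset <- function(truth, noise = noise_model(),
                              grid = grid_spec(), seed = 1L,
                              sampling_rate_hz = 10000,
                              trace_len_ms = 550, stim_onset_ms = 100) {
  stopifnot(inherits(noise, "noise_model"), sampling_rate_hz > 0,
            trace_len_ms >= stim_onset_ms + 50)
  fs <- sampling_rate_hz
  n_samp <- round(trace_len_ms * fs / 1000)
  n_reps <- noise$n_reps
  idx <- data.frame(
    site_row = rep(rep(seq_len(grid$n_rows), grid$n_cols), each = n_reps),
    site_col = rep(rep(seq_len(grid$n_cols), each = grid$n_rows), each = n_reps),
    rep = rep(seq_len(n_reps), grid$n_rows * grid$n_cols))
  n_sweeps <- nrow(idx)
  kern <- epsc_kernel(noise$rise_tau_ms, noise$decay_tau_ms, fs)
  with_seed(derive_seed(seed, paste0("sweeps:", truth$cell_id)), {
    if (noise$baseline_sd_pA > 0) {
      a <- if (noise$noise_corr_ms > 0)
        exp(-1000 / fs / noise$noise_corr_ms) else 0
      tr <- matrix(stats::rnorm(n_sweeps * n_samp,
                                sd = noise$baseline_sd_pA * sqrt(1 - a^2)),
                   n_sweeps, n_samp)
      tr[, 1] <- stats::rnorm(n_sweeps, sd = noise$baseline_sd_pA)
      if (a > 0) for (t in 2:n_samp) tr[, t] <- a * tr[, t - 1] + tr[, t]
    } else {
      tr <- matrix(0, n_sweeps, n_samp)
    }
    if (noise$spont_rate_hz > 0) {
      n_ev <- stats::rpois(n_sweeps, noise$spont_rate_hz * trace_len_ms / 1000)
      for (i in which(n_ev > 0)) {
        at <- sample.int(n_samp, n_ev[i], replace = TRUE)
        amp <- stats::runif(n_ev[i], noise$spont_amp_range_pA[1],
                            noise$spont_amp_range_pA[2])
        for (e in seq_len(n_ev[i])) tr <- add_event(tr, i, at[e], amp[e], kern)
      }
    }
    if (nrow(truth$sources)) {
      onset <- round(stim_onset_ms * fs / 1000) + 1L
      sdlog <- sqrt(log(1 + noise$amp_cv^2))
      for (s in seq_len(nrow(truth$sources))) {
        rows_i <- which(idx$site_row == truth$sources$row[s] &
                          idx$site_col == truth$sources$col[s])
        for (i in rows_i) {
          lat <- stats::rnorm(1, noise$evoked_latency_mean_ms,
                              noise$evoked_latency_sd_ms)
          lat <- min(max(lat, 1), 45)  # peak stays inside the 50 ms window
          m <- truth$sources$mean_amp_pA[s] / truth$sources$n_presyn[s]
          amp <- sum(stats::rlnorm(truth$sources$n_presyn[s],
                                   log(m) - sdlog^2 / 2, sdlog))
          tr <- add_event(tr, i, onset + round(lat * fs / 1000), amp, kern)
        }
      }
    }
    structure(list(cell_id = truth$cell_id, grid = grid, traces = tr,
                   index = idx, n_reps = n_reps, sampling_rate_hz = fs,
                   stim_onset_ms = stim_onset_ms, trace_len_ms = trace_len_ms),
              class = "sweep_set")
  })
}

#' Extract one sweep from a sweep set
#'
#' @param ss A `sweep_set`.
#' @param row,col Site indices (1-based).
#' @param rep Repetition number.
#' @return A `sweep`: site, repetition, samples (pA, inward negative),
#'   sampling_rate_hz, stim_onset_ms.
#' @export
get_sweep <- function(ss, row, col, rep = 1L) {
  i <- which(ss$index$site_row == row & ss$index$site_col == col &
               ss$index$rep == rep)
  if (length(i) != 1L) stop("no sweep for site (", row, ",", col, ") rep ", rep)
  structure(list(site = c(row = row, col = col), repetition = as.integer(rep),
                 samples = ss$traces[i, ], sampling_rate_hz = ss$sampling_rate_hz,
                 stim_onset_ms = ss$stim_onset_ms),
            class = "sweep")
}

#' Simulate a current-clamp excitation profile
#'
#' Emulates the calibration experiment in which glutamate is uncaged on a
#' fine grid (default 8x8, 50 um spacing) over a cortical neuron recorded in
#' current clamp, and action potentials are counted per site. Every site
#' within `excitation_radius_um` of the soma fires 1-2 APs (two with a small
#' per-type probability, giving mean spikes per firing site of ~1.03-1.04);
#' all other sites stay silent. The soma sits on the central grid site.
#'
#' @param cell_type One of `"L2/3"`, `"L5A_RS"`, `"L5B_nonRS"` (sets the
#'   doublet probability), or any label with `p_two` given explicitly.
#' @param grid A [grid_spec()]; default 8x8 at 50 um with no layer scheme.
#' @param excitation_radius_um Maximal soma-site distance at which uncaging
#'   drives the cell to threshold.
#' @param seed Integer seed.
#' @param p_two Probability that a firing site fires a doublet; default by
#'   cell type.
#' @return An `excitation_profile`: ap_counts matrix, soma_site, cell_type,
#'   grid.
#' @export
simulate_excitation_profile <- function(cell_type = "L5A_RS",
                                        grid = excitation_grid(),
                                        excitation_radius_um = 75,
                                        seed = 1L, p_two = NULL) {
  stopifnot(excitation_radius_um >= 0)
  if (is.null(p_two))
    p_two <- switch(cell_type, "L2/3" = 0.04, "L5A_RS" = 0.03,
                    "L5B_nonRS" = 0.04, 0.03)
  soma <- c(ceiling(grid$n_rows / 2), ceiling(grid$n_cols / 2))
  rr <- matrix(seq_len(grid$n_rows), grid$n_rows, grid$n_cols)
  cc <- matrix(rep(seq_len(grid$n_cols), each = grid$n_rows),
               grid$n_rows, grid$n_cols)
  d <- grid$spacing_um * sqrt((rr - soma[1])^2 + (cc - soma[2])^2)
  fires <- d <= excitation_radius_um
  with_seed(derive_seed(seed, paste0("excitation:", cell_type)), {
    ap <- matrix(0L, grid$n_rows, grid$n_cols)
    ap[fires] <- 1L + stats::rbinom(sum(fires), 1L, p_two)
    excitation_profile(ap, soma, grid, cell_type)
  })
}

#' Fine uncaging grid for excitation profiles
#'
#' @param n_rows,n_cols Grid dimensions (8x8 or 24x8 in practice).
#' @param spacing_um Site spacing, default 50 um.
#' @return A [grid_spec()] with a neutral layer scheme.
#' @export
excitation_grid <- function(n_rows = 8L, n_cols = 8L, spacing_um = 50) {
  grid_spec(n_cols = n_cols, n_rows = n_rows, spacing_um = spacing_um,
            l5a_row = 1L, layer_scheme = rep("cortex", n_rows))
}
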