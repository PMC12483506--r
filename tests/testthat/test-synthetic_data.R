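test_that("cohort truths follow the configured pattern distributions", {
  g <- grid_spec()
  co <- generate_cohort_truth(200, g, pattern_params(), seed = 5)
  expect_length(co$truths, 200)
  # every source lies on the grid
  for (t in co$truths) {
    expect_true(all(t$sources$row >= 1 & t$sources$row <= g$n_rows))
    expect_true(all(t$sources$col >= 1 & t$sources$col <= g$n_cols))
    expect_true(all(t$sources$n_presyn >= 1 & t$sources$n_presyn <= 5))
    expect_true(all(t$sources$mean_amp_pA > 0))
  }
  # drawn cluster count matches the configured mean (1.9) within 3 SE;
  # the realized plan can only lose clusters to grid clipping
  drawn <- vapply(co$truths, function(t) t$n_clusters_drawn, numeric(1))
  realized <- vapply(co$truths, function(t) nrow(t$cluster_plan), numeric(1))
  se <- sd(drawn) / sqrt(length(drawn))
  expect_lt(abs(mean(drawn) - 1.9), 3 * se)
  expect_true(all(realized <= drawn))
  # single forced cluster of one site
  pp1 <- pattern_params(n_cluster_probs = 1, width_probs = 1,
                        rows_per_col_probs = 1)
  co1 <- generate_cohort_truth(1, g, pp1, seed = 9)
  expect_identical(nrow(co1$truths[[1]]$sources), 1L)
  expect_identical(nrow(co1$truths[[1]]$cluster_plan), 1L)
})

test_that("sweep simulation is deterministic and seed-driven", {
  g <- small_grid()
  tr <- make_truth(data.frame(row = 2, col = 3), g)
  a <- simulate_sweepset(tr, noise_model(), g, seed = 4,
                         sampling_rate_hz = 1000, trace_len_ms = 160)
  b <- simulate_sweepset(tr, noise_model(), g, seed = 4,
                         sampling_rate_hz = 1000, trace_len_ms = 160)
  c <- simulate_sweepset(tr, noise_model(), g, seed = 5,
                         sampling_rate_hz = 1000, trace_len_ms = 160)
  expect_identical(a$traces, b$traces)
  expect_false(identical(a$traces, c$traces))
  # cohort generation likewise
  x <- generate_cohort_truth(5, grid_spec(), pattern_params(), seed = 1)
  y <- generate_cohort_truth(5, grid_spec(), pattern_params(), seed = 1)
  expect_equal(x, y)
})

test_that("source-free sweeps stay below the detection threshold", {
  # no sources, no spontaneous events: the detector's smoothed window peak
  # must cross 3 baseline SDs in well under 1% of sweeps
  g <- small_grid(8)
  nm <- noise_model(spont_rate_hz = 0)
  exceed <- unlist(lapply(1:4, function(s) {
    ss <- simulate_sweepset(empty_truth(), nm, g, seed = s,
                            sampling_rate_hz = 2500, trace_len_ms = 200)
    peaks <- lspsmap:::sweep_peaks(ss$traces, ss$sampling_rate_hz,
                                   ss$stim_onset_ms, 3, 50, 100, 2, 1e-6)
    peaks > 0
  }))
  expect_lt(mean(exceed), 0.01)
})

test_that("evoked amplitudes average to the configured mean", {
  # >= 500 connected sites through the full simulate -> detect path
  g <- grid_spec()
  pp <- pattern_params()
  nm <- noise_model()
  amps <- c()
  s <- 0
  while (length(amps) < 500) {
    s <- s + 1
    co <- generate_cohort_truth(16, g, pp, seed = 100 + s)
    for (id in co$cells$cell_id) {
      t <- co$truths[[id]]
      if (nrow(t$sources) == 0) next
      ss <- simulate_sweepset(t, nm, g, seed = 100 + s,
                              sampling_rate_hz = 2000, trace_len_ms = 160)
      m <- build_maps(ss)
      hit <- m$input$amplitudes[cbind(t$sources$row, t$sources$col)]
      amps <- c(amps, hit[hit > 0])
    }
    if (s > 9) break
  }
  expect_gte(length(amps), 500)
  expect_lt(abs(mean(amps) - 40) / 40, 0.05)
})

test_that("excitation profiles confine firing to the excitation radius", {
  g <- excitation_grid()
  # radius 0: only the somatic site can fire
  p0 <- simulate_excitation_profile("L5A_RS", g, 0, seed = 1)
  expect_identical(sum(p0$ap_counts >= 1), 1L)
  expect_equal(excitation_radius(p0), 0)
  # radius 75 on the 50 um grid: 3x3 neighborhood (corner distance 70.7)
  p75 <- simulate_excitation_profile("L5A_RS", g, 75, seed = 1)
  expect_identical(p75$sap, 9L)
  expect_lte(excitation_radius(p75), 75)
  # radius 60: 3x3 minus the 70.7 um corners
  p60 <- simulate_excitation_profile("L5A_RS", g, 60, seed = 1)
  expect_identical(p60$sap, 5L)
  idx <- which(p60$ap_counts >= 1, arr.ind = TRUE)
  d <- 50 * sqrt((idx[, 1] - p60$soma_site[1])^2 + (idx[, 2] - p60$soma_site[2])^2)
  expect_true(all(d <= 60))
  # counts are 1 or 2 with mean slightly above 1
  expect_true(all(p75$ap_counts[p75$ap_counts > 0] %in% 1:2))
})

test_that("noise-free pipeline recovers the planned clusters exactly", {
  g <- grid_spec()
  co <- generate_cohort_truth(6, g, pattern_params(), seed = 21)
  for (id in co$cells$cell_id) {
    t <- co$truths[[id]]
    ss <- simulate_sweepset(t, noise_free(), g, seed = 21,
                            sampling_rate_hz = 2000, trace_len_ms = 160)
    m <- build_maps(ss)
    expect_identical(m$connectivity$connected,
                     truth_connectivity_map(t, g)$connected)
    cl <- collapse_and_clusters(m$connectivity)$clusters
    expect_identical(cl$start_col, t$cluster_plan$start_col)
    expect_identical(cl$end_col, t$cluster_plan$end_col)
  }
})
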