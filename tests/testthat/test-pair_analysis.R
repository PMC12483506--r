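cmap_from_sites <- function(sites, grid = grid_spec()) {
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[as.matrix(sites)] <- TRUE
  connectivity_map(m, grid)
}

test_that("identical and disjoint maps give the boundary pair metrics", {
  g <- grid_spec()
  a <- cmap_from_sites(data.frame(row = c(3, 8), col = c(4, 7)), g)
  pm <- pair_metrics(a, a, 100, 300)
  expect_equal(pm$aligned_pct, 100)
  expect_equal(pm$overlap_pct, 100)
  expect_equal(pm$field_overlap_um, 4 * 75)  # full field width, cols 4..7
  expect_equal(pm$spn_distance_um, 200)
  b <- cmap_from_sites(data.frame(row = 5, col = 20), g)
  pm2 <- pair_metrics(a, b)
  expect_equal(pm2$field_overlap_um, 0)
  expect_equal(pm2$aligned_pct, 0)
  expect_equal(pm2$overlap_pct, 0)
})

test_that("alignment counts column matches, overlap exact site coincidence", {
  g <- grid_spec()
  a <- cmap_from_sites(data.frame(row = 10, col = 5), g)
  b <- cmap_from_sites(data.frame(row = c(12, 10), col = c(5, 9)), g)
  pm <- pair_metrics(a, b)
  # A's (10,5) matches column 5 of B; B's (12,5) matches column 5 of A;
  # B's (10,9) has no counterpart -> 2 aligned of 3 pooled sites
  expect_equal(pm$aligned_pct, 100 * 2 / 3)
  expect_equal(pm$overlap_pct, 0)
})

test_that("pair metrics are symmetric and internally consistent", {
  g <- grid_spec()
  set.seed(55)
  for (i in 1:60) {
    a <- random_cmap(g, 0.06); b <- random_cmap(g, 0.06)
    if (sum(a$connected) == 0 || sum(b$connected) == 0) next
    ab <- pair_metrics(a, b, 0, 150)
    ba <- pair_metrics(b, a, 150, 0)
    expect_equal(ab$aligned_pct, ba$aligned_pct)
    expect_equal(ab$overlap_pct, ba$overlap_pct)
    expect_equal(ab$field_overlap_um, ba$field_overlap_um)
    # site coincidence implies column coincidence
    expect_lte(ab$overlap_pct, ab$aligned_pct)
    # overlap cannot exceed either field width
    wa <- field_metrics(collapse_and_clusters(a)$clusters, g)$width_um
    wb <- field_metrics(collapse_and_clusters(b)$clusters, g)$width_um
    expect_lte(ab$field_overlap_um, min(wa, wb))
    if (ab$field_overlap_um == 0) {
      expect_equal(ab$aligned_pct, 0)
      expect_equal(ab$overlap_pct, 0)
    }
  }
})

test_that("pairing requires same slice and non-empty maps", {
  g <- grid_spec()
  a <- cmap_from_sites(data.frame(row = 3, col = 4), g)
  expect_error(pair_metrics(a, a, slice_a = "s1", slice_b = "s2"),
               "same slice")
  empty <- connectivity_map(matrix(FALSE, 16, 29), g)
  expect_error(pair_metrics(a, empty), ">= 1 connected site")
})

test_that("distance-binned summary marks empty bins as missing", {
  g <- grid_spec()
  a <- cmap_from_sites(data.frame(row = 3, col = 4), g)
  b <- cmap_from_sites(data.frame(row = 7, col = 4), g)
  cells <- data.frame(cell_id = c("x", "y"), slice_id = "s1",
                      lateral_pos_um = c(0, 50), depth_um = 90,
                      subtype = c("D1", "D2"), stringsAsFactors = FALSE)
  pairs <- cohort_pairs(list(x = a, y = b), cells)
  expect_identical(nrow(pairs), 1L)
  s <- cohort_pair_summary(pairs, bin_um = 100, max_um = 600)
  expect_equal(s$frac_with_overlap[1], 1)
  expect_equal(s$mean_aligned_pct[1], 100)
  expect_true(all(is.na(s$frac_with_overlap[s$bin_lo_um >= 500])))
})

test_that("planted shared sources make alignment fall with distance", {
  # near pairs share a column; far pairs are disjoint by construction
  g <- grid_spec()
  near_a <- cmap_from_sites(data.frame(row = 4, col = 10), g)
  near_b <- cmap_from_sites(data.frame(row = 9, col = 10), g)
  far_a <- cmap_from_sites(data.frame(row = 4, col = 3), g)
  far_b <- cmap_from_sites(data.frame(row = 9, col = 24), g)
  cells <- data.frame(cell_id = c("a", "b", "c", "d"),
                      slice_id = c("s1", "s1", "s2", "s2"),
                      lateral_pos_um = c(0, 80, 0, 650), depth_um = 90,
                      subtype = "D1", stringsAsFactors = FALSE)
  pairs <- cohort_pairs(list(a = near_a, b = near_b, c = far_a, d = far_b),
                        cells)
  s <- cohort_pair_summary(pairs, bin_um = 100, max_um = 700)
  expect_gt(s$mean_aligned_pct[1], s$mean_aligned_pct[7])
})
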