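test_that("cluster finding matches run-length enumeration on hand cases", {
  g <- grid_spec()
  prof <- rep(FALSE, 29); prof[c(2, 3, 6)] <- TRUE
  m <- matrix(FALSE, 16, 29); m[5, prof] <- TRUE
  cc <- collapse_and_clusters(connectivity_map(m, g))
  expect_identical(cc$profile, prof)
  expect_identical(cc$clusters$start_col, c(2L, 6L))
  expect_identical(cc$clusters$end_col, c(3L, 6L))
  # all columns connected: one cluster of 29 sites
  cc2 <- collapse_and_clusters(connectivity_map(matrix(TRUE, 16, 29), g))
  expect_identical(nrow(cc2$clusters), 1L)
  expect_identical(cc2$clusters$n_sites, 29L)
  # empty map: empty cluster list, caller decides exclusion
  cc0 <- collapse_and_clusters(connectivity_map(matrix(FALSE, 16, 29), g))
  expect_identical(nrow(cc0$clusters), 0L)
})

test_that("cluster finding equals the brute-force oracle on random maps", {
  g <- grid_spec()
  set.seed(1234)
  for (i in 1:300) {
    cm <- random_cmap(g, p = runif(1, 0.01, 0.3))
    cc <- collapse_and_clusters(cm)
    orc <- oracle_clusters(apply(cm$connected, 2, any))
    expect_identical(cc$clusters$start_col, orc$start_col)
    expect_identical(cc$clusters$end_col, orc$end_col)
  }
})

test_that("column count implements sum of ceiling(ConsSites/2)", {
  mk <- function(sizes) {
    if (!length(sizes))
      return(data.frame(start_col = integer(0), end_col = integer(0),
                        n_sites = integer(0)))
    start <- cumsum(c(1, head(sizes, -1) + 1))
    data.frame(start_col = start, end_col = start + sizes - 1,
               n_sites = sizes)
  }
  expect_identical(column_count(mk(1)), 1L)
  expect_identical(column_count(mk(3)), 2L)
  expect_identical(column_count(mk(c(2, 2, 5))), 5L)
  expect_identical(column_count(mk(integer(0))), 0L)
  # monotone under adding a connected column to any cluster
  set.seed(2)
  for (i in 1:50) {
    sizes <- sample(1:5, sample(1:4, 1), replace = TRUE)
    grown <- sizes; j <- sample(length(sizes), 1)
    grown[j] <- grown[j] + 1
    expect_gte(column_count(mk(grown)), column_count(mk(sizes)))
  }
})

test_that("input-field metrics follow the inclusive-extent definitions", {
  g <- grid_spec()
  one <- data.frame(start_col = 4L, end_col = 4L, n_sites = 1L)
  f1 <- field_metrics(one, g)
  expect_equal(f1$width_um, 75)
  expect_equal(f1$gap_fraction_pct, 0)
  expect_length(f1$cluster_spacings_um, 0)
  two <- data.frame(start_col = c(2L, 6L), end_col = c(3L, 6L),
                    n_sites = c(2L, 1L))
  f2 <- field_metrics(two, g)
  expect_equal(f2$cluster_spacings_um, 150)
  expect_equal(f2$width_um, 375)
  expect_equal(f2$gap_fraction_pct, 40)
  far <- data.frame(start_col = c(1L, 13L), end_col = c(1L, 13L),
                    n_sites = c(1L, 1L))
  f3 <- field_metrics(far, g)
  expect_equal(f3$cluster_spacings_um, 825)  # within the 75-900 um range
  expect_error(field_metrics(one[0, ], g), "empty")
})

test_that("cluster and gap widths partition the input field", {
  g <- grid_spec()
  set.seed(77)
  for (i in 1:100) {
    cm <- random_cmap(g, p = runif(1, 0.02, 0.25))
    cl <- collapse_and_clusters(cm)$clusters
    if (nrow(cl) == 0) next
    f <- field_metrics(cl, g)
    expect_equal(sum(cl$width_um) + sum(f$cluster_spacings_um), f$width_um)
    expect_identical(f$gap_fraction_pct == 0, nrow(cl) == 1L)
  }
})

test_that("layer summary conserves the whole-map EPSC sum", {
  g <- grid_spec()
  a <- matrix(0, 16, 29)
  im0 <- input_map(a, g)
  expect_true(all(layer_summary(im0)$epsc_total_pA == 0))
  a[10, 5] <- 40
  im1 <- input_map(a, g)
  ls1 <- layer_summary(im1)
  expect_equal(ls1$epsc_total_pA[ls1$layer == "L5a"], 40)
  expect_equal(sum(ls1$epsc_total_pA[ls1$layer != "L5a"]), 0)
  set.seed(11)
  a2 <- matrix(rexp(16 * 29) * (runif(16 * 29) < 0.2), 16, 29)
  im2 <- input_map(a2, g)
  expect_equal(sum(layer_summary(im2)$epsc_total_pA), sum(a2))
})

test_that("dominant-cluster ratio divides top cluster by the others", {
  g <- grid_spec()
  a <- matrix(0, 16, 29)
  a[3, 2] <- 40; a[9, 6] <- 40
  im <- input_map(a, g)
  cl <- collapse_and_clusters(as_connectivity_map(im))$clusters
  expect_equal(dominant_cluster_ratio(im, cl), 1)
  a[3, 2] <- 100; a[9, 6] <- 50
  im <- input_map(a, g)
  expect_equal(dominant_cluster_ratio(im, cl), 2)
  a[3, 2] <- 60; a[9, 6] <- 30; a[14, 12] <- 10
  im <- input_map(a, g)
  cl3 <- collapse_and_clusters(as_connectivity_map(im))$clusters
  expect_equal(dominant_cluster_ratio(im, cl3), 3)        # 60 / mean(30, 10)
  expect_equal(dominant_cluster_ratio(im, cl3, "sum"), 1.5)  # 60 / (30+10)
  expect_error(dominant_cluster_ratio(im, cl3[1, ]), ">= 2 clusters")
})

test_that("per-cell metrics table reports empty maps as excluded-from-pattern rows", {
  g <- grid_spec()
  row <- cell_metrics(input_map(matrix(0, 16, 29), g),
                      list(cell_id = "c0", subtype = "D1", lateral_pos_um = 500))
  expect_identical(row$n_clusters, 0L)
  expect_true(is.na(row$field_width_um))
  expect_true(is.na(row$connectivity_cm_um))
  a <- matrix(0, 16, 29); a[10, 4] <- 40; a[12, 9] <- 20
  row2 <- cell_metrics(input_map(a, g), list(cell_id = "c1", subtype = "D2",
                                             lateral_pos_um = 500))
  expect_identical(row2$n_clusters, 2L)
  expect_equal(row2$epsc_sum_pA, 60)
  expect_equal(row2$epsc_L5a_pA, 40)
  expect_equal(row2$epsc_L5b_pA, 20)
})
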