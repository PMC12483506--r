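test_that("centers of mass match their definitions on hand cases", {
  g <- grid_spec()
  m <- matrix(FALSE, 16, 29); m[4, 5] <- TRUE  # single column at 300 um
  expect_equal(connectivity_cm(connectivity_map(m, g)), 300)
  m[5, 5] <- FALSE
  m2 <- matrix(FALSE, 16, 29); m2[c(2, 9), 1] <- TRUE; m2[4, 5] <- TRUE
  expect_equal(connectivity_cm(connectivity_map(m2, g)), 100)  # (2*0 + 1*300)/3
  # with equal amplitudes AND equal per-column counts the two CMs coincide;
  # unequal counts re-weight the connectivity CM but not the synaptic CM
  a <- matrix(0, 16, 29); a[3, 1] <- 10; a[4, 5] <- 10
  expect_equal(synaptic_cm(input_map(a, g)),
               connectivity_cm(connectivity_map(a > 0, g)))
  a[7, 1] <- 10
  expect_equal(synaptic_cm(input_map(a, g)), 150)      # column means 10, 10
  expect_equal(connectivity_cm(connectivity_map(a > 0, g)), 100)  # counts 2, 1
  a2 <- matrix(0, 16, 29); a2[3, 1] <- 10; a2[4, 17] <- 30  # cols at 0 and 1200
  expect_equal(synaptic_cm(input_map(a2, g)), 900)
  expect_error(connectivity_cm(connectivity_map(matrix(FALSE, 16, 29), g)),
               "undefined")
})

test_that("centers of mass equal direct per-site evaluation on random maps", {
  g <- grid_spec(refhor_col_offset_um = -700)
  set.seed(42)
  for (i in 1:200) {
    cm <- random_cmap(g, p = runif(1, 0.02, 0.3))
    if (sum(cm$connected) == 0) next
    expect_equal(connectivity_cm(cm), oracle_connectivity_cm(cm))
    a <- matrix(0, g$n_rows, g$n_cols)
    a[cm$connected] <- runif(sum(cm$connected), 5, 80)
    im <- input_map(a, g)
    expect_equal(synaptic_cm(im), oracle_synaptic_cm(im))
    # CM lies within the field extent
    cols <- range(which(apply(cm$connected, 2, any)))
    expect_gte(connectivity_cm(cm), site_lateral_um(cols[1], g))
    expect_lte(connectivity_cm(cm), site_lateral_um(cols[2], g))
  }
})

test_that("centers of mass are translation-equivariant in the grid offset", {
  set.seed(3)
  g0 <- grid_spec(refhor_col_offset_um = 0)
  g1 <- grid_spec(refhor_col_offset_um = 430)
  m <- matrix(runif(16 * 29) < 0.1, 16, 29)
  a <- matrix(0, 16, 29); a[m] <- runif(sum(m), 5, 60)
  expect_equal(connectivity_cm(connectivity_map(m, g1)),
               connectivity_cm(connectivity_map(m, g0)) + 430)
  expect_equal(synaptic_cm(input_map(a, g1)),
               synaptic_cm(input_map(a, g0)) + 430)
})

test_that("cohort topography summary recovers planted correlation structure", {
  # perfectly linear cohort
  pos <- seq(100, 1600, length.out = 20)
  s <- topography_summary(pos, 0.9 * pos + 50)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$spearman_r, 1)
  expect_equal(s$slope, 0.9, tolerance = 1e-10)
  expect_equal(max(abs(s$residuals_um)), 0, tolerance = 1e-9)
  # shuffled positions: |R| within the permutation null band
  set.seed(8)
  cm <- 1 * pos + rnorm(20, 0, 100)
  r_obs <- abs(topography_summary(sample(pos), cm)$pearson_r)
  null_r <- replicate(1000, abs(cor(sample(pos), cm)))
  expect_lt(r_obs, quantile(null_r, 0.999))
  expect_error(topography_summary(pos[1:2], cm[1:2]), ">= 3 cells")
})

test_that("projection-zone width reports per-bin max pairwise SPN distance", {
  g <- grid_spec()
  m1 <- matrix(FALSE, 16, 29); m1[5, 3] <- TRUE   # col 3 -> 150 um -> bin [150,300)
  m2 <- matrix(FALSE, 16, 29); m2[9, 3] <- TRUE
  m3 <- matrix(FALSE, 16, 29); m3[2, 20] <- TRUE  # isolated bin, single cell
  pz <- projection_zone_width(list(connectivity_map(m1, g),
                                   connectivity_map(m2, g),
                                   connectivity_map(m3, g)),
                              c(0, 600, 300), bin_um = 150)
  b1 <- pz[pz$bin_lo_um == 150, ]
  expect_identical(b1$n_cells, 2L)
  expect_equal(b1$max_spn_distance_um, 600)
  b2 <- pz[pz$bin_lo_um == floor(site_lateral_um(20, g) / 150) * 150, ]
  expect_identical(b2$n_cells, 1L)
  expect_true(is.na(b2$max_spn_distance_um))
})
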