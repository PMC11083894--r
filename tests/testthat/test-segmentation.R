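test_that("median filter removes impulses, preserves constants, matches oracle", {
  a <- array(0, c(3, 3, 3)); a[2, 2, 2] <- 100
  expect_true(all(median_filter_3d(voxel_grid(a, 1, 1, 1), 1)$data == 0))

  g <- voxel_grid(array(7, c(4, 5, 6)), 1, 1, 1)
  expect_equal(median_filter_3d(g, 2)$data, g$data)

  set.seed(101)
  r <- rand_grid(c(5, 5, 5))
  expect_equal(median_filter_3d(r, 1)$data, oracle_median3d(r$data, c(1, 1, 1)))

  expect_error(median_filter_3d(r, -1), "non-negative")
  expect_identical(median_filter_3d(r, 0)$data, r$data)
})

test_that("white top-hat removes broad structure, keeps thin features", {
  flat <- voxel_grid(array(50, c(9, 9, 9)), 1, 1, 1)
  expect_true(all(tophat_filter_3d(flat, 2)$data == 0))

  a <- array(0, c(9, 9, 9)); a[5, 5, ] <- 100
  th <- tophat_filter_3d(voxel_grid(a, 1, 1, 1), 3)
  expect_equal(th$data[5, 5, 5], 100)

  # plateau + thin line: only the line's excess remains
  a <- array(40, c(15, 15, 15)); a[8, 8, ] <- 100
  g <- voxel_grid(a, 1, 1, 1)
  th <- tophat_filter_3d(g, 3)
  se <- mitonet3d:::ellipsoid_se(3, 1, 1, 1)
  expect_equal(th$data, oracle_tophat(a, se))
  expect_equal(th$data[8, 8, 8], 60)
  expect_true(all(th$data >= 0))

  expect_error(tophat_filter_3d(voxel_grid(array(1, c(3, 3, 3)), 1, 1, 1), 5),
               "larger than the stack")
})

test_that("top-hat structuring element is anisotropy-corrected", {
  se <- mitonet3d:::ellipsoid_se(1.0, 0.35, 0.325, 0.325)
  # physical radius 1 um: up to 2 voxels along z (0.35), 3 along y/x (0.325)
  expect_equal(max(abs(se[, 1])), 2)
  expect_equal(max(abs(se[, 2])), 3)
  expect_true(all((se[, 1] * 0.35)^2 + (se[, 2] * 0.325)^2 +
                    (se[, 3] * 0.325)^2 <= 1 + 1e-6))
})

test_that("constant threshold is inclusive with clean limits", {
  g <- voxel_grid(array(c(0, 5, 10), c(3, 1, 1)), 1, 1, 1)
  m <- threshold_constant(g, 5)
  expect_equal(as.vector(m$data), c(FALSE, TRUE, TRUE))
  expect_true(all(threshold_constant(g, 0)$data))
  expect_false(any(threshold_constant(g, 11)$data))
  expect_error(threshold_constant(g, -1), "non-negative")
})

test_that("labelling respects connectivity and matches flood fill on random masks", {
  # corner-touching voxels: one object under 26, two under 6
  a <- array(FALSE, c(3, 3, 3)); a[1, 1, 1] <- TRUE; a[2, 2, 2] <- TRUE
  m <- make_mask(a)
  expect_equal(label_objects(m, 26)$n_labels, 1L)
  expect_equal(label_objects(m, 18)$n_labels, 2L)  # corners need 26
  expect_equal(label_objects(m, 6)$n_labels, 2L)
  # edge-sharing voxels are 18-connected but not 6-connected
  b <- array(FALSE, c(3, 3, 3)); b[1, 1, 1] <- TRUE; b[2, 2, 1] <- TRUE
  mb <- make_mask(b)
  expect_equal(label_objects(mb, 18)$n_labels, 1L)
  expect_equal(label_objects(mb, 6)$n_labels, 2L)

  # two clusters separated by >= 2 background voxels
  a <- array(FALSE, c(8, 8, 8))
  a[1:2, 1:2, 1:2] <- TRUE; a[6:8, 6:8, 6:8] <- TRUE
  expect_equal(label_objects(make_mask(a), 26)$n_labels, 2L)

  set.seed(77)
  a <- array(runif(1000) < 0.2, c(10, 10, 10))
  for (conn in c(6L, 18L, 26L)) {
    lab <- label_objects(make_mask(a), conn)
    expect_true(same_partition(lab$data, oracle_flood_label(a, conn)))
    if (lab$n_labels > 0) {
      expect_equal(sort(unique(as.vector(lab$data[lab$data > 0]))),
                   seq_len(lab$n_labels))
    }
  }
})

test_that("label order is deterministic in (z, y, x) scan order", {
  set.seed(5)
  a <- array(runif(512) < 0.25, c(8, 8, 8))
  m <- make_mask(a)
  l1 <- label_objects(m, 26); l2 <- label_objects(m, 26)
  expect_identical(l1$data, l2$data)
  # first voxel of label k in scan order precedes that of label k+1
  firsts <- vapply(seq_len(l1$n_labels), function(k) {
    idx <- which(aperm(l1$data, c(3, 2, 1)) == k)[1]  # (z,y,x) lexicographic
    idx
  }, numeric(1))
  expect_true(all(diff(firsts) > 0))
})

test_that("size classification uses closed middle interval", {
  expect_equal(classify_size(c(1.9, 2, 5, 10, 10.5)),
               c("small", "medium", "medium", "medium", "network"))
  expect_error(classify_size(-1), "non-negative")
  # exhaustive, disjoint partition of sampled volumes
  v <- c(0, 10^seq(-3, 3, length.out = 200))
  cls <- classify_size(v)
  expect_true(all(cls %in% c("small", "medium", "network")))
  expect_equal(cls == "small", v < 2)
  expect_equal(cls == "network", v > 10)
})

test_that("measure_objects computes exact volumes, intensities and classes", {
  # one object of 100 voxels at the 20x geometry
  a <- array(FALSE, c(10, 10, 10)); a[1:4, 1:5, 1:5] <- TRUE
  stopifnot(sum(a) == 100)
  m <- make_mask(a, 0.35, 0.325, 0.325)
  lab <- label_objects(m, 26)
  g <- voxel_grid(array(10, c(10, 10, 10)), 0.35, 0.325, 0.325)
  rec <- measure_objects(lab, g)
  expect_equal(rec$volume_um3, 100 * 0.35 * 0.325 * 0.325)
  expect_equal(rec$volume_um3, 3.696875)
  expect_equal(rec$size_class, "medium")
  expect_equal(rec$mean_intensity, 10)
  expect_equal(rec$total_intensity, 10 * rec$voxel_count)

  expect_error(measure_objects(lab, voxel_grid(array(1, c(9, 10, 10)), 1, 1, 1)),
               "mismatch")
})

test_that("object measurements are invariant to label renumbering", {
  set.seed(42)
  a <- array(runif(1728) < 0.15, c(12, 12, 12))
  m <- make_mask(a)
  lab <- label_objects(m, 26)
  skip_if(lab$n_labels < 2)
  g <- rand_grid(c(12, 12, 12))
  rec1 <- measure_objects(lab, g)
  perm <- sample(lab$n_labels)
  lab2 <- lab
  lab2$data[lab$data > 0] <- perm[lab$data[lab$data > 0]]
  rec2 <- measure_objects(lab2, g)
  o <- order(rec2$voxel_count, rec2$total_intensity)
  o1 <- order(rec1$voxel_count, rec1$total_intensity)
  expect_equal(rec1$total_intensity[o1], rec2$total_intensity[o])
  expect_equal(rec1$volume_um3[o1], rec2$volume_um3[o])
})

test_that("segment_mito conserves voxels, is deterministic, measures raw intensities", {
  sim <- simulate_cell(sim_cell_params(shape = c(16, 64, 64),
                                       cell_radii_um = c(2.2, 8.5, 8.5),
                                       nucleus_radii_um = c(1, 2.5, 2.5),
                                       n_mito = 6, mito_radius_um = 0.8,
                                       psf_sigma_um = 0.25, seed = 3))
  cfg <- analysis_config(threshold_mito = 40)
  seg1 <- segment_mito(sim$channels$mito, cfg)
  seg2 <- segment_mito(sim$channels$mito, cfg)
  expect_identical(seg1$labels$data, seg2$labels$data)

  # conservation: object voxel counts sum to mask voxel count
  filt <- tophat_filter_3d(median_filter_3d(sim$channels$mito, 1), 1.0)
  mask <- threshold_constant(filt, 40)
  expect_equal(sum(seg1$objects$voxel_count), sum(mask$data))

  # intensities come from the raw stack, not the filtered one
  lab <- seg1$labels
  raw_mean <- mean(sim$channels$mito$data[lab$data == 1])
  expect_equal(seg1$objects$mean_intensity[1], raw_mean)

  # all-zero stack yields an empty record list
  z <- voxel_grid(array(0, c(8, 8, 8)), 1, 1, 1)
  seg0 <- segment_mito(z, analysis_config(threshold_mito = 1,
                                          tophat_radius_um = 2))
  expect_equal(nrow(seg0$objects), 0L)
  expect_equal(seg0$labels$n_labels, 0L)
})

test_that("suggested threshold tracks background statistics", {
  set.seed(8)
  a <- array(rnorm(4096, 50, 5), c(16, 16, 16))
  g <- voxel_grid(pmax(a, 0), 1, 1, 1)
  bg <- array(TRUE, c(16, 16, 16))
  thr <- suggest_threshold(g, bg, k = 3)
  expect_equal(thr, mean(g$data) + 3 * sd(g$data))
})
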