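small_params <- function(n_mito = 6, ...) {
  sim_cell_params(shape = c(16, 64, 64), cell_radii_um = c(2.2, 8.5, 8.5),
                  nucleus_radii_um = c(1, 2.5, 2.5), n_mito = n_mito,
                  mito_radius_um = 0.8, psf_sigma_um = 0.25, ...)
}

test_that("identical seeds reproduce stacks bit for bit", {
  s1 <- simulate_cell(small_params(seed = 7))
  s2 <- simulate_cell(small_params(seed = 7))
  expect_identical(s1$channels$mito$data, s2$channels$mito$data)
  expect_identical(s1$channels$cell$data, s2$channels$cell$data)
  expect_identical(s1$truth$label_map$data, s2$truth$label_map$data)
  s3 <- simulate_cell(small_params(seed = 8))
  expect_false(identical(s1$channels$mito$data, s3$channels$mito$data))
})

test_that("ground truth is internally consistent", {
  sim <- simulate_cell(small_params(seed = 2))
  gt <- sim$truth
  vv <- voxel_volume(sim$channels$mito)
  # volumes follow exactly from label-map voxel counts
  counts <- tabulate(gt$label_map$data[gt$label_map$data > 0],
                     nbins = gt$label_map$n_labels)
  expect_equal(gt$objects$voxel_count, counts)
  expect_equal(gt$objects$volume_um3, counts * vv)
  # per-object intensity sums over the clean field match an exhaustive scan
  for (j in gt$objects$object_id) {
    expect_equal(gt$objects$mean_intensity[j],
                 mean(gt$clean_mito$data[gt$label_map$data == j]))
  }
})

test_that("zero planted objects segment to nothing at a suitable threshold", {
  sim <- simulate_cell(small_params(n_mito = 0, seed = 5))
  seg <- segment_mito(sim$channels$mito, analysis_config(threshold_mito = 60))
  expect_equal(nrow(seg$objects), 0L)
})

test_that("membrane-potential proxy scales intensities but not volumes", {
  lo <- simulate_cell(small_params(seed = 9, potential_mean = 150,
                                   potential_sd = 0))
  hi <- simulate_cell(small_params(seed = 9, potential_mean = 300,
                                   potential_sd = 0))
  cfg_lo <- analysis_config(threshold_mito = 75)
  cfg_hi <- analysis_config(threshold_mito = 150)  # threshold scaled with signal
  seg_lo <- segment_mito(lo$channels$mito, cfg_lo)
  seg_hi <- segment_mito(hi$channels$mito, cfg_hi)
  expect_gt(sum(seg_hi$objects$total_intensity),
            sum(seg_lo$objects$total_intensity))
  expect_equal(sum(seg_hi$objects$voxel_count),
               sum(seg_lo$objects$voxel_count), tolerance = 0.05)
})

test_that("population draws object counts from the preset distribution", {
  preset <- population_preset("mesoangioblast")
  # reduced rendering for speed; the count distribution is what is under test
  preset$template <- small_params()
  pop <- simulate_population(preset, n_cells = 30, seed = 17)
  expect_length(pop, 30)
  set.seed(17)
  drawn <- pmax(1L, round(rnorm(30, 30, 12)))
  planted <- vapply(pop, function(x) x$truth$label_map$n_labels, integer(1))
  # planted (pre-merge) counts equal the drawn counts up to merging of
  # touching objects, so recovered labels never exceed the draw
  expect_true(all(planted <= drawn))
  expect_lt(abs(mean(drawn) - 30), 2 * 12 / sqrt(30))
})

test_that("myotube and mesoangioblast presets plant a ~12-fold volume ratio", {
  meso <- simulate_population("mesoangioblast", 2, variability = 0, seed = 11)
  myo <- simulate_population("myotube", 2, variability = 0, seed = 21)
  tv <- function(x) sum(x$truth$objects$volume_um3)
  planted_ratio <- mean(vapply(myo, tv, numeric(1))) /
    mean(vapply(meso, tv, numeric(1)))
  expect_gt(planted_ratio, 12 * 0.6)
  expect_lt(planted_ratio, 12 * 1.4)

  # the pipeline recovers the planted ratio within 20%
  cfg <- validation_config()
  rv <- function(x) sum(segment_mito(x$channels$mito, cfg)$objects$volume_um3)
  rec_ratio <- mean(vapply(myo, rv, numeric(1))) /
    mean(vapply(meso, rv, numeric(1)))
  expect_lt(abs(rec_ratio - planted_ratio) / planted_ratio, 0.2)
})

test_that("simulated series decay follows the planted closed form", {
  cellp <- small_params(seed = 31, n_mito = 8, background_level = 10)
  sp <- sim_series_params(cell = cellp, decay_slope = -0.3,
                          between_roi_sd = 0, n_rois = 3)
  ss <- simulate_series(sp)
  ser <- suppressWarnings(build_series(ss$stacks, ss$rois))
  # ROI means scale with the decay factor; relative ~ planted curve
  expected <- 1 + sp$decay_slope * ss$truth$t
  by_acq <- as.numeric(tapply(ser$relative, ser$acquisition, mean))
  expect_equal(by_acq, expected, tolerance = 0.05)

  # zero decay, zero dispersion: flat within noise, fitted slope ~ 0
  sp0 <- sim_series_params(cell = cellp, decay_slope = 0, between_roi_sd = 0,
                           n_rois = 3)
  ss0 <- simulate_series(sp0)
  ser0 <- suppressWarnings(build_series(ss0$stacks, ss0$rois))
  f0 <- fit_trend(ser0)
  expect_lt(abs(f0$beta), 0.05)

  expect_error(sim_series_params(cell = cellp, decay_slope = -1.2),
               "exceed -1")
})

test_that("image-level decay is recovered by the trend fit", {
  cellp <- small_params(seed = 41, n_mito = 8, background_level = 10)
  sp <- sim_series_params(cell = cellp, decay_slope = -0.14,
                          between_roi_sd = 0.01, n_rois = 4)
  ss <- simulate_series(sp)
  ser <- suppressWarnings(build_series(ss$stacks, ss$rois))
  f <- fit_trend(ser)
  expect_lt(abs(f$beta - (-0.14)), 0.04)
})

test_that("fragmentation shifts size-class mass away from networks", {
  cellp <- sim_cell_params(shape = c(16, 72, 72), cell_radii_um = c(2.2, 10, 10),
                           nucleus_radii_um = c(1, 2.5, 2.5), n_mito = 8,
                           mito_radius_um = 0.8, mito_length_um = c(4, 6),
                           psf_sigma_um = 0.25, seed = 51)
  sp <- sim_series_params(cell = cellp, decay_slope = 0, n_rois = 2,
                          morphology_change = TRUE)
  ss <- simulate_series(sp)
  cfg <- analysis_config(threshold_mito = 40)
  p1 <- size_class_percentages(segment_mito(ss$stacks[[1]], cfg)$objects)
  p10 <- size_class_percentages(segment_mito(ss$stacks[[10]], cfg)$objects)
  net1 <- p1$pct[p1$size_class == "network"]
  net10 <- p10$pct[p10$size_class == "network"]
  expect_lt(net10, net1)
})

test_that("vacuoles are carved and recovered by hole filling", {
  sim <- simulate_cell(small_params(seed = 61, n_vacuoles = 2))
  cellmask <- threshold_constant(sim$channels$cell, 60)
  filled <- fill_holes_3d(cellmask)
  expect_gt(sum(filled$data), sum(cellmask$data))
})
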