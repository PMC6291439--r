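test_that("phantom assigns compartment parameters and masks consistently", {
  gt <- make_phantom(small_spec())
  m <- gt$masks
  expect_true(all(gt$f_map[m$cortex] == 190))
  expect_true(all(gt$f_map[m$medulla] == 170))
  expect_true(all(gt$f_map[!m$whole] == 0))
  expect_true(all(gt$t1_map[m$cortex] == 790))
  expect_true(all(gt$bat_map[m$medulla] == 185))
  # cortex and medulla partition the whole kidney
  expect_false(any(m$cortex & m$medulla))
  expect_equal(m$cortex | m$medulla, m$whole)
  expect_gt(sum(m$medulla), 0)
})

test_that("cortex shell equals whole minus in-plane erosion of given depth", {
  spec <- phantom_spec(grid_shape = c(8, 20, 40), cortex_depth = 3)
  gt <- make_phantom(spec)
  depth_map <- cityblock_interior_depth(gt$masks$whole)
  expect_equal(gt$masks$medulla, depth_map > 3)
  expect_equal(gt$masks$cortex, gt$masks$whole & depth_map <= 3)
})

test_that("explicit zero-size medulla semi-axes give an all-cortex kidney", {
  spec <- tiny_spec()
  spec$kidneys <- lapply(spec$kidneys, function(k) {
    k$medulla_semi_axes <- c(0, 0, 0); k
  })
  gt <- make_phantom(spec)
  expect_equal(sum(gt$masks$medulla), 0)
  expect_equal(gt$masks$cortex, gt$masks$whole)
})

test_that("overlapping kidney ellipsoids are rejected", {
  spec <- tiny_spec()
  spec$kidneys[[2]]$center <- spec$kidneys[[1]]$center
  expect_error(make_phantom(spec), "overlap")
})

test_that("phantom construction is deterministic", {
  expect_identical(make_phantom(small_spec()), make_phantom(small_spec()))
})

test_that("noiseless acquisition reproduces the forward model exactly", {
  p <- asl_protocol()
  spec <- tiny_spec(noise_sd = 0, n_averages = 2)
  gt <- make_phantom(spec)
  acq <- simulate_acquisition(gt, spec, p)
  dm_true <- forward_model_volume(gt, p)
  dm_mean <- apply(acq$controls - acq$labels, 1:4, mean)
  expect_equal(dm_mean, dm_true, tolerance = 1e-14)
  # before the bolus arrives the difference signal is zero
  v <- which(gt$masks$cortex)[1]
  pre_bat <- which(p$ti < gt$bat_map[v])
  ijk <- arrayInd(v, dim(gt$f_map))
  expect_true(all(dm_true[ijk[1], ijk[2], ijk[3], pre_bat] == 0))
  # M0 volume is the noise-free m0 map
  expect_equal(acq$m0, gt$m0_map)
})

test_that("acquisition noise is reproducible, independent and correctly scaled", {
  p <- asl_protocol()
  spec <- phantom_spec(grid_shape = c(6, 12, 24), noise_sd = 0.02,
                       n_averages = 2, seed = 9L)
  gt <- make_phantom(spec)
  a1 <- simulate_acquisition(gt, spec, p)
  a2 <- simulate_acquisition(gt, spec, p)
  expect_identical(a1, a2)
  a3 <- simulate_acquisition(gt, spec, p, seed = 10L)
  expect_false(identical(a1$controls, a3$controls))
  # noise realizations are mutually independent across control/label,
  # TIs and averages
  nc <- a1$controls - rep(gt$m0_map, times = length(p$ti) * 2)
  dim(nc) <- c(prod(spec$grid_shape), length(p$ti), 2)
  expect_lt(abs(cor(nc[, 1, 1], nc[, 2, 1])), 0.08)
  expect_lt(abs(cor(nc[, 1, 1], nc[, 1, 2])), 0.08)
  expect_equal(sd(nc[, 3, 1]), 0.02, tolerance = 0.1)
  # control and label noise independent at the same TI/average
  lab_noise <- a1$labels[, , , 3, 1] - (gt$m0_map - forward_model_volume(gt, p)[, , , 3])
  expect_lt(abs(cor(as.vector(nc[, 3, 1]), as.vector(lab_noise))), 0.08)
})

test_that("repeatability scenario perturbs truth multiplicatively per scan", {
  spec <- tiny_spec()
  sc0 <- make_study_scenario(spec, "repeatability", between_scan_sd = 0,
                             simulate = FALSE)
  expect_length(sc0$timepoints, 2)
  expect_identical(sc0$timepoints[[1]]$truth$f_map,
                   sc0$timepoints[[2]]$truth$f_map)
  sc <- make_study_scenario(spec, "repeatability", between_scan_sd = 0.05,
                            simulate = FALSE)
  f1 <- sc$timepoints[[1]]$truth$f_map
  f2 <- sc$timepoints[[2]]$truth$f_map
  m <- sc$timepoints[[1]]$truth$masks$cortex
  expect_false(isTRUE(all.equal(f1[m][1], f2[m][1])))
  # BAT and T1 are untouched
  expect_identical(sc$timepoints[[1]]$truth$t1_map,
                   sc$timepoints[[2]]$truth$t1_map)
})

test_that("challenge scenario holds perfusion flat while blood pressure dips", {
  spec <- tiny_spec()
  sc <- make_study_scenario(spec, "gtn_challenge", simulate = FALSE)
  expect_length(sc$timepoints, 6)
  for (k in 2:6) {
    expect_identical(sc$timepoints[[1]]$truth$f_map,
                     sc$timepoints[[k]]$truth$f_map)
  }
  expect_equal(sc$bp$systolic, c(120, 120, 105, 110, 115, 120))
  expect_equal(min(sc$bp$systolic), sc$bp$systolic[3])
  expect_equal(sc$bp$systolic[1], sc$bp$systolic[6])
  expect_error(make_study_scenario(spec, "unknown"), "arg")
})

test_that("between-scan variability has the designed log-ratio spread", {
  # Monte-Carlo check of the generator: the scan-to-scan log-ratio of
  # cortical perfusion has sd ~ between_scan_sd * sqrt(2)
  spec <- phantom_spec(grid_shape = c(2, 6, 12), seed = 3L)
  lr <- vapply(1:1000, function(i) {
    sc <- make_study_scenario(spec, "repeatability", between_scan_sd = 0.05,
                              simulate = FALSE, seed = i)
    m <- sc$timepoints[[1]]$truth$masks$cortex
    log(sc$timepoints[[1]]$truth$f_map[m][1] /
          sc$timepoints[[2]]$truth$f_map[m][1])
  }, numeric(1))
  expect_equal(sd(lr), 0.05 * sqrt(2), tolerance = 0.08)
})

test_that("generated volumes share geometry", {
  p <- asl_protocol()
  spec <- tiny_spec()
  gt <- make_phantom(spec)
  acq <- simulate_acquisition(gt, spec, p)
  expect_equal(dim(acq$controls)[1:3], spec$grid_shape)
  expect_equal(dim(acq$labels), dim(acq$controls))
  expect_equal(dim(acq$m0), spec$grid_shape)
  expect_equal(acq$voxel_size_mm, spec$voxel_size_mm)
  expect_equal(dim(acq$controls)[4], length(p$ti))
  expect_equal(dim(acq$controls)[5], spec$n_averages)
})

test_that("repeatability cohort reflects between- and within-subject variation", {
  d0 <- simulate_repeatability_cohort(n_subjects = 8, between_scan_sd = 0,
                                      seed = 2L)
  expect_equal(d0$scan1, d0$scan2)
  expect_equal(ma_regression(d0$scan1, d0$scan2)$r_squared, 1)
  d <- simulate_repeatability_cohort(n_subjects = 200, between_scan_sd = 0.05,
                                     seed = 2L)
  # expected correlation ~ var_between / (var_between + var_within)
  expected_r2 <- (30^2 / (30^2 + (0.05 * 190)^2))^2
  expect_equal(ma_regression(d$scan1, d$scan2)$r_squared, expected_r2,
               tolerance = 0.1)
  expect_identical(d, simulate_repeatability_cohort(n_subjects = 200,
                                                    between_scan_sd = 0.05,
                                                    seed = 2L))
})
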