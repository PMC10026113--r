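test_that("cell scenes are empty, reproducible, and mask-consistent", {
  empty <- make_cell_scene(0, size = 128, seed = 1)
  expect_true(all(empty$truth_mask == 0))
  a <- make_cell_scene(20, size = 960, seed = 1)
  b <- make_cell_scene(20, size = 960, seed = 1)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_equal(max(a$truth_mask), 20)
  expect_equal(nrow(a$truth_params), 20)
  # every truth label is a connected region and its area matches the mask
  for (i in c(1, 10, 20)) {
    prof <- compute_shape_profile(a$truth_mask, i)
    expect_equal(prof$area_shape, sum(a$truth_mask == i))
  }
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("truth masks have the requested elongation", {
  sc <- make_cell_scene(5, size = 320, elongation = 3, seed = 2)
  prof <- profile_objects(sc$truth_mask, neighbors = FALSE)
  ratio <- prof$major_axis_length / prof$minor_axis_length
  expect_true(all(abs(ratio - 3) / 3 < 0.1))
})

test_that("infeasible density fails with the achieved count named", {
  expect_error(make_cell_scene(500, size = 64, seed = 1),
               "could only place")
})

test_that("time-lapse preserves identity and walks at the requested step", {
  sc <- make_cell_scene(3, size = 256, seed = 5)
  frozen <- make_timelapse(sc, n_frames = 4, step_px = 0, seed = 6)
  for (f in 2:4)
    expect_identical(frozen$frames[[f]]$truth_mask, sc$truth_mask)
  tl <- make_timelapse(sc, n_frames = 24, step_px = 5, seed = 7)
  expect_equal(length(tl$frames), 24)
  paths <- tl$truth_tracks |>
    dplyr::group_by(label) |>
    dplyr::arrange(frame, .by_group = TRUE) |>
    dplyr::summarise(path = sum(sqrt(diff(row)^2 + diff(col)^2)))
  expect_true(all(abs(paths$path - 23 * 5) / (23 * 5) < 0.15))
  # identity persists across frames
  expect_true(all(table(tl$truth_tracks$label) == 24))
})

test_that("fluorescence truth fusion index follows the requested fraction", {
  z <- make_fluorescence_scene(10, 0, seed = 1)
  expect_equal(z$truth_fusion_index, 0)
  o <- make_fluorescence_scene(10, 1, seed = 1)
  expect_equal(o$truth_fusion_index, 1)
  h <- make_fluorescence_scene(10, 0.2, seed = 2)
  expect_equal(h$truth_fusion_index, 0.2)
  expect_error(make_fluorescence_scene(10, 1.2), "fusion_fraction")
  # nuclei centroids lie inside the image; myotube nuclei lie on green
  fs <- make_fluorescence_scene(24, 0.5, seed = 3, size = 768)
  tn <- fs$truth_nuclei
  expect_true(all(tn$row >= 1 & tn$row <= 768 & tn$col >= 1 & tn$col <= 768))
  in_myo <- !is.na(tn$myotube)
  expect_true(all(fs$green[cbind(round(tn$row[in_myo]),
                                 round(tn$col[in_myo]))] > 0.3))
})

test_that("beta-gal scenes render the exact positive fraction in a blue hue", {
  none <- make_bgal_scene(10, 0, seed = 1)
  hsv <- grDevices::rgb2hsv(r = as.numeric(none$rgb[, , 1]),
                            g = as.numeric(none$rgb[, , 2]),
                            b = as.numeric(none$rgb[, , 3]))
  expect_true(all(hsv[2, ] < 0.15))   # nothing saturated blue
  some <- make_bgal_scene(10, 0.2, seed = 2)
  expect_equal(some$truth_fraction, 0.2)
  expect_equal(sum(some$truth$positive), 2)
  expect_identical(make_bgal_scene(8, 0.5, seed = 9)$rgb,
                   make_bgal_scene(8, 0.5, seed = 9)$rgb)
  expect_error(make_bgal_scene(10, -0.1), "positive_fraction")
})

test_that("OD plates follow the 1:3 dilution design with duplicate wells", {
  pl <- make_od_plate(c(111.111), noise_sd = 0, seed = 1)
  expect_equal(nrow(pl$standards), 7)
  expect_equal(pl$standards$conc[7], 1000 / 3^6)
  expect_equal(pl$standards$conc[7], 1.37, tolerance = 0.003)
  # a sample at a standard's concentration reads the standard's OD
  s3 <- pl$standards$conc[3]
  pl2 <- make_od_plate(s3, noise_sd = 0, seed = 1)
  expect_equal(unique(pl2$samples$od), pl$standards$od[3])
  expect_equal(table(pl2$samples$sample)[[1]], 2)
  expect_error(make_od_plate(c(-5)), "non-negative")
})

test_that("synthetic cohorts carry the built-in age slope", {
  flat <- make_cohort(cohort_spec(n_donors = 10, fi_age_slope = 0,
                                  noise_sd = 0, seed = 1))
  expect_true(all(abs(flat$FusionIndex - flat$FusionIndex[1]) < 1e-12))
  neg <- make_cohort(cohort_spec(n_donors = 10, fi_intercept = 0.9,
                                 fi_age_slope = -0.004, noise_sd = 0, seed = 2))
  expect_equal(cor(neg$Age, neg$FusionIndex), -1)
  expect_identical(make_cohort(cohort_spec(seed = 5)),
                   make_cohort(cohort_spec(seed = 5)))
  expect_error(cohort_spec(n_donors = 2), "n_donors")
})
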