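test_that("a large digital disk scores as a circle on every circle-like descriptor", {
  mask <- disk_mask(50)
  p <- compute_shape_profile(mask, 1L)
  expect_equal(p$area_shape, sum(mask))
  expect_lt(abs(p$compactness - 1), 0.02)
  expect_lt(abs(p$form_factor - 1), 0.02)
  expect_lt(p$eccentricity, 0.05)
  # moment axes and Feret diameters all approximate the true diameter
  expect_equal(p$major_axis_length, 100, tolerance = 0.01)
  expect_equal(p$minor_axis_length, 100, tolerance = 0.01)
  expect_equal(p$max_feret_diameter, 100, tolerance = 0.02)
  expect_equal(p$min_feret_diameter, 100, tolerance = 0.02)
  expect_equal(p$maximum_radius, 50, tolerance = 0.02)
  expect_equal(p$equivalent_diameter, sqrt(4 * sum(mask) / pi))
})

test_that("axis-aligned rectangles match closed-form descriptor values", {
  for (dims in list(c(10, 30), c(20, 20), c(4, 40))) {
    h <- dims[1]; w <- dims[2]
    p <- compute_shape_profile(rect_mask(h, w), 1L)
    expect_equal(p$area_shape, h * w)
    expect_equal(p$min_feret_diameter, min(h, w), tolerance = 1 / min(h, w))
    expect_equal(p$max_feret_diameter, sqrt(h^2 + w^2),
                 tolerance = 1 / sqrt(h^2 + w^2))
    expect_equal(p$extent, 1)
    expect_equal(p$solidity, 1)
    expect_equal(p$bounding_box_area, h * w)
  }
})

test_that("caliper Feret diameters agree with an exhaustive 0.1-degree sweep", {
  for (seed in 1:50) {
    mask <- random_blob(seed)
    p <- compute_shape_profile(mask, 1L)
    oracle <- feret_sweep(mask)
    expect_lt(abs(p$max_feret_diameter - oracle["max"]) / oracle["max"], 0.005)
    expect_lt(abs(p$min_feret_diameter - oracle["min"]) / oracle["min"], 0.005)
    # isodiametric bound
    expect_lte(p$equivalent_diameter, p$max_feret_diameter + 1e-9)
  }
})

test_that("descriptors are invariant under translation and 90-degree rotation", {
  mask <- random_blob(3, size = 60)
  base <- compute_shape_profile(mask, 1L)
  shifted <- matrix(0L, 80, 90)
  shifted[13:72, 21:80] <- mask
  tr <- compute_shape_profile(shifted, 1L)
  invariant <- setdiff(names(base),
                       c("label", "centroid_row", "centroid_col",
                         "first_closest_distance", "second_closest_distance"))
  for (v in invariant) expect_equal(tr[[v]], base[[v]], info = v)
  rot <- compute_shape_profile(t(mask[nrow(mask):1, ]), 1L)
  for (v in c("area_shape", "perimeter", "max_feret_diameter",
              "min_feret_diameter", "solidity", "maximum_radius",
              "mean_radius", "median_radius", "major_axis_length",
              "minor_axis_length"))
    expect_equal(rot[[v]], base[[v]], tolerance = 1e-9, info = v)
})

test_that("elongating a fixed-area rectangle raises eccentricity and Feret, lowers form factor", {
  shapes <- list(c(20, 20), c(10, 40), c(8, 50), c(5, 80), c(4, 100))
  profs <- purrr::map_dfr(shapes, ~ compute_shape_profile(rect_mask(.x[1], .x[2]), 1L))
  expect_true(all(diff(profs$eccentricity) > 0))
  expect_true(all(diff(profs$max_feret_diameter) > 0))
  expect_true(all(diff(profs$form_factor) < 0))
})

test_that("neighbour distances need enough objects and are symmetric", {
  m <- matrix(0L, 20, 60)
  m[10, c(5, 15, 30)] <- c(1L, 2L, 3L)  # collinear points at x = 0, 10, 25
  prof <- profile_objects(m)
  expect_equal(prof$first_closest_distance[1], 10)
  expect_equal(prof$second_closest_distance[1], 25)
  expect_equal(prof$first_closest_distance[2], 10)
  # pair symmetry
  m2 <- matrix(0L, 20, 40); m2[10, c(5, 25)] <- c(1L, 2L)
  p2 <- profile_objects(m2)
  expect_equal(p2$first_closest_distance[1], p2$first_closest_distance[2])
  expect_true(all(is.na(p2$second_closest_distance)))
  # singleton: explicitly missing, never zero
  m1 <- matrix(0L, 10, 10); m1[5, 5] <- 1L
  p1 <- profile_objects(m1)
  expect_true(is.na(p1$first_closest_distance))
  expect_true(is.na(p1$second_closest_distance))
})

test_that("image summaries aggregate objects and ignore label identities", {
  m <- matrix(0L, 60, 120)
  g <- expand.grid(r = 1:60, c = 1:120)
  m[(g$r - 30)^2 + (g$c - 30)^2 <= 5.6^2] <- 1L   # ~100 px
  m[(g$r - 30)^2 + (g$c - 90)^2 <= 9.77^2] <- 2L  # ~300 px
  s <- summarize_image(m)
  expect_equal(s$n_objects, 2)
  expect_equal(s$total_area_occupied, sum(m > 0))
  expect_equal(s$area_shape_mean, mean(c(sum(m == 1), sum(m == 2))))
  # relabelling leaves the summary unchanged
  m_swap <- m; m_swap[m == 1] <- 2L; m_swap[m == 2] <- 1L
  expect_equal(summarize_image(m_swap), s)
  # single object: SD undefined, mean equals the object's value
  m1 <- m; m1[m == 2] <- 0L
  s1 <- summarize_image(m1)
  expect_true(is.na(s1$area_shape_sd))
  expect_equal(s1$area_shape_mean, sum(m == 1))
  # empty mask
  s0 <- summarize_image(matrix(0L, 10, 10))
  expect_equal(s0$n_objects, 0)
  expect_equal(s0$total_area_occupied, 0)
})

test_that("profiling an absent label is an error", {
  expect_error(compute_shape_profile(disk_mask(10), 7L), "not present")
})
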