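test_that("fusion index counts nuclei inside multinucleated regions only", {
  # two nuclei in one MHC blob (a myotube), one nucleus in its own blob,
  # one nucleus on bare background
  nuclei <- matrix(0L, 60, 120)
  mhc <- matrix(FALSE, 60, 120)
  g <- expand.grid(r = 1:60, c = 1:120)
  put_nuc <- function(id, r0, c0) {
    nuclei[(g$r - r0)^2 + (g$c - c0)^2 <= 3^2] <<- id
  }
  put_nuc(1L, 30, 20); put_nuc(2L, 30, 40)   # inside the myotube
  put_nuc(3L, 30, 80)                         # mononucleated cell
  put_nuc(4L, 30, 105)                        # background
  mhc[20:40, 10:50] <- TRUE
  mhc[20:40, 70:90] <- TRUE
  fi <- fusion_index(nuclei, mhc, min_cells = 2)
  expect_equal(fi$n_nuclei_total, 4)
  expect_equal(fi$n_nuclei_in_myotubes, 2)
  expect_equal(fi$fusion_index, 0.5)
  expect_equal(fi$n_mhc_cells, 2)
  expect_false(fi$low_count)
  expect_true(fusion_index(nuclei, mhc, min_cells = 500)$low_count)
  expect_error(fusion_index(nuclei, mhc[1:30, ]), "dimensions")
  expect_error(fusion_index(matrix(0L, 5, 5), matrix(FALSE, 5, 5)),
               "no nuclei")
})

test_that("measured fusion index matches generator truth across fractions", {
  for (frac in c(0, 0.5, 1)) {
    fs <- make_fluorescence_scene(40, frac, seed = 7, size = 768)
    nuc <- identify_primary_objects(fs$blue > 0.5, min_diameter = 6)
    fi <- fusion_index(nuc, fs$green > 0.3, min_cells = 1)
    expect_equal(fi$fusion_index, fs$truth_fusion_index, tolerance = 1e-12)
  }
})

test_that("replicate averaging accepts vectors and stacked tables", {
  expect_equal(mean_fusion_index(c(0.5, 0.7)), 0.6)
  tb <- dplyr::bind_rows(
    tibble::tibble(fusion_index = 0.2),
    tibble::tibble(fusion_index = 0.8))
  expect_equal(mean_fusion_index(tb), 0.5)
  expect_error(mean_fusion_index(numeric(0)), "at least one")
})

test_that("per-nucleus CD56 recovers each cell's painted intensity", {
  fs <- make_fluorescence_scene(30, 0.4, seed = 5, size = 768)
  rec <- cd56_per_nucleus(fs$nuclei_mask, fs$red, cell_mask = fs$red > 0.1)
  truth <- fs$truth_nuclei
  expect_equal(nrow(rec), nrow(truth))
  in_cell <- !is.na(truth$cd56)
  expect_true(all(abs(rec$cd56_mean_intensity[in_cell] -
                        truth$cd56[in_cell]) < 1e-9))
  # background nuclei have no stained region
  expect_true(all(is.na(rec$cd56_mean_intensity[!in_cell])))
  # nearest-nucleus distances match a direct pairwise computation
  dm <- as.matrix(stats::dist(cbind(rec$row, rec$col)))
  diag(dm) <- Inf
  expect_equal(rec$closest_nucleus_distance, apply(dm, 1, min))
})

test_that("CD56-distance correlation flags a constructed monotone field", {
  # intensity increasing with isolation: perfect positive rank relation
  rec <- tibble::tibble(cd56_mean_intensity = c(0.2, 0.4, 0.6, 0.8, 0.9),
                        closest_nucleus_distance = c(10, 20, 30, 40, 80))
  out <- cd56_distance_correlation(rec)
  expect_equal(out$r, 1)
  expect_error(cd56_distance_correlation(rec[1:2, ]), "at least 3")
})

test_that("beta-gal scoring reproduces the generated positive fraction", {
  for (frac in c(0, 0.3, 1)) {
    sc <- make_bgal_scene(10, frac, seed = 11)
    expect_equal(bgal_positive_fraction(sc$rgb, sc$cells), frac)
  }
  sc <- make_bgal_scene(6, 0.5, seed = 2)
  # narrowing the hue window to reds finds nothing
  expect_equal(bgal_positive_fraction(sc$rgb, sc$cells,
                                      hue_window = c(0, 30)), 0)
  expect_error(bgal_positive_fraction(sc$rgb, matrix(0L, 4, 4)),
               "dimensions")
})
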