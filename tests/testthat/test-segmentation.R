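test_that("line enhancement amplifies thin ridges and bounds its output", {
  flat <- matrix(0.4, 64, 64)
  expect_equal(enhance_line_structures(flat, 7), matrix(0, 64, 64))
  img <- matrix(0.5, 64, 64)
  img[20:44, 31:33] <- 0.9  # 3-px-wide bright line
  enh <- enhance_line_structures(img, 7)
  expect_true(all(enh >= 0 & enh <= 1))
  expect_equal(max(enh[25:40, 32]), 1)           # line attains the maximum
  expect_lt(mean(enh[1:10, 1:10]), 0.6)          # background stays low
  expect_error(enhance_line_structures(array(0, c(4, 4, 2)), 7))
})

test_that("three-class Otsu matches a brute-force search and honours the floor", {
  # trimodal image with well-separated modes
  set.seed(1)
  img <- matrix(sample(c(0.1, 0.5, 0.9), 64 * 64, TRUE), 64, 64)
  img <- img + matrix(rnorm(64 * 64, 0, 0.01), 64, 64)
  img <- pmin(pmax(img, 0), 1)
  thr <- otsu_three_class(img, smoothing_scale = 0, lower_bound = 0)
  expect_gt(thr$t_low, 0.1); expect_lt(thr$t_low, 0.5)
  expect_gt(thr$t_high, 0.5); expect_lt(thr$t_high, 0.9)
  oracle <- otsu3_bruteforce(img)
  expect_equal(c(thr$t_low, thr$t_high), oracle, tolerance = 1e-12)
  # oracle equivalence on random images
  for (seed in 1:4) {
    set.seed(seed)
    ri <- matrix(runif(64 * 64)^2, 64, 64)
    t2 <- otsu_three_class(ri, smoothing_scale = 0, lower_bound = 0)
    expect_equal(c(t2$t_low, t2$t_high), otsu3_bruteforce(ri),
                 tolerance = 1e-12)
  }
  # flooring contract
  t3 <- otsu_three_class(img, smoothing_scale = 0, lower_bound = 0.74)
  expect_equal(t3$t_low, 0.74)
  expect_identical(t3$foreground, img > 0.74)
  expect_error(otsu_three_class(matrix(0.5, 8, 8)), "constant")
})

test_that("primary-object identification applies the diameter cut-off and 8-connectivity", {
  expect_equal(max(identify_primary_objects(disk_mask(10) > 0, 13)), 1)
  expect_equal(max(identify_primary_objects(disk_mask(4) > 0, 13)), 0)
  # two disks touching diagonally are one 8-connected component
  m <- matrix(0L, 60, 90)
  g <- expand.grid(r = 1:60, c = 1:90)
  m[(g$r - 30)^2 + (g$c - 30)^2 <= 10^2] <- 1L
  m[(g$r - 44)^2 + (g$c - 44)^2 <= 10^2] <- 1L  # touching pair
  expect_equal(max(identify_primary_objects(m > 0, 13)), 1)
})

test_that("merging uses gap width with transitive closure and is idempotent", {
  two_sq <- function(gap) {
    m <- matrix(0L, 40, 60)
    m[11:20, 11:20] <- 1L
    m[11:20, (21 + gap):(30 + gap)] <- 2L
    m
  }
  expect_equal(max(merge_close_objects(two_sq(3), 4)), 1)
  expect_equal(max(merge_close_objects(two_sq(6), 4)), 2)
  # chain A-B-C with consecutive 3-px gaps all merges
  m <- matrix(0L, 40, 80)
  m[11:20, 11:20] <- 1L; m[11:20, 24:33] <- 2L; m[11:20, 37:46] <- 3L
  merged <- merge_close_objects(m, 4)
  expect_equal(max(merged), 1)
  # pixel membership unchanged, idempotent
  expect_identical(merged > 0, m > 0)
  expect_identical(merge_close_objects(merged, 4), merged)
})

test_that("major-axis filtering keeps bars and drops small squares", {
  bar <- rect_mask(4, 30)
  expect_equal(max(filter_by_major_axis(bar, 15)), 1)
  sq <- rect_mask(10, 10)   # moment-based major axis ~ 11.6 px
  expect_equal(max(filter_by_major_axis(sq, 15)), 0)
  empty <- matrix(0L, 10, 10)
  expect_identical(filter_by_major_axis(empty, 15), empty)
})

test_that("full pipeline recovers synthetic spindles and rejects blank frames", {
  sc <- make_cell_scene(12, size = 512, seed = 11)
  lab <- segment_pipeline(sc$image)
  expect_equal(attr(lab, "n_objects"), 12)
  expect_true(all(truth_ious(sc$truth_mask, lab) >= 0.7))
  # labels are compact 1..n
  expect_identical(sort(unique(as.integer(lab[lab > 0]))),
                   seq_len(attr(lab, "n_objects")))
  expect_error(segment_pipeline(matrix(0.5, 128, 128)), "constant")
})

test_that("confluence is the covered-area fraction", {
  expect_equal(estimate_confluence(matrix(0L, 8, 8)), 0)
  expect_equal(estimate_confluence(matrix(1L, 8, 8)), 1)
  half <- matrix(0L, 8, 8); half[, 1:4] <- 1L
  expect_equal(estimate_confluence(half), 0.5)
})
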