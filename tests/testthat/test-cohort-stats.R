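test_that("rank correlation matches exact permutation enumeration", {
  set.seed(3)
  for (k in 1:5) {
    x <- sample(100, 7)
    y <- sample(100, 7)
    got <- rank_correlation(x, y, exact = TRUE)
    expect_equal(got$r, cor(x, y, method = "spearman"))
    expect_equal(got$p, spearman_exact_p(x, y), tolerance = 0.02)
  }
  expect_error(rank_correlation(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_error(rank_correlation(1:12, 12:1, exact = TRUE), "n <= 9")
  expect_warning(con <- rank_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(con$r))
  # perfect monotone relation
  perf <- rank_correlation(1:8, (1:8)^3)
  expect_equal(perf$r, 1)
  expect_true(perf$correlated)
})

test_that("the correlated flag fires strictly beyond half", {
  set.seed(9)
  x <- rnorm(30)
  weak <- x + rnorm(30, sd = 3)
  r_weak <- product_moment_correlation(x, weak)
  strong <- x + rnorm(30, sd = 0.3)
  r_strong <- product_moment_correlation(x, strong)
  expect_equal(r_weak$correlated, abs(r_weak$r) > 0.5)
  expect_equal(r_strong$correlated, abs(r_strong$r) > 0.5)
  expect_true(r_strong$correlated)
  expect_equal(product_moment_correlation(1:10, 2 * (1:10) + 3)$r, 1)
})

test_that("Mann-Whitney p-values agree with exact enumeration", {
  set.seed(5)
  for (k in 1:5) {
    a <- rnorm(5); b <- rnorm(6, mean = 0.5)
    got <- mann_whitney(a, b)
    expect_match(got$method, "exact")
    expect_equal(got$p, mann_whitney_exact_p(a, b), tolerance = 1e-12)
  }
  # tied data: enumeration conditions on mid-ranks
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  expect_equal(mann_whitney(a, b)$p, mann_whitney_exact_p(a, b),
               tolerance = 1e-12)
  # large samples fall back to the normal approximation, close to exact
  set.seed(8)
  a <- rnorm(8); b <- rnorm(8, 1)
  approx_p <- mann_whitney(a, b)$p
  expect_match(mann_whitney(a, b)$method, "approximation")
  expect_equal(approx_p, mann_whitney_exact_p(a, b), tolerance = 0.05)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("signed-rank p-values agree with exact sign enumeration", {
  set.seed(6)
  for (k in 1:5) {
    a <- rnorm(8); b <- a + rnorm(8, 0.4)
    got <- wilcoxon_paired(a, b)
    expect_match(got$method, "exact")
    expect_equal(got$p, signed_rank_exact_p(a - b), tolerance = 1e-12)
  }
  expect_warning(z <- wilcoxon_paired(1:4, 1:4), "zero")
  expect_true(is.na(z$p))
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
})

test_that("chi-square matches the closed form on a 2x2 table", {
  tab <- matrix(c(12, 8, 5, 15), 2, byrow = TRUE)
  got <- chi_square(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(got$statistic, stat)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq(stat, 1, lower.tail = FALSE))
  expect_error(chi_square(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("demographics summary reproduces hand-computed group statistics", {
  cohort <- tibble::tibble(
    Age = c(20, 30, 40, 50, 60, 70),
    Sex = rep(c("M", "F"), each = 3),
    BMI = c(22, 24, 26, 21, 23, 25),
    FusionIndex = c(0.8, 0.7, 0.6, 0.5, 0.4, 0.3),
    Tobacco = c(1, 1, 0, 0, 0, 1))
  s <- demographics_summary(cohort)
  m <- s$by_sex[s$by_sex$Sex == "M", ]
  expect_equal(m$age_mean, 30)
  expect_equal(m$age_sd, sd(c(20, 30, 40)))
  expect_equal(m$tobacco_pct, 100 * 2 / 3)
  expect_equal(s$overall$fusionindex_mean, mean(cohort$FusionIndex))
  expect_equal(nrow(s$tests), 4)  # 3 continuous + 1 flag
  expect_true(all(s$tests$p >= 0 & s$tests$p <= 1, na.rm = TRUE))
  td <- generics::tidy(s)
  expect_equal(td$Sex[1], "all")
  expect_equal(generics::glance(s)$n_donors, 6)
  expect_output(print(s), "Cohort demographics")
  expect_error(demographics_summary(cohort[, c("Age", "Sex")]),
               "missing columns")
  expect_warning(demographics_summary(dplyr::mutate(cohort, Sex = "M")),
                 "two sex groups")
})

test_that("the descriptor screen finds planted couplings and skips absent columns", {
  spec <- cohort_spec(n_donors = 40, seed = 31)
  cohort <- make_cohort(spec, descriptor_coupling = c(area_shape = -0.9),
                        descriptor_noise_sd = 0.2)
  scr <- descriptor_fusion_screen(cohort,
                                  descriptors = c("area_shape", "form_factor",
                                                  "not_a_descriptor"))
  expect_s3_class(scr, "fusion_screen")
  expect_equal(attr(scr, "skipped"),
               paste("not_a_descriptor", rep(c("12h", "24h"), each = 2),
                     c("P2", "P3"), sep = "_"))
  planted <- scr[scr$descriptor == "area_shape", ]
  expect_true(all(planted$r < -0.5))
  expect_true(all(planted$correlated))
  neutral <- scr[scr$descriptor == "form_factor", ]
  expect_true(all(abs(neutral$r) < 0.5))
  expect_error(descriptor_fusion_screen(dplyr::select(cohort, -FusionIndex)),
               "FusionIndex")
})

test_that("screen p-value adjustment is Holm over the screened cells", {
  spec <- cohort_spec(n_donors = 20, seed = 12)
  cohort <- make_cohort(spec)
  raw <- descriptor_fusion_screen(cohort, descriptors = c("area_shape",
                                                          "perimeter"))
  adj <- descriptor_fusion_screen(cohort, descriptors = c("area_shape",
                                                          "perimeter"),
                                  adjust = "holm")
  expect_equal(adj$p, raw$p)
  expect_equal(adj$p_adj, p.adjust(raw$p, "holm"))
  expect_true(all(adj$p_adj >= raw$p))
})
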