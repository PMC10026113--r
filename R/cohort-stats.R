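# Statistical layer: small-cohort correlation and comparison tests.
# The wrappers standardise output as one-row tibbles and apply the
# |r| > 0.5 correlation call used throughout the shape screen.

cor_report <- function(r, p, n, method) {
  tibble(r = r, p = p, n = as.integer(n), method = method,
         correlated = !is.na(r) & (r < -0.5 | r > 0.5))
}

#' Spearman rank correlation report
#'
#' Spearman's rho with mid-ranks for ties. By default the p-value uses the
#' t approximation (the common package behaviour at cohort sizes around
#' n = 14); `exact = TRUE` switches to the exact permutation distribution,
#' available for n <= 9 without ties. An |r| beyond 0.5 sets the
#' `correlated` flag.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); incomplete pairs
#'   are dropped.
#' @param exact Use the exact permutation p-value (n <= 9, no ties).
#' @return One-row tibble: `r`, `p`, `n`, `method`, `correlated`.
#' @export
rank_correlation <- function(x, y, exact = FALSE) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) abort("need >= 3 complete pairs of equal length.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input; rank correlation is undefined.")
    return(cor_report(NA_real_, NA_real_, n, "rank"))
  }
  if (exact && (n > 9 || anyDuplicated(x) || anyDuplicated(y)))
    abort("exact rank-correlation p-values require n <= 9 and no ties.")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  cor_report(unname(ct$estimate), ct$p.value, n, "rank")
}

#' Pearson product-moment correlation report
#'
#' @inheritParams rank_correlation
#' @return One-row tibble: `r`, `p` (two-sided t test), `n`, `method`,
#'   `correlated`.
#' @export
product_moment_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) abort("need >= 3 complete pairs of equal length.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input; correlation is undefined.")
    return(cor_report(NA_real_, NA_real_, n, "product-moment"))
  }
  ct <- cor.test(x, y, method = "pearson")
  cor_report(unname(ct$estimate), ct$p.value, n, "product-moment")
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two independent groups. For small samples
#' (`n_a + n_b <= exact_max`) the p-value is computed by exact enumeration
#' of all group assignments conditional on the observed (mid-)ranks, which
#' also handles ties; larger samples use the normal approximation with tie
#' correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_max Largest total sample size for which assignments are
#'   enumerated.
#' @return One-row tibble: `statistic` (U for group `a`), `p`, `n_a`,
#'   `n_b`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) abort("both groups must be non-empty.")
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= exact_max) {
    picks <- combn(na + nb, na)
    us <- colSums(matrix(rk[picks], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "mann-whitney (exact enumeration)"
  } else {
    p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    method <- "mann-whitney (normal approximation)"
  }
  tibble(statistic = u, p = p, n_a = na, n_b = nb, method = method)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired comparison; zero differences are dropped. For
#' `n <= exact_max` remaining pairs without tied magnitudes the p-value is
#' computed by exact enumeration over all sign assignments, otherwise by
#' the normal approximation with tie correction.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param exact_max Largest number of non-zero differences enumerated.
#' @return One-row tibble: `statistic` (V, sum of positive ranks), `p`,
#'   `n` (pairs used), `method`. All-zero differences yield `NA` with a
#'   warning.
#' @export
wilcoxon_paired <- function(a, b, exact_max = 12) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  ok <- complete.cases(a, b)
  d <- (a - b)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; the test is undefined.")
    return(tibble(statistic = NA_real_, p = NA_real_, n = 0L,
                  method = "wilcoxon signed-rank"))
  }
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  if (n <= exact_max && !anyDuplicated(abs(d))) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% rk)
    mu <- n * (n + 1) / 4
    p <- mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
    method <- "wilcoxon signed-rank (exact enumeration)"
  } else {
    p <- suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
    method <- "wilcoxon signed-rank (normal approximation)"
  }
  tibble(statistic = v, p = p, n = as.integer(n), method = method)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; the p-value comes from the chi-square
#' reference distribution with the table's degrees of freedom.
#'
#' @param table A matrix of non-negative counts (typically 2 x 2).
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table)))
    abort("counts must be finite and non-negative.")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Cohort demographics summary with between-sex tests
#'
#' Per-sex and overall mean +/- sample SD of age, BMI and fusion index,
#' per-sex percentages of the lifestyle flags present in the table, and
#' between-sex comparisons (Mann-Whitney for continuous variables,
#' chi-square for flags). SDs of single-donor groups are `NA`.
#'
#' @param cohort A donor table with at least `Age`, `Sex`, `BMI`,
#'   `FusionIndex`; flag columns (`Tobacco`, `Alcohol`, `DrugUse`,
#'   `Diabetes`) are summarised when present.
#' @return A list of class `demographics_summary`: `by_sex`, `overall`
#'   and `tests` tibbles.
#' @export
demographics_summary <- function(cohort) {
  need <- c("Age", "Sex", "BMI", "FusionIndex")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  flags <- intersect(c("Tobacco", "Alcohol", "DrugUse", "Diabetes"),
                     names(cohort))
  cont <- c("Age", "BMI", "FusionIndex")

  stat_block <- function(d) {
    out <- tibble(n = nrow(d))
    for (v in cont) {
      out[[paste0(tolower(v), "_mean")]] <- mean(d[[v]], na.rm = TRUE)
      out[[paste0(tolower(v), "_sd")]] <-
        if (sum(!is.na(d[[v]])) >= 2) sd(d[[v]], na.rm = TRUE) else NA_real_
    }
    for (v in flags)
      out[[paste0(tolower(v), "_pct")]] <- 100 * mean(d[[v]] > 0, na.rm = TRUE)
    out
  }
  by_sex <- cohort |>
    group_by(Sex = .data$Sex) |>
    group_modify(~ stat_block(.x)) |>
    ungroup()
  overall <- stat_block(cohort)

  sexes <- unique(cohort$Sex)
  tests <- NULL
  if (length(sexes) == 2) {
    g1 <- cohort[cohort$Sex == sexes[1], ]
    g2 <- cohort[cohort$Sex == sexes[2], ]
    tests <- bind_rows(
      purrr::map_dfr(cont, function(v) {
        mw <- mann_whitney(g1[[v]], g2[[v]])
        tibble(variable = v, test = mw$method, statistic = mw$statistic,
               p = mw$p)
      }),
      purrr::map_dfr(flags, function(v) {
        tab <- rbind(c(sum(g1[[v]] > 0), sum(g1[[v]] == 0)),
                     c(sum(g2[[v]] > 0), sum(g2[[v]] == 0)))
        if (any(colSums(tab) == 0))
          return(tibble(variable = v, test = "chi-square (degenerate)",
                        statistic = NA_real_, p = NA_real_))
        cs <- chi_square(tab)
        tibble(variable = v, test = "chi-square", statistic = cs$statistic,
               p = cs$p)
      })
    )
  } else {
    warn("need exactly two sex groups for between-sex tests; skipping them.")
  }
  structure(list(by_sex = by_sex, overall = overall, tests = tests),
            class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat("Cohort demographics\n\nOverall:\n")
  print(x$overall)
  cat("\nBy sex:\n")
  print(x$by_sex)
  if (!is.null(x$tests)) {
    cat("\nBetween-sex tests:\n")
    print(x$tests)
  }
  invisible(x)
}

#' @export
tidy.demographics_summary <- function(x, ...) {
  bind_rows(mutate(x$overall, Sex = "all", .before = 1), x$by_sex)
}

#' @export
glance.demographics_summary <- function(x, ...) {
  tibble(n_donors = x$overall$n, n_groups = nrow(x$by_sex))
}
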