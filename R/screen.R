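#' Screen shape descriptors against the fusion index
#'
#' Correlates each per-image descriptor mean (by timepoint and passage)
#' with the donors' fusion index, one correlation per descriptor x
#' timepoint x passage cell — the shape-vs-myogenicity screen. Descriptor
#' columns are expected to be named `<descriptor>_<timepoint>_<passage>`
#' (e.g. `area_shape_12h_P2`); missing columns are listed in the
#' `skipped` attribute and skipped. Incomplete donor pairs are dropped per
#' cell (pairwise-complete), with the effective n reported.
#'
#' @param cohort Donor table with `FusionIndex` and descriptor columns.
#' @param descriptors Descriptor names to screen.
#' @param timepoints,passages Character vectors spanned by the column
#'   naming scheme.
#' @param method `"rank"` (Spearman, default) or `"product-moment"`.
#' @param alpha Significance level for the `significant` flag.
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()];
#'   `"none"` by default (the screen reports raw per-descriptor p-values).
#' @return A tibble of class `fusion_screen`: `descriptor`, `timepoint`,
#'   `passage`, `r`, `p`, `n`, `correlated` (|r| > 0.5), `significant`
#'   (adjusted p < alpha). Attribute `skipped` lists absent columns.
#' @export
descriptor_fusion_screen <- function(cohort,
                                     descriptors = shape_descriptor_names(),
                                     timepoints = c("12h", "24h"),
                                     passages = c("P2", "P3"),
                                     method = c("rank", "product-moment"),
                                     alpha = 0.05,
                                     adjust = "none") {
  method <- match.arg(method)
  if (!"FusionIndex" %in% names(cohort))
    abort("`cohort` must contain a FusionIndex column.")
  fi <- cohort$FusionIndex
  grid <- tidyr::expand_grid(descriptor = descriptors,
                             timepoint = timepoints,
                             passage = passages) |>
    mutate(column = paste(.data$descriptor, .data$timepoint, .data$passage,
                          sep = "_"))
  present <- grid$column %in% names(cohort)
  skipped <- grid$column[!present]
  grid <- grid[present, ]
  if (nrow(grid) == 0) abort("no descriptor columns found in `cohort`.")

  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    v <- cohort[[grid$column[i]]]
    ok <- complete.cases(v, fi)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(fi[ok]) == 0)
      return(tibble(r = NA_real_, p = NA_real_, n = sum(ok),
                    method = method, correlated = FALSE))
    if (method == "rank") rank_correlation(v[ok], fi[ok])
    else product_moment_correlation(v[ok], fi[ok])
  })
  out <- bind_cols(grid[c("descriptor", "timepoint", "passage")], res) |>
    mutate(p_adj = p.adjust(.data$p, method = adjust),
           significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
  attr(out, "skipped") <- skipped
  class(out) <- c("fusion_screen", class(out))
  out
}

#' Heatmap of a descriptor-fusion screen
#'
#' @param screen A [descriptor_fusion_screen()] result.
#' @return A ggplot object: descriptors x (timepoint, passage), fill = r,
#'   significant cells starred.
#' @export
plot_fusion_screen <- function(screen) {
  df <- mutate(screen, cell = paste(.data$timepoint, .data$passage))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$descriptor,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Shape descriptors vs fusion index") +
    ggplot2::theme_minimal()
}
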