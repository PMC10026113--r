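#' Fusion index from nuclei and MHC masks
#'
#' A nucleus is assigned to the MHC-positive connected component containing
#' its centroid; components holding two or more nuclei are myotubes. The
#' fusion index is the number of nuclei in myotubes divided by the total
#' number of nuclei. A quality flag (`low_count`) is raised when the image
#' holds fewer than `min_cells` MHC-positive cells/myotubes, mirroring the
#' at-least-500-cells acquisition rule.
#'
#' @param nuclei Integer label mask of nuclei.
#' @param mhc_mask Logical (or 0/1) mask of MHC-positive staining; same
#'   dimensions as `nuclei`.
#' @param min_cells Minimum number of MHC-positive cells for a
#'   full-quality estimate.
#' @return A one-row tibble: `n_nuclei_total`, `n_nuclei_in_myotubes`,
#'   `fusion_index`, `n_mhc_cells`, `low_count`.
#' @export
fusion_index <- function(nuclei, mhc_mask, min_cells = 500) {
  assert_mask(nuclei, "nuclei")
  if (!all(dim(nuclei) == dim(mhc_mask)))
    abort("`nuclei` and `mhc_mask` dimensions differ.")
  cent <- label_centroids(nuclei)
  if (nrow(cent) == 0) abort("no nuclei in the mask.")
  comp <- label_components(mhc_mask > 0)
  at <- comp[cbind(pmin(pmax(round(cent$row), 1), nrow(comp)),
                   pmin(pmax(round(cent$col), 1), ncol(comp)))]
  counts <- table(at[at > 0])
  myotubes <- as.integer(names(counts)[counts >= 2])
  n_in <- sum(at %in% myotubes)
  tibble(
    n_nuclei_total = nrow(cent),
    n_nuclei_in_myotubes = as.integer(n_in),
    fusion_index = n_in / nrow(cent),
    n_mhc_cells = max(comp),
    low_count = max(comp) < min_cells
  )
}

#' Mean fusion index over replicate images
#'
#' Unweighted mean of per-image fusion indices — one centre-of-well image
#' and four cardinal-point images in the study design.
#'
#' @param results Numeric vector of fusion indices, or a data frame with a
#'   `fusion_index` column (e.g. stacked [fusion_index()] rows).
#' @return The mean fusion index.
#' @export
mean_fusion_index <- function(results) {
  v <- if (is.data.frame(results)) results$fusion_index else results
  if (is.null(v) || length(v) < 1) abort("at least one image is required.")
  mean(v)
}

#' Per-nucleus CD56 intensity and nearest-nucleus distance
#'
#' Grows a secondary cell region from each nucleus by distance-limited
#' expansion (every pixel joins its nearest nucleus, capped at
#' `max_expansion` px) and reports the mean red-channel intensity over that
#' region together with the centroid distance to the nearest other nucleus.
#'
#' @param nuclei Integer label mask of nuclei.
#' @param red Red-channel intensity matrix, same dimensions.
#' @param max_expansion Expansion cap in px.
#' @param cell_mask Optional logical mask of the stained cytoplasm; when
#'   given, secondary regions are clipped to it (a nucleus whose region
#'   contains no stained pixel gets `NA` intensity).
#' @return A tibble: `nucleus`, `row`, `col`, `cd56_mean_intensity`,
#'   `closest_nucleus_distance` (`NA` with a single nucleus).
#' @export
cd56_per_nucleus <- function(nuclei, red, max_expansion = 30,
                             cell_mask = NULL) {
  assert_mask(nuclei, "nuclei")
  if (!all(dim(nuclei) == dim(red)))
    abort("`nuclei` and `red` dimensions differ.")
  ids <- label_ids(nuclei)
  if (!length(ids)) abort("no nuclei in the mask.")
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  dist_best <- matrix(Inf, nr, nc)
  assign_best <- matrix(0L, nr, nc)
  for (id in ids) {
    px <- label_pixels(nuclei, id)
    r1 <- max(1, min(px[, 1]) - max_expansion - 1)
    r2 <- min(nr, max(px[, 1]) + max_expansion + 1)
    c1 <- max(1, min(px[, 2]) - max_expansion - 1)
    c2 <- min(nc, max(px[, 2]) + max_expansion + 1)
    sub <- nuclei[r1:r2, c1:c2] == id
    d <- EBImage::distmap(!sub, metric = "euclidean")  # distance to nucleus
    d <- matrix(as.numeric(d), nrow(sub), ncol(sub))
    upd <- d < dist_best[r1:r2, c1:c2]
    db <- dist_best[r1:r2, c1:c2]; ab <- assign_best[r1:r2, c1:c2]
    db[upd] <- d[upd]; ab[upd] <- id
    dist_best[r1:r2, c1:c2] <- db
    assign_best[r1:r2, c1:c2] <- ab
  }
  cent <- label_centroids(nuclei)
  dmat <- if (nrow(cent) > 1) {
    m <- as.matrix(stats::dist(cbind(cent$row, cent$col)))
    diag(m) <- Inf
    apply(m, 1, min)
  } else NA_real_
  region_ok <- dist_best <= max_expansion & assign_best > 0
  if (!is.null(cell_mask)) {
    if (!all(dim(cell_mask) == dim(nuclei)))
      abort("`cell_mask` dimensions differ from `nuclei`.")
    region_ok <- region_ok & (cell_mask > 0)
  }
  means <- vapply(seq_along(ids), function(i) {
    sel <- region_ok & assign_best == ids[i]
    if (!any(sel)) NA_real_ else mean(red[sel])
  }, numeric(1))
  tibble(nucleus = as.integer(ids), row = cent$row, col = cent$col,
         cd56_mean_intensity = means,
         closest_nucleus_distance = dmat)
}

#' Correlation of CD56 intensity with nearest-nucleus distance
#'
#' Rank correlation between the per-nucleus marker intensity and the
#' distance to the closest neighbouring nucleus.
#'
#' @param records A [cd56_per_nucleus()] table (columns
#'   `cd56_mean_intensity` and `closest_nucleus_distance`).
#' @return A one-row correlation tibble, see [rank_correlation()].
#' @export
cd56_distance_correlation <- function(records) {
  ok <- complete.cases(records$cd56_mean_intensity,
                       records$closest_nucleus_distance)
  if (sum(ok) < 3) abort("at least 3 complete nuclei are required.")
  rank_correlation(records$cd56_mean_intensity[ok],
                   records$closest_nucleus_distance[ok])
}

#' Fraction of beta-galactosidase-positive cells
#'
#' A cell is scored positive when at least `min_pixel_fraction` of its
#' pixels fall in the blue hue window at sufficient saturation (HSV space);
#' the result is positives over total cells.
#'
#' @param rgb A height x width x 3 array of RGB intensities in \[0, 1\].
#' @param cells Integer label mask of the cells.
#' @param hue_window Blue hue window in degrees.
#' @param min_saturation Minimum HSV saturation for a stained pixel.
#' @param min_pixel_fraction Minimum stained-pixel fraction per cell.
#' @return The positive fraction, in \[0, 1\].
#' @export
bgal_positive_fraction <- function(rgb, cells, hue_window = c(180, 260),
                                   min_saturation = 0.15,
                                   min_pixel_fraction = 0.10) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (!all(dim(rgb)[1:2] == dim(cells)))
    abort("`rgb` and `cells` dimensions differ.")
  ids <- label_ids(cells)
  if (!length(ids)) abort("no cells in the mask.")
  idx <- which(cells > 0)
  n_px <- prod(dim(cells))
  hsv <- rgb2hsv(r = rgb[idx], g = rgb[idx + n_px], b = rgb[idx + 2 * n_px],
                 maxColorValue = 1)
  hue <- hsv[1, ] * 360
  stained <- hue >= hue_window[1] & hue <= hue_window[2] &
    hsv[2, ] >= min_saturation
  frac <- tapply(stained, cells[idx], mean)
  mean(frac >= min_pixel_fraction)
}
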