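#' Segmentation configuration
#'
#' Bundles the parameters of the brightfield object-identification chain.
#' The defaults are the values used throughout the profiling workflow:
#' objects below 13 px equivalent diameter are discarded, objects separated
#' by at most a 4 px gap are merged, objects with a major axis under 15 px
#' are filtered out, the threshold smoothing scale is 1.3488 (used directly
#' as the Gaussian sigma, in px), the lower bound of the threshold is 0.74
#' normalised intensity, and line structures are enhanced with a disk of
#' radius 7 px.
#'
#' @param min_diameter Minimum equivalent diameter of a primary object, px.
#' @param merge_distance Maximum gap between objects that are merged, px.
#' @param min_major_axis Minimum major-axis length kept, px.
#' @param smoothing_scale Gaussian sigma applied before thresholding, px.
#' @param threshold_lower_bound Floor for the lower Otsu threshold, in
#'   normalised intensity units (0-1).
#' @param enhancement_radius Disk radius of the top-hat line enhancement, px.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(min_diameter = 13,
                                merge_distance = 4,
                                min_major_axis = 15,
                                smoothing_scale = 1.3488,
                                threshold_lower_bound = 0.74,
                                enhancement_radius = 7) {
  stopifnot(min_diameter > 0, merge_distance >= 0, min_major_axis > 0,
            smoothing_scale > 0, enhancement_radius >= 1,
            threshold_lower_bound >= 0, threshold_lower_bound <= 1)
  structure(
    list(min_diameter = min_diameter, merge_distance = merge_distance,
         min_major_axis = min_major_axis, smoothing_scale = smoothing_scale,
         threshold_lower_bound = threshold_lower_bound,
         enhancement_radius = enhancement_radius),
    class = "segmentation_config"
  )
}

#' Enhance elongated line structures
#'
#' The difference of the white and black morphological top-hats with a disk
#' structuring element, rescaled to \[0, 1\]. Thin bright ridges (cell
#' bodies narrower than the disk) are pushed towards 1, thin dark ridges
#' (cell rims) towards 0, and flat background lands in between — the
#' brightfield analogue of a neurite-enhancement filter for spindle-shaped
#' cells. A constant image returns an all-zero (zero-contrast) image.
#'
#' @param image Numeric matrix of intensities.
#' @param radius Disk radius of the structuring element, px (>= 1).
#' @return Enhanced image in \[0, 1\], same dimensions.
#' @export
enhance_line_structures <- function(image, radius = 7) {
  assert_image(image)
  stopifnot(radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  wth <- EBImage::whiteTopHat(image, brush)
  bth <- EBImage::blackTopHat(image, brush)
  out <- rescale01(wth - bth)
  matrix(as.numeric(out), nrow(image), ncol(image))
}

#' Three-class Otsu thresholding with the middle class as foreground
#'
#' Smooths the image with a Gaussian of the given sigma, then finds the
#' threshold pair maximising the between-class variance of a three-class
#' split on a 256-bin histogram. Foreground is everything above the lower
#' threshold (middle plus upper class — in brightfield the cells are the
#' mid-intensity phase and their rims the brightest one, so discarding the
#' top class would drop cell rims). The lower threshold is floored at
#' `lower_bound` to guard against illumination drift.
#'
#' @param image Numeric matrix of intensities in \[0, 1\]; must not be
#'   constant.
#' @param smoothing_scale Gaussian sigma in px (0 disables smoothing).
#' @param lower_bound Floor applied to the lower threshold.
#' @return A list of class `threshold_result`: `t_low`, `t_high` (normalised
#'   intensities) and `foreground` (logical matrix).
#' @export
otsu_three_class <- function(image, smoothing_scale = 1.3488,
                             lower_bound = 0.74) {
  assert_image(image)
  if (diff(range(image)) == 0)
    abort("image is constant; no threshold is defined.")
  sm <- if (smoothing_scale > 0) {
    m <- EBImage::gblur(image, sigma = smoothing_scale)
    matrix(as.numeric(m), nrow(image), ncol(image))
  } else image

  nb <- 256L
  bin <- pmin(pmax(floor(sm * nb), 0), nb - 1L)  # bin k covers [k/nb, (k+1)/nb)
  counts <- tabulate(bin + 1L, nbins = nb)
  w <- cumsum(counts)
  s <- cumsum(counts * (seq_len(nb) - 0.5))  # bin centres in bin units
  n <- w[nb]; stot <- s[nb]

  # between-class variance for every threshold pair (i < j), vectorised:
  # class 0 = bins 1..i, class 1 = bins (i+1)..j, class 2 = rest
  w0 <- matrix(w, nb, nb)                 # rows i
  s0 <- matrix(s, nb, nb)
  w1 <- matrix(w, nb, nb, byrow = TRUE) - w0   # cols j
  s1 <- matrix(s, nb, nb, byrow = TRUE) - s0
  w2 <- n - w0 - w1
  s2 <- stot - s0 - s1
  sq <- function(sw, ww) { v <- sw^2 / ww; v[ww == 0] <- 0; v }
  bcv <- sq(s0, w0) + sq(s1, w1) + sq(s2, w2)
  bcv[!upper.tri(bcv)] <- -Inf             # need i < j
  best <- arrayInd(which.max(bcv), dim(bcv))
  t_low <- best[1] / nb                    # upper edge of class-0 bins
  t_high <- best[2] / nb

  t_low <- max(t_low, lower_bound)
  if (t_high <= t_low) t_high <- min(t_low + 1 / nb, 1)
  structure(
    list(t_low = t_low, t_high = t_high, foreground = sm > t_low),
    class = "threshold_result"
  )
}

#' Identify primary objects in a binary mask
#'
#' Labels 8-connected components and discards components whose equivalent
#' diameter (diameter of the equal-area circle) is below `min_diameter`.
#'
#' @param mask Logical or 0/1 matrix.
#' @param min_diameter Minimum equivalent diameter in px.
#' @return Integer label mask with labels 1..n.
#' @export
identify_primary_objects <- function(mask, min_diameter = 13) {
  lab <- label_components(mask > 0)
  if (!max(lab)) return(lab)
  areas <- tabulate(lab[lab > 0])
  min_area <- pi * (min_diameter / 2)^2
  keep <- which(areas >= min_area)
  lab[!(lab %in% keep)] <- 0L
  compact_labels(lab)
}

#' Merge objects separated by a small gap
#'
#' Objects whose boundaries are within `merge_distance` pixels of each other
#' (gap width, i.e. minimum Euclidean centre-to-centre distance between
#' boundary pixels minus one) receive a common label, with transitive
#' closure; pixel memberships are unchanged. Labels are re-compacted to
#' 1..n, so a merged label can cover disconnected pixels.
#'
#' @param labels Integer label mask.
#' @param merge_distance Maximum gap in px.
#' @return Integer label mask.
#' @export
merge_close_objects <- function(labels, merge_distance = 4) {
  assert_mask(labels, "labels")
  ids <- label_ids(labels)
  if (length(ids) < 2) return(compact_labels(labels))

  # boundary pixels (those with a 4-neighbour outside the object) per object
  bounds <- lapply(ids, function(id) {
    px <- label_pixels(labels, id)
    inside <- function(rr, cc) {
      ok <- rr >= 1 & rr <= nrow(labels) & cc >= 1 & cc <= ncol(labels)
      v <- rep(FALSE, length(rr))
      v[ok] <- labels[cbind(rr[ok], cc[ok])] == id
      v
    }
    core <- inside(px[, 1] - 1, px[, 2]) & inside(px[, 1] + 1, px[, 2]) &
      inside(px[, 1], px[, 2] - 1) & inside(px[, 1], px[, 2] + 1)
    px[!core, , drop = FALSE]
  })
  boxes <- t(vapply(bounds, function(b)
    c(min(b[, 1]), max(b[, 1]), min(b[, 2]), max(b[, 2])), numeric(4)))

  k <- length(ids)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  gate <- merge_distance + 1  # centre distance corresponding to the gap
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (boxes[j, 1] - boxes[i, 2] > gate || boxes[i, 1] - boxes[j, 2] > gate ||
          boxes[j, 3] - boxes[i, 4] > gate || boxes[i, 3] - boxes[j, 4] > gate)
        next
      bi <- bounds[[i]]; bj <- bounds[[j]]
      d2min <- min(outer(bi[, 1], bj[, 1], "-")^2 +
                     outer(bi[, 2], bj[, 2], "-")^2)
      if (sqrt(d2min) - 1 <= merge_distance) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  out <- labels
  out[out > 0] <- root[match(out[out > 0], ids)]
  compact_labels(out)
}

#' Filter objects by major-axis length
#'
#' Removes objects whose moment-based major-axis length is below
#' `min_major_axis`; survivors keep their pixels and labels are
#' re-compacted to 1..n.
#'
#' @param labels Integer label mask.
#' @param min_major_axis Minimum major-axis length in px.
#' @return Integer label mask.
#' @export
filter_by_major_axis <- function(labels, min_major_axis = 15) {
  assert_mask(labels, "labels")
  ids <- label_ids(labels)
  if (!length(ids)) return(compact_labels(labels))
  major <- vapply(ids, function(id) {
    px <- label_pixels(labels, id)
    mrr <- mean((px[, 1] - mean(px[, 1]))^2) + 1 / 12
    mcc <- mean((px[, 2] - mean(px[, 2]))^2) + 1 / 12
    mrc <- mean((px[, 1] - mean(px[, 1])) * (px[, 2] - mean(px[, 2])))
    4 * sqrt((mrr + mcc + sqrt((mrr - mcc)^2 + 4 * mrc^2)) / 2)
  }, numeric(1))
  out <- labels
  out[out %in% ids[major < min_major_axis]] <- 0L
  compact_labels(out)
}

#' Full brightfield segmentation chain
#'
#' Line-structure enhancement, three-class Otsu thresholding (middle +
#' upper class as foreground), primary-object identification, merging of
#' near objects and major-axis filtering, in that order. The per-image
#' object count is attached as the `n_objects` attribute so runs can be
#' monitored frame by frame.
#'
#' @param image Numeric intensity matrix in \[0, 1\].
#' @param config A [segmentation_config()].
#' @return Integer label mask with attribute `n_objects`.
#' @export
segment_pipeline <- function(image, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  enh <- enhance_line_structures(image, config$enhancement_radius)
  thr <- otsu_three_class(enh, config$smoothing_scale,
                          config$threshold_lower_bound)
  lab <- identify_primary_objects(thr$foreground, config$min_diameter)
  lab <- merge_close_objects(lab, config$merge_distance)
  lab <- filter_by_major_axis(lab, config$min_major_axis)
  attr(lab, "n_objects") <- max(lab)
  lab
}

#' Confluence (area fraction) of a mask
#'
#' @param mask Logical or label matrix; anything positive counts as covered.
#' @return Fraction of covered pixels, in \[0, 1\].
#' @export
estimate_confluence <- function(mask) {
  assert_mask(mask)
  mean(mask > 0)
}
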