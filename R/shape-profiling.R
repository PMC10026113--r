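#' Names of the cell-shape descriptors
#'
#' The descriptor suite measured per object (18 object-level descriptors)
#' plus the image-level total area occupied, 19 in all. These names are used
#' as column names by [profile_objects()], [summarize_image()] and the
#' synthetic cohort generator, and as row identities by
#' [descriptor_fusion_screen()].
#'
#' @param level `"object"` for the per-object descriptors, `"image"` to also
#'   include `total_area_occupied`.
#' @return Character vector of descriptor names.
#' @export
shape_descriptor_names <- function(level = c("image", "object")) {
  level <- match.arg(level)
  obj <- c(
    "area_shape", "bounding_box_area", "compactness", "eccentricity",
    "equivalent_diameter", "extent", "form_factor", "major_axis_length",
    "max_feret_diameter", "maximum_radius", "mean_radius", "median_radius",
    "min_feret_diameter", "minor_axis_length", "perimeter", "solidity",
    "first_closest_distance", "second_closest_distance"
  )
  if (level == "object") obj else c("total_area_occupied", obj)
}

#' Shape profile of a single labelled object
#'
#' Computes the full descriptor suite for one object of a label mask:
#' pixel-count area, bounding-box area and extent, moment-based axis lengths
#' and eccentricity (with the +1/12 per-pixel variance correction, so a
#' single pixel has finite axes), compactness normalised so a filled circle
#' scores 1, form factor \eqn{4\pi A / P^2}, Feret diameters by caliper
#' search over the convex hull of pixel corners, radii from the Euclidean
#' distance transform, a corner-corrected boundary-length perimeter, and
#' solidity against the pixel-corner convex hull.
#'
#' @param labels Integer label mask (0 = background).
#' @param label The object label to profile.
#' @param perimeter_method `"vossepoel"` (corner-corrected weights, default)
#'   or `"chain"` (naive 1/sqrt(2) weights).
#' @return A one-row tibble with `label`, `centroid_row`, `centroid_col` and
#'   the per-object descriptors of [shape_descriptor_names()]. The
#'   neighbour distances are `NA` here; fill them with
#'   [neighbor_distances()] once all objects of the image are profiled.
#' @seealso [profile_objects()] for all objects at once.
#' @export
compute_shape_profile <- function(labels, label,
                                  perimeter_method = c("vossepoel", "chain")) {
  assert_mask(labels, "labels")
  perimeter_method <- match.arg(perimeter_method)
  px <- label_pixels(labels, label)
  area <- nrow(px)

  r <- px[, 1]; c <- px[, 2]
  rmin <- min(r); rmax <- max(r); cmin <- min(c); cmax <- max(c)
  bbox_area <- (rmax - rmin + 1) * (cmax - cmin + 1)
  cr <- mean(r); cc <- mean(c)

  # second central moments with the square-pixel (+1/12) correction
  mrr <- mean((r - cr)^2) + 1 / 12
  mcc <- mean((c - cc)^2) + 1 / 12
  mrc <- mean((r - cr) * (c - cc))
  tr <- mrr + mcc
  det_rt <- sqrt(max((mrr - mcc)^2 + 4 * mrc^2, 0))
  l1 <- (tr + det_rt) / 2
  l2 <- (tr - det_rt) / 2
  l2 <- max(l2, 0)

  msd <- mean((r - cr)^2 + (c - cc)^2)
  compactness <- 2 * pi * msd / area
  eccentricity <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0

  hull <- pixel_corner_hull(px)
  feret <- feret_from_hull(hull)
  hull_area <- polygon_area(hull)

  perim <- pixel_set_perimeter(px, perimeter_method)

  # Euclidean distance of object pixels to the nearest background pixel
  sub <- matrix(FALSE, rmax - rmin + 3L, cmax - cmin + 3L)
  sub[cbind(r - rmin + 2L, c - cmin + 2L)] <- TRUE
  dm <- EBImage::distmap(sub, metric = "euclidean")
  radii <- dm[sub]

  tibble(
    label = as.integer(label),
    centroid_row = cr,
    centroid_col = cc,
    area_shape = as.numeric(area),
    bounding_box_area = as.numeric(bbox_area),
    compactness = compactness,
    eccentricity = eccentricity,
    equivalent_diameter = sqrt(4 * area / pi),
    extent = area / bbox_area,
    form_factor = 4 * pi * area / perim^2,
    major_axis_length = 4 * sqrt(l1),
    max_feret_diameter = unname(feret["max"]),
    maximum_radius = max(radii),
    mean_radius = mean(radii),
    median_radius = median(radii),
    min_feret_diameter = unname(feret["min"]),
    minor_axis_length = 4 * sqrt(l2),
    perimeter = perim,
    solidity = if (hull_area > 0) min(area / hull_area, 1) else NA_real_,
    first_closest_distance = NA_real_,
    second_closest_distance = NA_real_
  )
}

#' Profile every object of a label mask
#'
#' @inheritParams compute_shape_profile
#' @param neighbors Fill the closest-object distances via
#'   [neighbor_distances()] (default `TRUE`).
#' @return A tibble with one row per object (empty, with the full schema,
#'   for an object-free mask).
#' @export
profile_objects <- function(labels, perimeter_method = "vossepoel",
                            neighbors = TRUE) {
  assert_mask(labels, "labels")
  ids <- label_ids(labels)
  if (!length(ids)) {
    out <- compute_shape_profile(matrix(c(0L, 1L), 2, 2), 1L)[0, ]
    return(out)
  }
  out <- purrr::map_dfr(ids, function(id)
    compute_shape_profile(labels, id, perimeter_method))
  if (neighbors) out <- neighbor_distances(out)
  out
}

#' Distances to the first and second closest objects
#'
#' Centroid-to-centroid distances, per object, to its nearest and second
#' nearest neighbour in the same image. An image must hold at least two
#' objects for the first distance and three for the second; otherwise the
#' distances are explicit `NA` markers (never 0).
#'
#' @param profiles A tibble with `centroid_row` and `centroid_col` columns,
#'   as produced by [profile_objects()].
#' @return The input with `first_closest_distance` and
#'   `second_closest_distance` filled in.
#' @export
neighbor_distances <- function(profiles) {
  n <- nrow(profiles)
  if (n == 0) return(profiles)
  profiles$first_closest_distance <- NA_real_
  profiles$second_closest_distance <- NA_real_
  if (n >= 2) {
    d <- as.matrix(stats::dist(cbind(profiles$centroid_row,
                                     profiles$centroid_col)))
    diag(d) <- Inf
    sorted <- apply(d, 1, sort)
    profiles$first_closest_distance <- unname(sorted[1, ])
    if (n >= 3) profiles$second_closest_distance <- unname(sorted[2, ])
  }
  profiles
}

#' Per-image summary of the shape descriptors
#'
#' Mirrors the per-image export of the profiling pipeline: the object count,
#' the total area occupied by all objects, and the mean and sample standard
#' deviation of every per-object descriptor across the objects of the image.
#'
#' @inheritParams compute_shape_profile
#' @param profiles Optionally, an already-computed [profile_objects()] table
#'   for `labels` (saves recomputation).
#' @return A one-row tibble: `n_objects`, `total_area_occupied`, then
#'   `<descriptor>_mean` and `<descriptor>_sd` columns. With a single object
#'   the SDs are `NA`; with no objects all statistics are `NA`.
#' @export
summarize_image <- function(labels, profiles = NULL,
                            perimeter_method = "vossepoel") {
  assert_mask(labels, "labels")
  if (is.null(profiles))
    profiles <- profile_objects(labels, perimeter_method)
  descs <- shape_descriptor_names("object")
  out <- tibble(
    n_objects = nrow(profiles),
    total_area_occupied = as.numeric(sum(labels > 0))
  )
  for (d in descs) {
    v <- profiles[[d]]
    out[[paste0(d, "_mean")]] <- if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    out[[paste0(d, "_sd")]] <- if (length(v) >= 2) sd(v, na.rm = TRUE) else NA_real_
  }
  if (nrow(profiles) == 0) out$total_area_occupied <- 0
  out
}
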