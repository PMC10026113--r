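#' Tracking configuration
#'
#' @param avg_diameter Average cell diameter in px (kept for interface
#'   fidelity with the profiling pipeline; the greedy matcher itself is
#'   purely distance-gated).
#' @param max_match_distance Maximum centroid displacement considered a
#'   match, px.
#' @param frame_interval Minutes between frames.
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(avg_diameter = 45, max_match_distance = 70,
                            frame_interval = 5) {
  stopifnot(max_match_distance > 0, frame_interval > 0)
  structure(list(avg_diameter = avg_diameter,
                 max_match_distance = max_match_distance,
                 frame_interval = frame_interval),
            class = "tracking_config")
}

as_centroid_matrix <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$row, x$col)
  if (is.null(x) || length(x) == 0) return(matrix(numeric(0), 0, 2))
  if (!is.matrix(x)) x <- matrix(x, ncol = 2, byrow = TRUE)
  x
}

#' Link objects between two consecutive frames
#'
#' Greedy nearest-neighbour bipartite matching: candidate pairs are taken
#' in ascending distance (ties broken by lower row, then column, of the
#' earlier frame's centroid) and accepted while both endpoints are free and
#' the distance does not exceed the match gate. Unmatched next-frame
#' objects start new tracks; unmatched previous-frame objects end theirs.
#'
#' @param prev,next_ Centroids of the two frames: a matrix or data frame
#'   with (row, col) coordinates.
#' @param config A [tracking_config()].
#' @return A list of class `frame_link`: `matches` (tibble `prev`, `next`,
#'   `distance`), `started` (indices into `next_`), `ended` (indices into
#'   `prev`).
#' @export
link_frames <- function(prev, next_, config = tracking_config()) {
  stopifnot(inherits(config, "tracking_config"))
  p <- as_centroid_matrix(prev)
  q <- as_centroid_matrix(next_)
  if (nrow(p) == 0 || nrow(q) == 0) {
    m <- tibble(prev = integer(), next_ = integer(), distance = numeric())
  } else {
    d <- sqrt(outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2)
    cand <- which(d <= config$max_match_distance, arr.ind = TRUE)
    m <- tibble(prev = integer(), next_ = integer(), distance = numeric())
    if (nrow(cand)) {
      dv <- d[cand]
      ord <- order(dv, p[cand[, 1], 1], p[cand[, 1], 2],
                   q[cand[, 2], 1], q[cand[, 2], 2])
      cand <- cand[ord, , drop = FALSE]
      dv <- dv[ord]
      used_p <- logical(nrow(p)); used_q <- logical(nrow(q))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_q[j]) {
          used_p[i] <- TRUE; used_q[j] <- TRUE
          m <- bind_rows(m, tibble(prev = as.integer(i), next_ = as.integer(j),
                                   distance = dv[k]))
        }
      }
    }
  }
  structure(list(
    matches = m,
    started = setdiff(seq_len(nrow(q)), m$next_),
    ended = setdiff(seq_len(nrow(p)), m$prev)),
    class = "frame_link")
}

#' Track objects across a whole sequence
#'
#' Applies [link_frames()] frame by frame, assigning persistent track ids.
#'
#' @param centroids_by_frame A list (one element per frame) of centroid
#'   matrices/data frames with (row, col), or a `timelapse` from
#'   [make_timelapse()] (its truth centroids are then used).
#' @param config A [tracking_config()].
#' @return A tibble of class `track_table`: `track_id`, `frame`, `object`
#'   (index within the frame), `row`, `col`, with `frame_interval` (min)
#'   attached as an attribute.
#' @export
track_objects <- function(centroids_by_frame, config = tracking_config()) {
  if (inherits(centroids_by_frame, "timelapse")) {
    tr <- centroids_by_frame$truth_tracks
    centroids_by_frame <- lapply(split(tr, tr$frame),
                                 function(d) cbind(d$row, d$col))
  }
  frames <- lapply(centroids_by_frame, as_centroid_matrix)
  n_frames <- length(frames)
  out <- list()
  next_id <- 0L
  cur_ids <- integer(0)
  for (f in seq_len(n_frames)) {
    q <- frames[[f]]
    ids <- rep(NA_integer_, nrow(q))
    if (f == 1 || length(cur_ids) == 0) {
      if (nrow(q)) ids <- next_id + seq_len(nrow(q))
      next_id <- next_id + nrow(q)
    } else {
      link <- link_frames(frames[[f - 1]], q, config)
      ids[link$matches$next_] <- cur_ids[link$matches$prev]
      if (length(link$started)) {
        ids[link$started] <- next_id + seq_along(link$started)
        next_id <- next_id + length(link$started)
      }
    }
    if (nrow(q))
      out[[f]] <- tibble(track_id = ids, frame = as.integer(f),
                         object = seq_len(nrow(q)),
                         row = q[, 1], col = q[, 2])
    cur_ids <- ids
  }
  res <- bind_rows(out)
  attr(res, "frame_interval") <- config$frame_interval
  class(res) <- c("track_table", class(res))
  res
}

#' Path length travelled per track within a time window
#'
#' Cumulative path length (sum of consecutive centroid displacements) for
#' every track alive throughout `[window_start, window_start + window_len)`
#' hours, plus the image-level mean over those tracks. A two-hour window
#' placed at 12 or 24 h of imaging matches the study design.
#'
#' @param tracks A [track_objects()] table.
#' @param window_start Window start, hours from the first frame.
#' @param window_len Window length, hours.
#' @param frame_interval Minutes between frames; defaults to the attribute
#'   stored on `tracks`.
#' @param measure `"path"` (cumulative path length, default) or `"net"`
#'   (straight-line start-to-end displacement).
#' @return A list of class `track_distance`: `per_track` (tibble
#'   `track_id`, `distance_px`) and `mean_distance` (`NA` with a warning if
#'   no track spans the window).
#' @export
track_distance <- function(tracks, window_start, window_len = 2,
                           frame_interval = NULL,
                           measure = c("path", "net")) {
  measure <- match.arg(measure)
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 5
  t_h <- (tracks$frame - 1) * frame_interval / 60
  in_win <- t_h >= window_start & t_h < window_start + window_len
  if (!any(in_win)) abort("the window is not covered by the sequence.")
  win <- tracks[in_win, ]
  frames_needed <- sort(unique(win$frame))
  per <- win |>
    group_by(.data$track_id) |>
    filter(length(unique(.data$frame)) == length(frames_needed)) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(distance_px = if (measure == "path")
      sum(sqrt(diff(.data$row)^2 + diff(.data$col)^2))
      else sqrt((last(.data$row) - first(.data$row))^2 +
                  (last(.data$col) - first(.data$col))^2),
      .groups = "drop")
  mean_d <- if (nrow(per)) mean(per$distance_px) else {
    warn("no track spans the whole window; mean distance is undefined.")
    NA_real_
  }
  structure(list(per_track = per, mean_distance = mean_d,
                 window = c(start_h = window_start, len_h = window_len)),
            class = "track_distance")
}

#' Time for the object count to double
#'
#' First time at which the per-frame object count reaches twice the count
#' of the first frame, linearly interpolated between frames, in hours.
#'
#' @param object_counts Per-frame object counts.
#' @param frame_interval Minutes between frames.
#' @return Doubling time in hours, or `NA` (with a warning) if the count
#'   never doubles.
#' @export
doubling_time <- function(object_counts, frame_interval = 5) {
  if (!length(object_counts)) abort("empty count series.")
  target <- 2 * object_counts[1]
  hit <- which(object_counts >= target)
  if (!length(hit)) {
    warn("object count never doubles within the series.")
    return(NA_real_)
  }
  f <- hit[1]
  t_hit <- if (f == 1) 0 else {
    c0 <- object_counts[f - 1]; c1 <- object_counts[f]
    (f - 2) + (target - c0) / (c1 - c0)   # frames are 1-based, t = (f-1)*dt
  }
  t_hit * frame_interval / 60
}
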