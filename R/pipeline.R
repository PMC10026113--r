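# Orchestration: run the profile-then-correlate analysis from a directory
# of images plus a donor table, or from synthetic data end to end. These
# functions are the package's batch interface; they only compose the
# module-level functions and handle file I/O.

read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3) img <- EBImage::channel(img, "luminance")
  m <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
  if (max(m) > 1) m <- m / max(m)
  m
}

#' Profile every frame of an image directory
#'
#' Segments each grayscale frame (TIFF/PNG, lexicographic order) with
#' [segment_pipeline()] and exports a per-object table (one row per object
#' per frame, all shape descriptors) and a per-image summary table.
#' Unreadable frames are reported and skipped; the run continues and the
#' failures are attached as the `failures` attribute.
#'
#' @param images A directory of TIFF/PNG frames, a character vector of
#'   file paths, or a list of intensity matrices.
#' @param config A [segmentation_config()].
#' @param out_dir Optional output directory; when given,
#'   `objects.csv` and `images.csv` are written there.
#' @return A list of class `profile_run`: `objects` and `images` tibbles
#'   (each with a `frame` column) and `failures` (tibble of file, error).
#' @export
run_profile <- function(images, config = segmentation_config(),
                        out_dir = NULL) {
  if (length(images) == 1 && is.character(images) && dir.exists(images)) {
    images <- sort(list.files(images, pattern = "\\.(tif|tiff|png)$",
                              ignore.case = TRUE, full.names = TRUE))
  }
  if (length(images) == 0) abort("no input frames found.")
  frames <- if (is.character(images)) as.list(images) else images
  objects <- list(); summaries <- list(); failures <- list()
  for (f in seq_along(frames)) {
    res <- tryCatch({
      img <- if (is.character(frames[[f]])) read_gray_image(frames[[f]])
      else frames[[f]]
      lab <- segment_pipeline(img, config)
      prof <- profile_objects(lab)
      list(objects = mutate(prof, frame = as.integer(f), .before = 1),
           summary = mutate(summarize_image(lab, prof),
                            frame = as.integer(f), .before = 1))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble(
        frame = f,
        file = if (is.character(frames[[f]])) frames[[f]] else NA_character_,
        error = conditionMessage(res))
    } else {
      objects[[f]] <- res$objects
      summaries[[f]] <- res$summary
    }
  }
  out <- list(objects = bind_rows(objects), images = bind_rows(summaries),
              failures = bind_rows(failures))
  if (nrow(out$failures))
    warn(sprintf("%d frame(s) failed; see $failures.", nrow(out$failures)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$objects, file.path(out_dir, "objects.csv"))
    readr::write_csv(out$images, file.path(out_dir, "images.csv"))
  }
  structure(out, class = "profile_run")
}

#' Demographics and descriptor screen for a donor table
#'
#' Runs [demographics_summary()] and, when descriptor columns (or a
#' separate per-donor image-summary table) are available,
#' [descriptor_fusion_screen()]; optionally writes the screen as CSV and a
#' structured JSON report.
#'
#' @param donors A donor table (tibble) or path to a donor CSV with the
#'   reference column layout (must include `FusionIndex`).
#' @param image_summaries Optional per-donor descriptor table with a
#'   `Donor` column to join onto `donors`; donor ids present in one table
#'   but not the other abort the run.
#' @param out_dir Optional output directory (`screen.csv`, `report.json`).
#' @param ... Passed to [descriptor_fusion_screen()].
#' @return A list of class `correlate_run`: `demographics` and `screen`
#'   (`NULL` when no descriptor columns exist).
#' @export
run_correlate <- function(donors, image_summaries = NULL, out_dir = NULL,
                          ...) {
  if (is.character(donors)) donors <- readr::read_csv(donors,
                                                      show_col_types = FALSE)
  if (!"FusionIndex" %in% names(donors))
    abort("donor table has no FusionIndex column.")
  if (!is.null(image_summaries)) {
    if (!"Donor" %in% names(donors) || !"Donor" %in% names(image_summaries))
      abort("both tables need a Donor column to be joined.")
    only_a <- setdiff(donors$Donor, image_summaries$Donor)
    only_b <- setdiff(image_summaries$Donor, donors$Donor)
    if (length(only_a) || length(only_b))
      abort(paste0("donor id mismatch between tables; only in donors: [",
                   paste(only_a, collapse = ", "), "], only in summaries: [",
                   paste(only_b, collapse = ", "), "]"))
    donors <- left_join(donors, image_summaries, by = "Donor")
  }
  demo <- demographics_summary(donors)
  has_desc <- any(vapply(shape_descriptor_names(), function(d)
    any(startsWith(names(donors), paste0(d, "_"))), logical(1)))
  screen <- if (has_desc) descriptor_fusion_screen(donors, ...) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(screen))
      readr::write_csv(as_tibble(screen), file.path(out_dir, "screen.csv"))
    report <- list(
      schema = "myoshape/report/v1",
      demographics = list(overall = demo$overall, by_sex = demo$by_sex,
                          tests = demo$tests),
      screen = if (!is.null(screen)) as_tibble(screen)
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  structure(list(demographics = demo, screen = screen),
            class = "correlate_run")
}

#' Simulate a dataset on disk
#'
#' Writes a synthetic time-lapse (TIFF frames under `frames/`, 16-bit TIFF
#' truth masks and JSON truth sidecars under `truth/`), a synthetic donor
#' cohort CSV and a manifest recording the generation parameters and seed
#' — a self-contained dataset whose `frames/` directory [run_profile()]
#' can consume directly and whose cohort [run_correlate()] can analyse.
#'
#' @param out_dir Output directory; must be empty unless `force = TRUE`.
#' @param n_cells,size,n_frames,step_px Scene and time-lapse parameters
#'   (see [make_cell_scene()] and [make_timelapse()]).
#' @param cohort A [cohort_spec()] for the donor table.
#' @param seed Integer seed for the whole dataset.
#' @param force Overwrite a non-empty `out_dir`.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(out_dir, n_cells = 20, size = 960, n_frames = 3,
                         step_px = 5, cohort = cohort_spec(), seed = 1,
                         force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    abort("`out_dir` is not empty; use force = TRUE to overwrite.")
  dir.create(file.path(out_dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  scene <- make_cell_scene(n_cells, size = size, seed = seed)
  tl <- make_timelapse(scene, n_frames = n_frames, step_px = step_px,
                       seed = seed + 1)
  for (f in seq_along(tl$frames)) {
    fr <- tl$frames[[f]]
    EBImage::writeImage(EBImage::Image(fr$image),
                        file.path(out_dir, "frames",
                                  sprintf("frame_%03d.tiff", f)))
    EBImage::writeImage(EBImage::Image(fr$truth_mask / 65535),
                        file.path(out_dir, "truth",
                                  sprintf("truth_%03d.tiff", f)),
                        bits.per.sample = 16L)
    jsonlite::write_json(fr$truth_params,
                         file.path(out_dir, "truth",
                                   sprintf("truth_%03d.json", f)),
                         dataframe = "rows", digits = NA)
  }
  cohort$seed <- cohort$seed %||% (seed + 2)
  donors <- make_cohort(cohort)
  readr::write_csv(donors, file.path(out_dir, "cohort.csv"))
  manifest <- list(schema = "myoshape/dataset/v1", seed = seed,
                   n_cells = n_cells, size = size, n_frames = n_frames,
                   step_px = step_px, cohort = unclass(cohort))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
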