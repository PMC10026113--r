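# Synthetic microscopy with exact ground truth. The generators emulate the
# study's imaging conditions (a 960 x 960 px brightfield field holding ~20
# spindle-shaped cells, frames every 5 min) while keeping every truth value
# analytic, so downstream stages can be tested without external data.

ellipse_metric <- function(rows, cols, r0, c0, a, b, theta) {
  dr <- rows - r0; dc <- cols - c0
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  (u / a)^2 + (v / b)^2
}

# paint one spindle cell (bright body, darker rim) into image/mask in place
paint_cell <- function(image, mask, label, r0, c0, a, b, theta,
                       body = 0.85, rim = 0.25, rim_width = 2) {
  nr <- nrow(image); nc <- ncol(image)
  ext <- ceiling(a + rim_width + 1)
  rs <- max(1, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cs <- max(1, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  grid_r <- matrix(rs, length(rs), length(cs))
  grid_c <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  m_in <- ellipse_metric(grid_r, grid_c, r0, c0, a, b, theta)
  m_out <- ellipse_metric(grid_r, grid_c, r0, c0, a + rim_width,
                          b + rim_width, theta)
  body_px <- m_in <= 1
  rim_px <- !body_px & m_out <= 1
  img_sub <- image[rs, cs]
  img_sub[body_px] <- body
  img_sub[rim_px] <- rim
  image[rs, cs] <- img_sub
  msk_sub <- mask[rs, cs]
  msk_sub[body_px] <- label
  mask[rs, cs] <- msk_sub
  list(image = image, mask = mask)
}

# rejection-sample non-overlapping centres; conservative circle exclusion
place_centres <- function(n, size, radius, margin, min_gap, max_tries) {
  centres <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centres) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- runif(2, margin, size - margin)
    if (nrow(centres) == 0 ||
        all(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) >=
              2 * radius + min_gap)) {
      centres <- rbind(centres, cand)
    }
  }
  if (nrow(centres) < n)
    abort(sprintf(
      "could only place %d of %d cells at this density; reduce n_cells or increase size",
      nrow(centres), n))
  centres
}

# variant with a per-site exclusion radius (large myotubes, small nuclei)
place_centres_var <- function(radii, size, min_gap, max_tries) {
  n <- length(radii)
  centres <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n && tries < max_tries) {
    tries <- tries + 1
    i <- placed + 1
    m <- radii[i] + 2
    cand <- runif(2, m, size - m)
    ok <- TRUE
    if (placed > 0) {
      d <- sqrt((centres[seq_len(placed), 1] - cand[1])^2 +
                  (centres[seq_len(placed), 2] - cand[2])^2)
      ok <- all(d >= radii[seq_len(placed)] + radii[i] + min_gap)
    }
    if (ok) {
      centres[i, ] <- cand
      placed <- placed + 1
    }
  }
  if (placed < n)
    abort(sprintf(
      "could only place %d of %d objects at this density; reduce the count or increase size",
      placed, n))
  centres
}

#' Synthetic brightfield scene of spindle-shaped cells
#'
#' Renders `n_cells` non-overlapping rotated ellipses (bright body, darker
#' rim, emulating brightfield myoblasts) on a textured mid-grey background
#' and returns the image together with its exact ground truth. The body
#' half-width is kept under the default line-enhancement radius so the
#' segmentation chain sees the cells as thin bright ridges.
#'
#' @param n_cells Number of cells (>= 0).
#' @param size Image side in px (>= 64); the default matches a 960 x 960 px
#'   field of view.
#' @param elongation Major/minor semi-axis ratio of the cells.
#' @param noise_sd Standard deviation of the smoothed background texture,
#'   in intensity units.
#' @param seed Optional integer seed; a fixed seed makes the scene
#'   bit-reproducible.
#' @param semi_major Range of the major semi-axis, px.
#' @return A list of class `cell_scene`: `image` (matrix in \[0, 1\]),
#'   `truth_mask` (integer label mask of the cell bodies) and
#'   `truth_params` (tibble: label, row, col, a, b, theta).
#' @export
make_cell_scene <- function(n_cells, size = 960, elongation = 3,
                            noise_sd = 0.02, seed = NULL,
                            semi_major = c(16, 21)) {
  stopifnot(n_cells >= 0, size >= 64, elongation >= 1, noise_sd >= 0)
  with_seed(seed, {
    image <- matrix(0.5, size, size)
    if (noise_sd > 0) {
      tex <- matrix(rnorm(size * size), size, size)
      tex <- EBImage::gblur(tex, sigma = 2)
      tex <- matrix(as.numeric(tex), size, size)
      image <- image + tex * (noise_sd / max(sd(as.numeric(tex)), 1e-12))
    }
    mask <- matrix(0L, size, size)
    params <- tibble(label = integer(), row = numeric(), col = numeric(),
                     a = numeric(), b = numeric(), theta = numeric())
    if (n_cells > 0) {
      a_max <- max(semi_major)
      centres <- place_centres(n_cells, size, radius = a_max, margin = a_max + 4,
                               min_gap = 8, max_tries = 400 * n_cells + 400)
      for (i in seq_len(n_cells)) {
        a <- runif(1, semi_major[1], semi_major[2])
        b <- a / elongation
        theta <- runif(1, 0, pi)
        painted <- paint_cell(image, mask, i, centres[i, 1], centres[i, 2],
                              a, b, theta)
        image <- painted$image
        mask <- painted$mask
        params <- bind_rows(params, tibble(
          label = i, row = centres[i, 1], col = centres[i, 2],
          a = a, b = b, theta = theta))
      }
    }
    image <- pmin(pmax(image, 0), 1)
    structure(list(image = image, truth_mask = mask, truth_params = params),
              class = "cell_scene")
  })
}

#' Synthetic time-lapse from a base scene
#'
#' Each cell performs a persistent-identity random walk (step direction
#' uniform, step length close to `step_px`) across `n_frames` frames,
#' emulating frames acquired every few minutes; cells reflect off the image
#' margins. Every frame is re-rendered with the same cell geometry so the
#' truth masks stay exact.
#'
#' @param scene A [make_cell_scene()] scene (frame 1 of the sequence).
#' @param n_frames Number of frames (>= 2).
#' @param step_px Mean per-frame step length in px (0 freezes the scene).
#' @param seed Optional integer seed.
#' @return A list of class `timelapse`: `frames` (list of `cell_scene`) and
#'   `truth_tracks` (tibble: frame, label, row, col).
#' @export
make_timelapse <- function(scene, n_frames, step_px, seed = NULL) {
  stopifnot(inherits(scene, "cell_scene"), n_frames >= 2, step_px >= 0)
  with_seed(seed, {
    size <- nrow(scene$image)
    params <- scene$truth_params
    margin <- if (nrow(params)) max(params$a) + 4 else 8
    frames <- vector("list", n_frames)
    frames[[1]] <- scene
    tracks <- params |>
      mutate(frame = 1L, .before = 1) |>
      select("frame", "label", "row", "col")
    cur <- params
    for (f in seq_len(n_frames)[-1]) {
      if (nrow(cur) && step_px > 0) {
        ang <- runif(nrow(cur), 0, 2 * pi)
        len <- abs(rnorm(nrow(cur), mean = step_px, sd = 0.1 * step_px))
        cur$row <- cur$row + len * sin(ang)
        cur$col <- cur$col + len * cos(ang)
        # reflect at the margins so cells stay in the field
        reflect <- function(x) {
          x <- abs(x - margin) + margin
          hi <- size - margin
          hi - abs(hi - x)
        }
        cur$row <- reflect(cur$row)
        cur$col <- reflect(cur$col)
      }
      image <- matrix(0.5, size, size)
      if (any(scene$image != 0.5)) {
        # fresh low-amplitude texture per frame
        tex <- matrix(rnorm(size * size), size, size)
        tex <- matrix(as.numeric(EBImage::gblur(tex, sigma = 2)), size, size)
        image <- image + tex * (0.02 / max(sd(as.numeric(tex)), 1e-12))
      }
      mask <- matrix(0L, size, size)
      if (nrow(cur)) {
        for (i in seq_len(nrow(cur))) {
          painted <- paint_cell(image, mask, cur$label[i], cur$row[i],
                                cur$col[i], cur$a[i], cur$b[i], cur$theta[i])
          image <- painted$image
          mask <- painted$mask
        }
      }
      frames[[f]] <- structure(
        list(image = pmin(pmax(image, 0), 1), truth_mask = mask,
             truth_params = cur),
        class = "cell_scene")
      tracks <- bind_rows(tracks, cur |>
                            mutate(frame = as.integer(f), .before = 1) |>
                            select("frame", "label", "row", "col"))
    }
    structure(list(frames = frames, truth_tracks = tracks),
              class = "timelapse")
  })
}

#' Synthetic three-channel fluorescence scene
#'
#' Builds a DAPI/MHC/CD56-like scene: a fraction `fusion_fraction` of the
#' nuclei are grouped into multinucleated MHC-positive myotubes (2-4 nuclei
#' each), the rest sit in mononucleated MHC-positive cells or on bare
#' background. The ground-truth fusion index is `round(fusion_fraction *
#' n_nuclei) / n_nuclei` exactly by construction. Each MHC-positive cell
#' carries its own mean CD56 (red) intensity.
#'
#' @param n_nuclei Total number of nuclei (>= 1).
#' @param fusion_fraction Target fraction of nuclei inside myotubes, in
#'   \[0, 1\].
#' @param seed Optional integer seed.
#' @param size Image side in px.
#' @return A list of class `fluorescence_scene` with `blue`, `green`, `red`
#'   intensity matrices, `truth_nuclei` (tibble: nucleus, row, col,
#'   myotube (NA = not in a myotube), cell, cd56), `nuclei_mask`,
#'   `mhc_mask`, and `truth_fusion_index`.
#' @export
make_fluorescence_scene <- function(n_nuclei, fusion_fraction, seed = NULL,
                                    size = 512) {
  stopifnot(n_nuclei >= 1)
  if (fusion_fraction < 0 || fusion_fraction > 1)
    abort("fusion_fraction must be in [0, 1].")
  with_seed(seed, {
    n_fused <- round(fusion_fraction * n_nuclei)
    if (n_fused == 1) n_fused <- 2  # a myotube needs at least 2 nuclei
    # partition fused nuclei into myotubes of 2-4 nuclei
    sizes <- integer(0); left <- n_fused
    while (left > 0) {
      s <- if (left <= 4) left else sample(2:4, 1)
      if (left - s == 1) s <- s + 1
      sizes <- c(sizes, s); left <- left - s
    }
    n_mono <- n_nuclei - sum(sizes)

    nuc_r <- 5
    blue <- matrix(0.05, size, size)
    green <- matrix(0.05, size, size)
    red <- matrix(0.05, size, size)
    nuclei_mask <- matrix(0L, size, size)
    mhc <- matrix(FALSE, size, size)
    truth <- tibble(nucleus = integer(), row = numeric(), col = numeric(),
                    myotube = integer(), cell = integer(), cd56 = numeric())

    # background singles: half of the mono nuclei sit outside MHC regions
    n_bg <- floor(n_mono / 2)
    site_radii <- c(14 * sizes + 6,                       # myotube half-length
                    rep(18, n_mono - n_bg),               # mononucleated cells
                    rep(nuc_r + 2, n_bg))                 # bare nuclei
    centres <- place_centres_var(site_radii, size, min_gap = 10,
                                 max_tries = 800 * length(site_radii) + 800)
    paint_region <- function(chan, r0, c0, a, b, theta, value) {
      ext <- ceiling(a + 1)
      rs <- max(1, floor(r0 - ext)):min(size, ceiling(r0 + ext))
      cs <- max(1, floor(c0 - ext)):min(size, ceiling(c0 + ext))
      gr <- matrix(rs, length(rs), length(cs))
      gc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
      sel <- ellipse_metric(gr, gc, r0, c0, a, b, theta) <= 1
      sub <- chan[rs, cs]; sub[sel] <- value; chan[rs, cs] <- sub
      chan
    }
    nuc_id <- 0L; cell_id <- 0L; myo_id <- 0L
    add_nucleus <- function(r0, c0, myotube, cell, cd56) {
      nuc_id <<- nuc_id + 1L
      blue <<- paint_region(blue, r0, c0, nuc_r, nuc_r, 0, 0.9)
      nuclei_mask <<- {
        m <- nuclei_mask
        ext <- nuc_r + 1
        rs <- max(1, floor(r0 - ext)):min(size, ceiling(r0 + ext))
        cs <- max(1, floor(c0 - ext)):min(size, ceiling(c0 + ext))
        gr <- matrix(rs, length(rs), length(cs))
        gc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
        sel <- (gr - r0)^2 + (gc - c0)^2 <= nuc_r^2
        sub <- m[rs, cs]; sub[sel] <- nuc_id; m[rs, cs] <- sub
        m
      }
      truth <<- bind_rows(truth, tibble(
        nucleus = nuc_id, row = r0, col = c0,
        myotube = myotube %||% NA_integer_, cell = cell, cd56 = cd56))
    }

    site <- 0L
    for (s in sizes) {            # myotubes: elongated green regions
      site <- site + 1L
      r0 <- centres[site, 1]; c0 <- centres[site, 2]
      theta <- runif(1, 0, pi)
      a <- 14 * s + 6; b <- 14
      myo_id <- myo_id + 1L; cell_id <- cell_id + 1L
      cd56 <- runif(1, 0.3, 0.9)
      green <- paint_region(green, r0, c0, a, b, theta, 0.7)
      red <- paint_region(red, r0, c0, a, b, theta, cd56)
      offs <- seq(-(s - 1) / 2, (s - 1) / 2) * 2.6 * nuc_r
      for (o in offs)
        add_nucleus(r0 + o * sin(theta), c0 + o * cos(theta),
                    myo_id, cell_id, cd56)
    }
    for (i in seq_len(n_mono)) {  # mononucleated cells / background nuclei
      site <- site + 1L
      r0 <- centres[site, 1]; c0 <- centres[site, 2]
      if (i <= n_mono - n_bg) {
        theta <- runif(1, 0, pi)
        cell_id <- cell_id + 1L
        cd56 <- runif(1, 0.3, 0.9)
        green <- paint_region(green, r0, c0, 16, 10, theta, 0.7)
        red <- paint_region(red, r0, c0, 16, 10, theta, cd56)
        add_nucleus(r0, c0, NA_integer_, cell_id, cd56)
      } else {
        add_nucleus(r0, c0, NA_integer_, NA_integer_, NA_real_)
      }
    }
    mhc <- green > 0.3
    structure(list(
      blue = blue, green = green, red = red,
      truth_nuclei = truth, nuclei_mask = nuclei_mask, mhc_mask = mhc,
      truth_fusion_index = sum(!is.na(truth$myotube)) / nrow(truth)),
      class = "fluorescence_scene")
  })
}

#' Synthetic beta-galactosidase colour field
#'
#' Renders `n_cells` round cells on a near-white field; a chosen number are
#' stained in a blue hue band (senescence-positive), the rest grey. The
#' truth fraction is exact.
#'
#' @param n_cells Number of cells (>= 1).
#' @param positive_fraction Fraction of positive (blue) cells, in \[0, 1\];
#'   the realised count is `round(positive_fraction * n_cells)`.
#' @param seed Optional integer seed.
#' @param size Image side in px.
#' @return A list of class `bgal_scene`: `rgb` (size x size x 3 array),
#'   `cells` (label mask), `truth` (tibble: label, positive) and
#'   `truth_fraction`.
#' @export
make_bgal_scene <- function(n_cells, positive_fraction, seed = NULL,
                            size = 512) {
  stopifnot(n_cells >= 1)
  if (positive_fraction < 0 || positive_fraction > 1)
    abort("positive_fraction must be in [0, 1].")
  with_seed(seed, {
    n_pos <- round(positive_fraction * n_cells)
    centres <- place_centres(n_cells, size, radius = 12, margin = 16,
                             min_gap = 6, max_tries = 600 * n_cells + 600)
    rgb_arr <- array(0.9, dim = c(size, size, 3))
    cells <- matrix(0L, size, size)
    positive <- c(rep(TRUE, n_pos), rep(FALSE, n_cells - n_pos))
    for (i in seq_len(n_cells)) {
      r0 <- centres[i, 1]; c0 <- centres[i, 2]
      colour <- if (positive[i]) c(0.25, 0.35, 0.75) else c(0.55, 0.55, 0.55)
      rad <- runif(1, 8, 12)
      rs <- max(1, floor(r0 - rad - 1)):min(size, ceiling(r0 + rad + 1))
      cs <- max(1, floor(c0 - rad - 1)):min(size, ceiling(c0 + rad + 1))
      gr <- matrix(rs, length(rs), length(cs))
      gc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
      sel <- (gr - r0)^2 + (gc - c0)^2 <= rad^2
      for (ch in 1:3) {
        sub <- rgb_arr[rs, cs, ch]; sub[sel] <- colour[ch]
        rgb_arr[rs, cs, ch] <- sub
      }
      sub <- cells[rs, cs]; sub[sel] <- i; cells[rs, cs] <- sub
    }
    structure(list(
      rgb = rgb_arr, cells = cells,
      truth = tibble(label = seq_len(n_cells), positive = positive),
      truth_fraction = n_pos / n_cells),
      class = "bgal_scene")
  })
}

#' Synthetic enzyme-assay OD plate
#'
#' Emulates a colorimetric acetylcholinesterase readout: seven 1:3 serially
#' diluted standards from 1000 mU/mL, duplicate wells per sample, and a
#' blank well, with ODs equal to blank + `curve_shape`(conc) + noise.
#'
#' @param sample_concs True sample concentrations in mU/mL (non-negative).
#' @param curve_shape Monotone map from concentration to blank-corrected
#'   OD; the default is a saturating binding curve `1.8 * c / (c + 150)`.
#' @param noise_sd OD noise standard deviation.
#' @param seed Optional integer seed.
#' @param blank Blank OD.
#' @return A list of class `od_plate`: `standards` (tibble: conc, od),
#'   `samples` (tibble: sample, replicate, od, true_conc) and `blank`.
#' @export
make_od_plate <- function(sample_concs, curve_shape = NULL, noise_sd = 0.01,
                          seed = NULL, blank = 0.05) {
  if (any(sample_concs < 0)) abort("concentrations must be non-negative.")
  stopifnot(noise_sd >= 0)
  if (is.null(curve_shape)) curve_shape <- function(conc) 1.8 * conc / (conc + 150)
  with_seed(seed, {
    concs <- serial_dilution(1000, 3, 7)
    std_od <- blank + curve_shape(concs) + rnorm(length(concs), 0, noise_sd)
    n <- length(sample_concs)
    samp <- tibble(
      sample = rep(seq_len(n), each = 2),
      replicate = rep(1:2, n),
      od = blank + curve_shape(rep(sample_concs, each = 2)) +
        rnorm(2 * n, 0, noise_sd),
      true_conc = rep(sample_concs, each = 2)
    )
    structure(list(standards = tibble(conc = concs, od = std_od),
                   samples = samp, blank = blank),
              class = "od_plate")
  })
}
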