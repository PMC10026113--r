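#' Specification for a synthetic donor cohort
#'
#' The defaults describe a cohort like the reference one: 14 donors aged
#' 16-92 (uniform), a fusion index declining by 0.005 per year of age from
#' an intercept of 0.85, and donor-level noise of 0.1 fusion-index units
#' (clipped to \[0, 1\]).
#'
#' @param n_donors Number of donors (>= 3).
#' @param age_range Age range in years (uniform sampling).
#' @param fi_intercept Fusion index at age 0 in the linear model.
#' @param fi_age_slope Fusion-index change per year of age.
#' @param noise_sd SD of the donor-level fusion-index noise.
#' @param seed Optional integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 14, age_range = c(16, 92),
                        fi_intercept = 0.85, fi_age_slope = -0.005,
                        noise_sd = 0.1, seed = NULL) {
  if (n_donors < 3) abort("`n_donors` must be >= 3.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(n_donors = n_donors, age_range = age_range,
                 fi_intercept = fi_intercept, fi_age_slope = fi_age_slope,
                 noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic donor cohort
#'
#' Builds a donor table with the reference cohort's column layout:
#' demographics, lifestyle flags, marker percentages, assay readouts, the
#' fusion index, and per-image shape-descriptor means for two imaging
#' timepoints (12 h, 24 h) and two passages (P2, P3). Built-in couplings:
#' the fusion index is linear in age plus noise (clipped to \[0, 1\]), the
#' senescence fraction increases with age, CD34 decreases with the fusion
#' index, and the descriptors named in `descriptor_coupling` co-vary with
#' the fusion index with the given sign/strength, so correlation screens
#' have a known answer.
#'
#' @param spec A [cohort_spec()].
#' @param descriptor_coupling Named numeric vector of couplings (in units
#'   of descriptor SD per fusion-index SD) for descriptor columns;
#'   descriptors not named get 0. The default couples the area-type
#'   descriptors negatively, emulating the observation that large early
#'   cell footprints predict poor myogenicity.
#' @param descriptor_noise_sd Residual descriptor noise (SD units).
#' @return A tibble with one row per donor.
#' @export
make_cohort <- function(spec = cohort_spec(),
                        descriptor_coupling = c(
                          total_area_occupied = -0.9, area_shape = -0.9,
                          bounding_box_area = -0.9, min_feret_diameter = -0.9,
                          minor_axis_length = -0.9),
                        descriptor_noise_sd = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_donors
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    fi_lin <- spec$fi_intercept + spec$fi_age_slope * age +
      rnorm(n, 0, spec$noise_sd)
    fi <- pmin(pmax(fi_lin, 0), 1)
    sexes <- sample(c("M", "F"), n, replace = TRUE)
    cohort <- tibble(
      Donor = sprintf("D%02d", seq_len(n)),
      Age = age,
      Sex = sexes,
      Ethnicity = sample(c("Caucasian", "African American"), n, TRUE,
                         prob = c(0.9, 0.1)),
      Tissue = sample(c("AR", "VL"), n, TRUE, prob = c(0.8, 0.2)),
      Diabetes = 0L,
      BMI = round(runif(n, 20, 47)),
      Tobacco = as.integer(runif(n) < 0.5),
      Alcohol = as.integer(runif(n) < 0.4),
      DrugUse = as.integer(runif(n) < 0.4),
      FusionIndex = fi,
      CD56 = pmin(pmax(40 + 20 * fi + rnorm(n, 0, 12), 0), 100),
      CD34 = pmin(pmax(25 - 25 * fi + rnorm(n, 0, 6), 0), 100),
      CD90 = pmin(pmax(95 + rnorm(n, 0, 6), 0), 100),
      BGal = pmin(pmax(5 + 0.5 * age + rnorm(n, 0, 8), 0), 100),
      AChE = exp(rnorm(n, log(50), 0.5))
    )
    fi_z <- if (sd(fi) > 0) (fi - mean(fi)) / sd(fi) else rep(0, n)
    base <- c(
      total_area_occupied = 60000, area_shape = 380, bounding_box_area = 900,
      compactness = 1.6, eccentricity = 0.92, equivalent_diameter = 21,
      extent = 0.45, form_factor = 0.35, major_axis_length = 38,
      max_feret_diameter = 40, maximum_radius = 6, mean_radius = 3,
      median_radius = 3, min_feret_diameter = 12, minor_axis_length = 13,
      perimeter = 95, solidity = 0.9, first_closest_distance = 90,
      second_closest_distance = 130
    )
    for (d in shape_descriptor_names()) {
      coup <- if (d %in% names(descriptor_coupling)) descriptor_coupling[[d]] else 0
      for (tp in c("12h", "24h")) for (pa in c("P2", "P3")) {
        noise <- rnorm(n, 0, descriptor_noise_sd)
        val <- base[[d]] * (1 + 0.15 * (coup * fi_z + noise))
        cohort[[paste(d, tp, pa, sep = "_")]] <- val
      }
    }
    cohort
  })
}

#' The 14-donor reference cohort
#'
#' Loads the donor table shipped with the package: demographics, lifestyle
#' flags and the day-5 fusion index (3-decimal values, with CD56 surface
#' expression) for the 14 muscle-biopsy donors used throughout the
#' documentation and tests.
#'
#' @return A tibble with columns `Age`, `Sex`, `Ethnicity`, `Catalogue`,
#'   `Tissue`, `Diabetes`, `BMI`, `Tobacco`, `Alcohol`, `DrugUse`,
#'   `FusionIndex`, `CD56`.
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "donor_cohort.csv", package = "myoshape")
  readr::read_csv(path, show_col_types = FALSE)
}
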