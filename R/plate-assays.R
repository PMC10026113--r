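#' Serial dilution series
#'
#' @param start Starting concentration (mU/mL).
#' @param factor Dilution factor per step (> 1).
#' @param n Number of members (>= 1).
#' @return Numeric vector `start / factor^(0:(n-1))`, descending. A 1:3
#'   series of 7 from 1000 mU/mL ends at 1000/3^6 ~ 1.37 mU/mL.
#' @export
serial_dilution <- function(start, factor = 3, n = 7) {
  if (!is.numeric(start) || start <= 0) abort("`start` must be positive.")
  if (factor <= 1) abort("`factor` must be > 1.")
  if (n < 1) abort("`n` must be >= 1.")
  start / factor^(seq_len(n) - 1)
}

#' Fit a standard curve from serially diluted standards
#'
#' Subtracts the blank from the standard ODs, enforces monotonicity in
#' concentration (isotonic adjustment with a warning if the noisy readings
#' violate it) and stores a piecewise-linear OD-to-concentration map on
#' log10 concentration — the usual plate-reader treatment for a
#' serial-dilution calibration.
#'
#' @param concs Standard concentrations (mU/mL, > 0), any order.
#' @param ods Raw ODs of the standards.
#' @param blank Blank OD subtracted from every reading.
#' @return An object of class `standard_curve`.
#' @seealso [interpolate_samples()], [make_od_plate()]
#' @export
fit_standard_curve <- function(concs, ods, blank = 0) {
  if (length(concs) != length(ods)) abort("`concs` and `ods` lengths differ.")
  if (length(concs) < 2) abort("at least 2 standards are required.")
  if (any(concs <= 0)) abort("standard concentrations must be positive.")
  ord <- order(concs)
  concs <- concs[ord]
  od_corr <- ods[ord] - blank
  if (any(diff(od_corr) < 0)) {
    warn("standard ODs are not monotone in concentration; applying isotonic adjustment.")
    od_corr <- isoreg(log10(concs), od_corr)$yf
  }
  structure(
    list(standard_concs = rev(concs),      # descending, as pipetted
         standard_ods = rev(od_corr),
         knots = tibble(log_conc = log10(concs), od = od_corr),
         blank = blank),
    class = "standard_curve"
  )
}

#' Interpolate sample concentrations from a standard curve
#'
#' Duplicate wells of a sample are averaged before inversion. Corrected ODs
#' outside the standards' OD range are flagged (`"below_range"` /
#' `"above_range"`) and never extrapolated.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param samples A data frame with columns `sample` and `od` (raw ODs; the
#'   curve's blank is subtracted here), or a bare numeric vector of ODs
#'   treated as one well per sample.
#' @return A tibble with one row per sample: `sample`, `od` (mean corrected
#'   OD), `conc` (mU/mL, `NA` when out of range) and `flag`
#'   (`"ok"`, `"below_range"` or `"above_range"`).
#' @export
interpolate_samples <- function(curve, samples) {
  stopifnot(inherits(curve, "standard_curve"))
  if (is.numeric(samples))
    samples <- tibble(sample = seq_along(samples), od = samples)
  if (!all(c("sample", "od") %in% names(samples)))
    abort("`samples` needs `sample` and `od` columns.")
  if (nrow(samples) == 0) abort("no sample wells supplied.")
  kn <- curve$knots
  lo <- min(kn$od); hi <- max(kn$od)
  samples |>
    group_by(.data$sample) |>
    summarise(od = mean(.data$od - curve$blank), .groups = "drop") |>
    mutate(
      flag = case_when(.data$od < lo ~ "below_range",
                       .data$od > hi ~ "above_range",
                       TRUE ~ "ok"),
      conc = ifelse(.data$flag == "ok",
                    10^approx(kn$od, kn$log_conc, xout = .data$od,
                              ties = mean)$y,
                    NA_real_)
    ) |>
    select("sample", "od", "conc", "flag")
}

#' @export
tidy.standard_curve <- function(x, ...) x$knots

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(n_standards = nrow(x$knots), blank = x$blank,
         od_min = min(x$knots$od), od_max = max(x$knots$od),
         conc_min = min(x$standard_concs), conc_max = max(x$standard_concs))
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %d standards, %g-%g mU/mL, blank %g\n",
              nrow(x$knots), min(x$standard_concs), max(x$standard_concs),
              x$blank))
  invisible(x)
}
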