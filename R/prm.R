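#' Monoisotopic residue and constant masses
#'
#' Standard amino-acid residue monoisotopic masses (Da), plus the proton and
#' water masses used in fragment-ion arithmetic.
#'
#' @format Named numeric vector of 20 residue masses.
#' @export
residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, E = 129.04259, K = 128.09496, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276466622
WATER_MASS <- 18.0105646863
AVOGADRO <- 6.02214076e23

#' Named modification mass offsets
#'
#' Exact monoisotopic mass offsets (Da) for the modifications handled by the
#' fragment tools, including the heavy-lysine SILAC-style label used for PRM
#' internal standards. A heavy label is always a mass offset on a named
#' residue position, never a sequence change.
#'
#' @format Named numeric vector.
#' @export
modification_masses <- c(
  "Label:13C(6)15N(2)" = 8.01419876,
  "Oxidation" = 15.9949146,
  "Deamidation" = 0.9840156,
  "Acetyl" = 42.0105646,
  "Cysteinylation" = 119.0040990,
  "Phospho" = 79.9663305
)

mod_offsets <- function(mods, n) {
  offsets <- numeric(n)
  if (is.null(mods) || length(mods) == 0) return(offsets)
  if (is.character(mods)) mods <- parse_modifications(mods)
  check_columns(mods, c("name", "position"), "modification table")
  for (i in seq_len(nrow(mods))) {
    m <- modification_masses[mods$name[i]]
    if (is.na(m)) abort(paste0("unknown modification: ", mods$name[i]))
    if (mods$position[i] < 1 || mods$position[i] > n) {
      abort("modification position outside peptide")
    }
    offsets[mods$position[i]] <- offsets[mods$position[i]] + m
  }
  offsets
}

#' Theoretical b/y fragment ion m/z values
#'
#' Computes singly-charged (by default) b- and y-series fragment m/z values
#' from monoisotopic residue masses: `b_i` is the summed mass of residues
#' `1..i` plus the proton(s); `y_i` adds water for the C-terminal fragment.
#' Fixed modifications (including heavy isotope labels) are applied as exact
#' mass offsets at their annotated positions.
#'
#' @param peptide Uppercase amino-acid sequence.
#' @param mods Optional modifications: a `name@pos;name@pos` string or a
#'   tibble with columns `name`, `position`. Names must appear in
#'   [modification_masses].
#' @param series Which ion series to compute, subset of `c("b", "y")`.
#' @param charge Positive integer charge state.
#' @return Tibble with columns `ion`, `series`, `index`, `mz`, ordered by
#'   series then index; indices run 1 to `nchar(peptide) - 1`.
#' @export
theoretical_fragments <- function(peptide, mods = NULL, series = c("b", "y"),
                                  charge = 1) {
  peptide <- toupper(peptide)
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  if (n < 2) abort("peptide must have at least 2 residues")
  if (any(!aa %in% names(residue_masses))) {
    abort(paste0("unknown residue in peptide: ", peptide))
  }
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  masses <- unname(residue_masses[aa]) + mod_offsets(mods, n)

  out <- list()
  idx <- seq_len(n - 1)
  if ("b" %in% series) {
    neutral <- cumsum(masses)[idx]
    out$b <- tibble::tibble(
      ion = paste0("b", idx), series = "b", index = idx,
      mz = (neutral + charge * PROTON_MASS) / charge
    )
  }
  if ("y" %in% series) {
    neutral <- cumsum(rev(masses))[idx] + WATER_MASS
    out$y <- tibble::tibble(
      ion = paste0("y", idx), series = "y", index = idx,
      mz = (neutral + charge * PROTON_MASS) / charge
    )
  }
  dplyr::bind_rows(out)
}

#' Fragment ions distinguishing two equal-length peptides
#'
#' Computes theoretical b/y series for two peptides of equal length (for
#' example an unmutated peptide and its single-substitution mutant) and
#' returns the ions whose m/z differ, with the mass shift. For a single
#' substitution every differing ion carries the same absolute shift — the
#' residue mass difference — and any of them (such as the b8 ion of a
#' position-7 variant 9-mer) discriminates the two forms in a spectrum.
#'
#' @param peptide_a,peptide_b Uppercase sequences of equal length.
#' @param mods_a,mods_b Optional modifications for each peptide (see
#'   [theoretical_fragments()]).
#' @param charge Charge state passed through.
#' @param tol Minimum m/z difference (Da) to report.
#' @return Tibble with `ion`, `series`, `index`, `mz_a`, `mz_b`, `delta_mz`
#'   (`mz_b - mz_a`).
#' @export
distinguishing_ions <- function(peptide_a, peptide_b, mods_a = NULL,
                                mods_b = NULL, charge = 1, tol = 1e-6) {
  if (nchar(peptide_a) != nchar(peptide_b)) {
    abort("peptides must have equal length")
  }
  fa <- theoretical_fragments(peptide_a, mods_a, charge = charge)
  fb <- theoretical_fragments(peptide_b, mods_b, charge = charge)
  joined <- dplyr::inner_join(
    dplyr::rename(fa, mz_a = "mz"),
    dplyr::select(dplyr::rename(fb, mz_b = "mz"), "series", "index", "mz_b"),
    by = c("series", "index")
  )
  joined$delta_mz <- joined$mz_b - joined$mz_a
  dplyr::filter(joined, abs(.data$delta_mz) > tol)
}

#' Fit a light/heavy PRM standard curve
#'
#' Ordinary least-squares fit of the measured light/heavy ratio against the
#' spiked light amount (fmol), as used to calibrate absolute quantitation of
#' endogenous MHC peptides against a constant heavy internal standard.
#' A weighted `1/x` fit (weights proportional to `1/fmol`, zero-amount point
#' weighted as the smallest nonzero amount) is available for
#' heteroscedastic series.
#'
#' @param points Tibble with columns `fmol` (spiked light amount) and
#'   `ratio` (measured light/heavy ratio); at least 3 points.
#' @param peptide Optional peptide label carried into the result.
#' @param weighted If `TRUE`, weight points by `1/fmol`.
#' @return Object of class `radpep_calcurve`: slope (ratio per fmol),
#'   intercept, `r_squared`, `valid_range`, and the fitted points. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
fit_standard_curve <- function(points, peptide = NULL, weighted = FALSE) {
  check_columns(points, c("fmol", "ratio"), "calibration table")
  points <- dplyr::filter(points, !is.na(.data$fmol), !is.na(.data$ratio))
  if (nrow(points) < 3) abort("calibration requires at least 3 points")
  if (var(points$fmol) == 0) abort("calibration amounts have zero variance")
  if (var(points$ratio) == 0) {
    abort("degenerate calibration: all ratios equal (zero slope)")
  }
  w <- NULL
  if (weighted) {
    x <- points$fmol
    x[x == 0] <- min(x[x > 0])
    w <- 1 / x
  }
  fit <- lm(ratio ~ fmol, data = points, weights = w)
  fit_summary <- suppressWarnings(summary(fit))
  res_sd <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  intercept <- unname(stats::coef(fit)[1])
  if (abs(intercept) > 1e-8 && abs(intercept) > 2 * res_sd) {
    warn(sprintf(
      "calibration intercept %.4g exceeds twice the residual SD (%.4g)",
      intercept, res_sd
    ))
  }
  structure(
    list(
      peptide = peptide,
      slope = unname(stats::coef(fit)[2]),
      intercept = intercept,
      slope_se = fit_summary$coefficients["fmol", "Std. Error"],
      r_squared = fit_summary$r.squared,
      valid_range = range(points$fmol),
      points = dplyr::mutate(points, fitted = stats::fitted(fit)),
      weighted = weighted
    ),
    class = "radpep_calcurve"
  )
}

#' @export
print.radpep_calcurve <- function(x, ...) {
  cat(sprintf(
    "PRM standard curve%s: ratio = %.5g + %.5g * fmol (r^2 = %.4f, %d points, %g-%g fmol)\n",
    if (is.null(x$peptide)) "" else paste0(" for ", x$peptide),
    x$intercept, x$slope, x$r_squared, nrow(x$points),
    x$valid_range[1], x$valid_range[2]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.radpep_calcurve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se)
  )
}

#' @exportS3Method generics::glance
glance.radpep_calcurve <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
    n = nrow(x$points), fmol_min = x$valid_range[1], fmol_max = x$valid_range[2]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.radpep_calcurve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fmol, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "light peptide spiked (fmol)", y = "light/heavy ratio",
      title = if (is.null(object$peptide)) "PRM standard curve"
              else paste("PRM standard curve:", object$peptide),
      subtitle = sprintf("slope = %.4g / fmol, r² = %.4f",
                         object$slope, object$r_squared)
    )
}

#' Back-calculate endogenous peptide amounts from light/heavy ratios
#'
#' Inverts a fitted standard curve: `endogenous = (ratio - intercept)/slope`.
#' Ratios mapping outside the calibrated amount range are flagged as
#' extrapolated (boundary values are within range).
#'
#' @param samples Tibble with a `ratio` column (other columns carried
#'   through), or a bare numeric vector of ratios.
#' @param curve A `radpep_calcurve` from [fit_standard_curve()].
#' @param heavy_spike_fmol Amount of heavy standard spiked into samples and
#'   standards (fmol); recorded in the output for provenance.
#' @return Input tibble with `endogenous_fmol`, `extrapolated` and
#'   `heavy_spike_fmol` columns appended.
#' @export
quantify_endogenous <- function(samples, curve, heavy_spike_fmol = 100) {
  if (is.numeric(samples)) samples <- tibble::tibble(ratio = samples)
  check_columns(samples, "ratio", "ratio table")
  stopifnot(inherits(curve, "radpep_calcurve"))
  fmol <- (samples$ratio - curve$intercept) / curve$slope
  dplyr::mutate(
    samples,
    endogenous_fmol = fmol,
    extrapolated = fmol < curve$valid_range[1] | fmol > curve$valid_range[2],
    heavy_spike_fmol = heavy_spike_fmol
  )
}

#' Convert femtomoles of peptide to copies per cell
#'
#' `copies = fmol * 1e-15 * N_A / n_cells` with Avogadro's number fixed at
#' the exact SI value 6.02214076e23, assuming complete MHC peptide recovery
#' from the input cells.
#'
#' @param samples Tibble with an `endogenous_fmol` column (e.g. from
#'   [quantify_endogenous()]), or a bare numeric vector of fmol amounts.
#' @param n_cells Number of input cells the amount was recovered from.
#' @return Input tibble with `n_cells`, `copies_per_cell` (unrounded) and
#'   `copies_per_cell_rounded` appended.
#' @export
copies_per_cell <- function(samples, n_cells) {
  if (is.numeric(samples)) samples <- tibble::tibble(endogenous_fmol = samples)
  check_columns(samples, "endogenous_fmol", "quantified sample table")
  if (any(n_cells <= 0)) abort("n_cells must be positive")
  copies <- samples$endogenous_fmol * 1e-15 * AVOGADRO / n_cells
  dplyr::mutate(
    samples,
    n_cells = n_cells,
    copies_per_cell = copies,
    copies_per_cell_rounded = round(copies)
  )
}
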