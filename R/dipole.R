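#' Dual-excitation calibration for di-8-ANEPPS ratiometry
#'
#' Linear mapping between the excitation ratio R = I420/I520 and the
#' membrane dipole potential: phi_d (mV) = (R + a) / b. Only the slope `b`
#' matters for potential differences; the intercept `a` shifts the absolute
#' scale, which is convention-dependent.
#'
#' @param intercept_a Dimensionless intercept. Default 0.3.
#' @param slope_b Slope in 1/mV; must be non-zero. Default 0.0043.
#' @return An object of class `dipole_calibration`.
#' @export
dipole_calibration <- function(intercept_a = 0.3, slope_b = 0.0043) {
  stopifnot(is.finite(intercept_a), is.finite(slope_b), slope_b != 0)
  structure(list(intercept_a = intercept_a, slope_b = slope_b),
            class = "dipole_calibration")
}

#' Fluorescence excitation ratio
#'
#' R = I420/I520 (both measured at 670 nm emission); the dual-wavelength
#' ratio compensates for fluidity-driven intensity changes.
#'
#' @param intensity_420,intensity_520 Fluorescence intensities (a.u.),
#'   strictly positive; vectorized.
#' @return Dimensionless ratio R.
#' @export
excitation_ratio <- function(intensity_420, intensity_520) {
  if (any(!is.finite(intensity_420)) || any(intensity_420 <= 0) ||
      any(!is.finite(intensity_520)) || any(intensity_520 <= 0))
    stop("fluorescence intensities must be finite and > 0")
  intensity_420 / intensity_520
}

#' Dipole potential from an excitation ratio
#'
#' @param R Excitation ratio, dimensionless.
#' @param cal A [dipole_calibration()].
#' @return Dipole potential in mV; strictly monotone in R.
#' @export
phi_d_from_ratio <- function(R, cal = dipole_calibration()) {
  (R + cal$intercept_a) / cal$slope_b
}

#' Dipole-potential titration curve from fluorescence pairs
#'
#' Converts replicate-resolved (I420, I520) pairs to dipole potentials and
#' returns the change relative to each replicate's zero-concentration
#' baseline, aggregated per concentration as mean, sd and n. The returned
#' curve has the same shape as a boundary-potential curve and can be passed
#' straight to [fit_langmuir_nonlinear()] to estimate the maximal
#' dipole-potential change and the desorption constant.
#'
#' @param points data.frame with columns `replicate`, `concentration_uM`,
#'   `I420`, `I520`; rows with `concentration_uM == 0` are the baselines.
#' @param cal A [dipole_calibration()].
#' @return A `boundary_potential_curve` in dipole-potential space.
#' @export
dipole_titration <- function(points, cal = dipole_calibration()) {
  stopifnot(is.data.frame(points),
            all(c("replicate", "concentration_uM", "I420", "I520") %in% names(points)))
  R <- excitation_ratio(points$I420, points$I520)
  phi <- phi_d_from_ratio(R, cal)

  base <- points$concentration_uM == 0
  base_phi <- tapply(phi[base], points$replicate[base], mean)
  pts <- !base
  if (!any(pts)) stop("need at least one point with concentration > 0")
  missing <- setdiff(as.character(unique(points$replicate[pts])), names(base_phi))
  if (length(missing))
    stop("missing baseline (C = 0) fluorescence for replicate(s): ",
         paste(missing, collapse = ", "))

  dphi <- phi[pts] - base_phi[as.character(points$replicate[pts])]
  agg <- aggregate_replicates(points$concentration_uM[pts], dphi)
  structure(agg, class = c("boundary_potential_curve", "data.frame"),
            space = "dipole")
}

#' Read a fluorescence titration CSV
#'
#' Header `replicate,concentration_uM,I420,I520`; baseline rows have
#' `concentration_uM = 0`.
#'
#' @param path File path.
#' @return data.frame suitable for [dipole_titration()].
#' @export
read_fluorescence_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "concentration_uM", "I420", "I520")
  if (!all(need %in% names(d)))
    stop("fluorescence CSV must have columns: ", paste(need, collapse = ", "))
  d
}
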