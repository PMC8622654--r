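#' Boundary-potential change from a conductance ratio
#'
#' Converts the ratio of carrier-mediated membrane conductance after and
#' before modifier addition (G/G0) to the change in membrane boundary
#' potential via the Boltzmann distribution of the lipophilic probe ion:
#' \deqn{\Delta\varphi_b = -\frac{kT}{ze}\,\ln(G/G_0)}
#' With a cationic probe (z = +1) a conductance increase maps to a negative
#' boundary-potential change (a potential decrease).
#'
#' @param g_ratio Conductance ratio G/G0, dimensionless, strictly positive.
#' @param cond [recording_conditions()] supplying the temperature.
#' @param charge [charge_spec()] supplying the probe valence.
#' @return Boundary-potential change in mV (signed), same length as `g_ratio`.
#' @seealso [conductance_ratio_from_delta_phi()] for the exact inverse.
#' @export
#' @examples
#' boltzmann_delta_phi(exp(1))         # -kT/e = -25.693 mV at 298.15 K
boltzmann_delta_phi <- function(g_ratio, cond = recording_conditions(),
                                charge = charge_spec()) {
  if (!is.numeric(g_ratio) || any(!is.finite(g_ratio)) || any(g_ratio <= 0)) {
    bad <- if (is.numeric(g_ratio)) g_ratio[!is.finite(g_ratio) | g_ratio <= 0][1] else g_ratio[1]
    stop("`g_ratio` must be finite and > 0; offending value: ", format(bad))
  }
  -thermal_voltage_mV(cond$temperature_K) / charge$z * log(g_ratio)
}

#' Conductance ratio from a boundary-potential change
#'
#' Exact algebraic inverse of [boltzmann_delta_phi()]:
#' G/G0 = exp(-ze * delta_phi / kT).
#'
#' @param delta_phi_mV Boundary-potential change in mV (finite).
#' @inheritParams boltzmann_delta_phi
#' @return Dimensionless conductance ratio.
#' @export
conductance_ratio_from_delta_phi <- function(delta_phi_mV,
                                             cond = recording_conditions(),
                                             charge = charge_spec()) {
  if (!is.numeric(delta_phi_mV) || any(!is.finite(delta_phi_mV)))
    stop("`delta_phi_mV` must be finite")
  exp(-charge$z * delta_phi_mV / thermal_voltage_mV(cond$temperature_K))
}

#' Build a boundary-potential titration curve from conductance data
#'
#' Takes replicate-resolved titration points (modifier concentration vs
#' membrane conductance) together with each replicate's baseline (zero
#' concentration) conductance, converts every point to a boundary-potential
#' change with [boltzmann_delta_phi()], and aggregates replicates per
#' concentration as mean, sd and n.
#'
#' @param points data.frame with columns `replicate`, `concentration_uM`,
#'   `conductance_nS`. Rows with `concentration_uM == 0` are treated as the
#'   baseline for their replicate unless `baseline_nS` is given.
#' @param baseline_nS Optional named numeric vector of baseline conductances
#'   per replicate (names = replicate ids). When `NULL`, baselines are taken
#'   from the zero-concentration rows of `points`.
#' @inheritParams boltzmann_delta_phi
#' @return A `boundary_potential_curve`: data.frame with columns
#'   `concentration_uM`, `delta_phi_mV`, `sd_mV`, `n`, sorted by
#'   concentration.
#' @export
build_titration_curve <- function(points, baseline_nS = NULL,
                                  cond = recording_conditions(),
                                  charge = charge_spec()) {
  stopifnot(is.data.frame(points),
            all(c("replicate", "concentration_uM", "conductance_nS") %in% names(points)))
  if (any(points$concentration_uM < 0)) stop("concentrations must be >= 0")
  if (any(!is.finite(points$conductance_nS) | points$conductance_nS <= 0))
    stop("conductances must be finite and > 0")

  if (is.null(baseline_nS)) {
    base_rows <- points[points$concentration_uM == 0, , drop = FALSE]
    baseline_nS <- tapply(base_rows$conductance_nS, base_rows$replicate, mean)
  }
  pts <- points[points$concentration_uM > 0, , drop = FALSE]
  if (nrow(pts) == 0L) stop("need at least one point with concentration > 0")
  reps <- unique(pts$replicate)
  missing <- setdiff(as.character(reps), names(baseline_nS))
  if (length(missing))
    stop("missing baseline (C = 0) conductance for replicate(s): ",
         paste(missing, collapse = ", "))
  if (any(baseline_nS == 0)) stop("baseline conductance must be non-zero")

  g0 <- baseline_nS[as.character(pts$replicate)]
  dphi <- boltzmann_delta_phi(pts$conductance_nS / g0, cond, charge)

  agg <- aggregate_replicates(pts$concentration_uM, dphi)
  structure(agg, class = c("boundary_potential_curve", "data.frame"),
            space = "boundary")
}

# mean +/- sd per concentration; sd = 0 for n = 1
aggregate_replicates <- function(concentration, value) {
  f <- factor(concentration, levels = sort(unique(concentration)))
  out <- data.frame(
    concentration_uM = as.numeric(levels(f)),
    delta_phi_mV = as.numeric(tapply(value, f, mean)),
    sd_mV = as.numeric(tapply(value, f, function(v) if (length(v) > 1) stats::sd(v) else 0)),
    n = as.integer(tapply(value, f, length))
  )
  rownames(out) <- NULL
  out
}

#' @export
print.boundary_potential_curve <- function(x, ...) {
  cat(sprintf("Titration curve (%s space): %d concentrations, %s replicates/point\n",
              attr(x, "space") %||% "boundary", nrow(x),
              paste(range(x$n), collapse = "-")))
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_curve_for_fit <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("concentration_uM", "delta_phi_mV") %in% names(curve)))
  if (length(unique(curve$concentration_uM)) < 3L)
    stop("insufficient data: need >= 3 distinct concentrations to fit the Langmuir isotherm")
  s <- sign(curve$delta_phi_mV[curve$delta_phi_mV != 0])
  if (length(unique(s)) > 1L)
    stop("mixed-sign potential changes: check the sign convention / probe valence before fitting")
  invisible(curve)
}

.langmuir_weights <- function(curve) {
  if (!is.null(curve$sd_mV) && all(curve$sd_mV > 0)) 1 / curve$sd_mV^2 else NULL
}

.new_langmuir_fit <- function(phi_max, k, se_phi_max, se_k, method, r2, n) {
  structure(list(phi_max_mV = phi_max, k_uM = k,
                 se_phi_max_mV = se_phi_max, se_k_uM = se_k,
                 method = method, r_squared = r2, n_points = n),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir fit (%s): phi_max = %.2f +/- %.2f mV, K = %.2f +/- %.2f uM (R^2 = %.4f, n = %d)\n",
              x$method, x$phi_max_mV, x$se_phi_max_mV, x$k_uM, x$se_k_uM,
              x$r_squared, x$n_points))
  invisible(x)
}

#' Nonlinear Langmuir adsorption fit
#'
#' Fits the Langmuir adsorption isotherm
#' \deqn{\Delta\varphi(C) = \Delta\varphi(\max)\frac{C}{C+K}}
#' to a titration curve by Levenberg-Marquardt least squares. Points are
#' weighted by `1/sd^2` when every point carries a positive replicate sd,
#' otherwise unweighted. Starting values come from the double-reciprocal
#' linearization.
#'
#' @param curve A `boundary_potential_curve` (boundary- or dipole-potential
#'   space), or any data.frame with `concentration_uM` and `delta_phi_mV`.
#' @return A `langmuir_fit` with `phi_max_mV` (signed plateau), `k_uM`
#'   (desorption constant), standard errors, `r_squared` and `method =
#'   "nonlinear"`.
#' @export
fit_langmuir_nonlinear <- function(curve) {
  .check_curve_for_fit(curve)
  d <- data.frame(C = curve$concentration_uM, y = curve$delta_phi_mV)
  w <- .langmuir_weights(curve)

  start <- tryCatch({
    lin <- fit_langmuir_linearized(curve, phi_max_mode = "double_reciprocal")
    list(phi_max = lin$phi_max_mV, K = max(lin$k_uM, 1e-6))
  }, error = function(e) {
    list(phi_max = d$y[which.max(abs(d$y))] * 1.2, K = stats::median(d$C))
  })

  fit <- minpack.lm::nlsLM(y ~ phi_max * C / (C + K), data = d, start = start,
                           weights = if (is.null(w)) rep(1, nrow(d)) else w,
                           lower = c(phi_max = -Inf, K = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  res <- d$y - stats::fitted(fit)
  r2 <- 1 - sum(res^2) / sum((d$y - mean(d$y))^2)
  if (co["K", "Estimate"] <= 0) stop("Langmuir fit returned non-positive K")
  .new_langmuir_fit(co["phi_max", "Estimate"], co["K", "Estimate"],
                    co["phi_max", "Std. Error"], co["K", "Std. Error"],
                    "nonlinear", r2, nrow(d))
}

#' Linearized Langmuir fit
#'
#' Implements the linearizations of the Langmuir isotherm. With
#' `phi_max_mode = "double_reciprocal"`, 1/potential is regressed on 1/C:
#' the intercept is 1/phi_max and the slope is K/phi_max. With
#' `phi_max_mode = "plateau"`, phi_max is the mean of the points in the
#' saturation region (concentrations >= `plateau_from_uM`) and K is the
#' slope of the regression of phi_max/potential(C) on 1/C (whose intercept
#' is 1 for perfect Langmuir data).
#'
#' @inheritParams fit_langmuir_nonlinear
#' @param phi_max_mode `"double_reciprocal"` (co-estimate phi_max) or
#'   `"plateau"` (fix phi_max from the saturated points).
#' @param plateau_from_uM Concentration from which the curve is considered
#'   saturated; used only in plateau mode. Default 120 uM.
#' @return A `langmuir_fit` with `method = "linearized"`.
#' @export
fit_langmuir_linearized <- function(curve,
                                    phi_max_mode = c("double_reciprocal", "plateau"),
                                    plateau_from_uM = 120) {
  phi_max_mode <- match.arg(phi_max_mode)
  .check_curve_for_fit(curve)
  if (any(curve$delta_phi_mV == 0))
    stop("linearization undefined: zero potential change at C = ",
         paste(curve$concentration_uM[curve$delta_phi_mV == 0], collapse = ", "))
  C <- curve$concentration_uM
  y <- curve$delta_phi_mV

  if (phi_max_mode == "double_reciprocal") {
    m <- stats::lm(I(1 / y) ~ I(1 / C))
    a <- stats::coef(m)[[1]]   # 1/phi_max
    b <- stats::coef(m)[[2]]   # K/phi_max
    if (a == 0) stop("degenerate linearized fit: zero intercept")
    phi_max <- 1 / a
    K <- b / a
    V <- suppressWarnings(stats::vcov(m))  # noiseless curves fit perfectly
    # delta method: phi_max = 1/a, K = b/a
    se_phi <- abs(phi_max^2) * sqrt(V[1, 1])
    grad <- c(-b / a^2, 1 / a)
    se_k <- sqrt(drop(t(grad) %*% V %*% grad))
    r2 <- suppressWarnings(summary(m)$r.squared)
  } else {
    sat <- y[C >= plateau_from_uM]
    if (!length(sat))
      stop("no points at or beyond the saturation threshold (", plateau_from_uM, " uM)")
    # For perfect Langmuir data the regression of phi_max/y on 1/C has
    # intercept 1 and slope K. The plateau mean underestimates |phi_max|
    # when the largest concentrations are not fully saturating, which shows
    # up as an intercept c0 != 1; dividing by c0 restores the identity.
    phi_hat <- mean(sat)
    m <- stats::lm(I(phi_hat / y) ~ I(1 / C))
    c0 <- stats::coef(m)[[1]]
    if (c0 == 0) stop("degenerate plateau-mode fit: zero intercept")
    phi_max <- phi_hat / c0
    K <- stats::coef(m)[[2]] / c0
    V <- suppressWarnings(stats::vcov(m))
    grad <- c(-K / c0, 1 / c0)   # K = b/c0
    se_k <- sqrt(drop(t(grad) %*% V %*% grad))
    se_hat <- if (length(sat) > 1) stats::sd(sat) / sqrt(length(sat)) else 0
    se_phi <- abs(phi_max) * sqrt((se_hat / phi_hat)^2 + V[1, 1] / c0^2)
    r2 <- suppressWarnings(summary(m)$r.squared)
  }
  if (K <= 0) stop("linearized Langmuir fit returned non-positive K")
  .new_langmuir_fit(phi_max, K, se_phi, se_k, "linearized", r2, length(C))
}

#' Predict a Langmuir isotherm
#'
#' @param fit A `langmuir_fit` (or list with `phi_max_mV`, `k_uM`).
#' @param concentration_uM Concentrations in uM, all >= 0.
#' @return Predicted potential change in mV; 0 at C = 0, phi_max/2 at C = K.
#' @export
langmuir_predict <- function(fit, concentration_uM) {
  if (any(concentration_uM < 0)) stop("concentration must be >= 0")
  fit$phi_max_mV * concentration_uM / (concentration_uM + fit$k_uM)
}

#' Read a titration CSV
#'
#' Expects a header `replicate,concentration_uM,conductance_nS`; baseline
#' rows carry `concentration_uM = 0`.
#'
#' @param path File path.
#' @return data.frame suitable for [build_titration_curve()].
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "concentration_uM", "conductance_nS")
  if (!all(need %in% names(d)))
    stop("titration CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' Serialize a Langmuir fit to JSON
#'
#' @param fit A `langmuir_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_langmuir_json <- function(fit, path = NULL) {
  obj <- list(phi_max_mV = fit$phi_max_mV, se_phi_max_mV = fit$se_phi_max_mV,
              K_uM = fit$k_uM, se_K_uM = fit$se_k_uM, method = fit$method,
              r_squared = fit$r_squared, n_points = fit$n_points)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
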