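#' Construct a thermogram
#'
#' A heating scan: excess heat capacity on a uniform, strictly increasing
#' temperature grid.
#'
#' @param temperature_C Temperature grid in degC; uniform within 1%, >= 50
#'   points.
#' @param cp_excess Excess heat capacity (any consistent scale; feature
#'   temperatures and widths are scale-invariant).
#' @param scan_rate_C_min Scan rate in degC/min (metadata only).
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(temperature_C, cp_excess, scan_rate_C_min = 0.2) {
  stopifnot(length(temperature_C) >= 50L,
            length(cp_excess) == length(temperature_C),
            all(diff(temperature_C) > 0))
  steps <- diff(temperature_C)
  if ((max(steps) - min(steps)) > 0.01 * stats::median(steps))
    stop("temperature grid must be uniform within 1%")
  structure(list(temperature_C = as.numeric(temperature_C),
                 cp_excess = as.numeric(cp_excess),
                 scan_rate_C_min = scan_rate_C_min),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram: %.2f-%.2f degC, %d points (step %.3g degC), scan %.2g degC/min\n",
              min(x$temperature_C), max(x$temperature_C),
              length(x$temperature_C), stats::median(diff(x$temperature_C)),
              x$scan_rate_C_min))
  invisible(x)
}

#' Subtract a linear instrumental baseline
#'
#' Fits a straight line through the mean signal of the two flanking regions
#' (first and last `flank_fraction` of the grid) and subtracts it. The
#' flanks must be peak-free: if either flank mean sits higher than 20% of
#' the global maximum above the lower flank, a peak probably overlaps it.
#'
#' @param thermo A `thermogram`.
#' @param flank_fraction Fraction of the grid used on each side; default 0.05.
#' @return A baseline-subtracted `thermogram` (flank means approximately 0).
#' @export
baseline_subtract <- function(thermo, flank_fraction = 0.05) {
  t <- thermo$temperature_C
  y <- thermo$cp_excess
  n <- length(t)
  k <- max(5L, floor(flank_fraction * n))
  i_lo <- seq_len(k); i_hi <- seq(n - k + 1L, n)
  m_lo <- mean(y[i_lo]); m_hi <- mean(y[i_hi])
  t_lo <- mean(t[i_lo]); t_hi <- mean(t[i_hi])
  slope <- (m_hi - m_lo) / (t_hi - t_lo)
  r <- y - (m_lo + slope * (t - t_lo))
  # validate on the detrended signal: the apex must sit between the flanks
  # and the flanks must be structureless relative to the peak
  if (which.max(r) %in% c(i_lo, i_hi) ||
      diff(range(r[i_lo])) > 0.2 * max(r) || diff(range(r[i_hi])) > 0.2 * max(r))
    stop("a peak overlaps a baseline flank; widen the scan range or reduce flank_fraction")
  thermogram(t, r, thermo$scan_rate_C_min)
}

# quadratic interpolation of the apex through the 3 samples around index i
.quad_apex <- function(t, y, i) {
  if (i == 1L || i == length(t)) return(c(t[i], y[i]))
  dt <- t[i + 1L] - t[i]
  d1 <- (y[i + 1L] - y[i - 1L]) / 2
  d2 <- y[i + 1L] - 2 * y[i] + y[i - 1L]
  if (d2 >= 0) return(c(t[i], y[i]))
  off <- -d1 / d2
  c(t[i] + off * dt, y[i] - d1^2 / (2 * d2))
}

#' Detect melting transitions in a thermogram
#'
#' Finds local maxima whose height is at least `prominence` times the
#' global maximum of the (baseline-subtracted) signal, and refines each
#' apex by quadratic interpolation of the three samples around the maximum.
#'
#' @param thermo A baseline-subtracted `thermogram`.
#' @param prominence Minimum peak height as a fraction of the global
#'   maximum; default 0.05.
#' @return data.frame with one row per peak (`t_peak_C`, `height`, `index`),
#'   sorted by temperature; zero rows when nothing qualifies.
#' @export
detect_transitions <- function(thermo, prominence = 0.05) {
  t <- thermo$temperature_C
  y <- thermo$cp_excess
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[y[i] >= prominence * max(y) & y[i] > 0]
  if (!length(i))
    return(data.frame(t_peak_C = numeric(0), height = numeric(0),
                      index = integer(0)))
  apex <- t(vapply(i, function(j) .quad_apex(t, y, j), numeric(2)))
  out <- data.frame(t_peak_C = apex[, 1], height = apex[, 2], index = i)
  out[order(out$t_peak_C), , drop = FALSE]
}

# half-height crossing by linear interpolation, walking from index i in steps of `dir`
.half_crossing <- function(t, y, i, half, dir) {
  j <- i
  while (j + dir >= 1L && j + dir <= length(y) && y[j + dir] >= half) j <- j + dir
  if (j + dir < 1L || j + dir > length(y))
    stop("half-height not bracketed on ", if (dir < 0) "the low" else "the high",
         "-temperature side of the peak")
  j2 <- j + dir
  t[j] + (t[j2] - t[j]) * (y[j] - half) / (y[j] - y[j2])
}

#' Main-transition features
#'
#' Extracts, for the main (highest) melting peak: the apex temperature
#' `t_m_C` (quadratic interpolation), the full width at half maximum
#' `t_half_C` (linear interpolation of the half-height crossings), and the
#' calorimetric `area` (trapezoidal integral over the peak's support, the
#' contiguous region around the apex where the signal stays above 1% of the
#' apex height).
#'
#' @param thermo A baseline-subtracted `thermogram`.
#' @param peak One row of [detect_transitions()] output (defaults to the
#'   highest detected peak).
#' @return A `transition_features` list: `t_pre_C` (NA here; see
#'   [pretransition_features()]), `t_m_C`, `t_half_C`, `area`.
#' @export
main_transition_features <- function(thermo, peak = NULL) {
  t <- thermo$temperature_C
  y <- thermo$cp_excess
  if (is.null(peak)) {
    pk <- detect_transitions(thermo)
    if (!nrow(pk)) stop("no transition peak detected")
    peak <- pk[which.max(pk$height), ]
  }
  i <- peak$index
  apex <- .quad_apex(t, y, i)
  half <- apex[2] / 2
  lo <- .half_crossing(t, y, i, half, -1L)
  hi <- .half_crossing(t, y, i, half, +1L)

  # support: contiguous region around the apex above 1% of apex height
  thr <- 0.01 * apex[2]
  a <- i; while (a > 1L && y[a - 1L] > thr) a <- a - 1L
  b <- i; while (b < length(y) && y[b + 1L] > thr) b <- b + 1L
  area <- pracma::trapz(t[a:b], y[a:b])

  structure(list(t_pre_C = NA_real_, t_m_C = apex[1], t_half_C = hi - lo,
                 area = area, apex_height = apex[2],
                 support_C = c(t[a], t[b])),
            class = "transition_features")
}

#' @export
print.transition_features <- function(x, ...) {
  cat(sprintf("Melting features: Tm = %.3f degC, T1/2 = %.3f degC, area = %.4g%s\n",
              x$t_m_C, x$t_half_C, x$area,
              if (is.na(x$t_pre_C)) "" else sprintf(", Tp = %.3f degC", x$t_pre_C)))
  invisible(x)
}

#' Pretransition detection
#'
#' Searches a window below the main peak (default `[t_m - 12, t_m - 2]`
#' degC) for the rippled-gel pretransition. A peak qualifies when its height
#' reaches `min_relative_height` (default 5%) of the main apex; otherwise
#' the pretransition is reported as suppressed. The window must not overlap
#' the main peak's half-height support region.
#'
#' @param thermo A baseline-subtracted `thermogram`.
#' @param main A `transition_features` from [main_transition_features()].
#' @param search_window Numeric `c(lo, hi)` in degC; default
#'   `t_m + c(-12, -2)`.
#' @param min_relative_height Suppression threshold as a fraction of the
#'   main apex height; default 0.05.
#' @return List with `t_pre_C` (NA when suppressed), `suppressed`, `height`.
#' @export
pretransition_features <- function(thermo, main, search_window = NULL,
                                   min_relative_height = 0.05) {
  if (is.null(search_window)) search_window <- main$t_m_C + c(-12, -2)
  stopifnot(length(search_window) == 2L, search_window[1] < search_window[2])
  # main-peak extent for overlap purposes: region above 5% of the apex
  t <- thermo$temperature_C
  y <- thermo$cp_excess
  i_m <- which.min(abs(t - main$t_m_C))
  thr <- 0.05 * main$apex_height
  a <- i_m; while (a > 1L && y[a - 1L] > thr) a <- a - 1L
  if (search_window[2] > t[a])
    stop(sprintf("pretransition window extends to %.2f degC, into the main peak support (from %.2f degC)",
                 search_window[2], t[a]))

  sel <- t >= search_window[1] & t <= search_window[2]
  if (sum(sel) < 5L) stop("pretransition window contains too few samples")
  sub <- thermogram(t[sel], y[sel], thermo$scan_rate_C_min)
  i <- which(diff(sign(diff(sub$cp_excess))) == -2) + 1L
  i <- i[sub$cp_excess[i] >= min_relative_height * main$apex_height]
  if (!length(i))
    return(list(t_pre_C = NA_real_, suppressed = TRUE, height = NA_real_))
  j <- i[which.max(sub$cp_excess[i])]
  apex <- .quad_apex(sub$temperature_C, sub$cp_excess, j)
  list(t_pre_C = apex[1], suppressed = FALSE, height = apex[2])
}

#' Full feature extraction for one thermogram
#'
#' Convenience wrapper: baseline subtraction, peak detection, main-peak
#' features and pretransition search in one call.
#'
#' @param thermo A raw `thermogram`.
#' @param flank_fraction Passed to [baseline_subtract()].
#' @param ... Passed to [pretransition_features()].
#' @return A `transition_features` with `t_pre_C` filled in (NA when the
#'   pretransition is suppressed).
#' @export
extract_transition_features <- function(thermo, flank_fraction = 0.05, ...) {
  flat <- baseline_subtract(thermo, flank_fraction)
  feats <- main_transition_features(flat)
  pre <- pretransition_features(flat, feats, ...)
  feats$t_pre_C <- pre$t_pre_C
  feats$pretransition_suppressed <- pre$suppressed
  feats
}

#' Control-vs-treated transition changes
#'
#' Reports the main-transition downshift `d_t_m_C = control Tm - treated Tm`
#' (positive for the usual drug-induced downshift), the broadening
#' `d_t_half_C = treated T1/2 - control T1/2`, and whether the treated
#' thermogram's pretransition is suppressed.
#'
#' @param control,treated `transition_features` objects from the same lipid
#'   system.
#' @return A `transition_delta` list.
#' @export
compare_to_control <- function(control, treated) {
  structure(list(
    d_t_m_C = control$t_m_C - treated$t_m_C,
    d_t_half_C = treated$t_half_C - control$t_half_C,
    pretransition_suppressed =
      isTRUE(treated$pretransition_suppressed) || is.na(treated$t_pre_C)
  ), class = "transition_delta")
}

#' @export
print.transition_delta <- function(x, ...) {
  cat(sprintf("Transition changes: -dTm = %.3f degC, dT1/2 = %.3f degC, pretransition %s\n",
              x$d_t_m_C, x$d_t_half_C,
              if (x$pretransition_suppressed) "suppressed" else "present"))
  invisible(x)
}

#' Read a thermogram CSV
#'
#' Header `temperature_C,cp_excess`; scan-rate metadata may sit in a JSON
#' sidecar `<path>.json`.
#'
#' @param path File path.
#' @return A `thermogram`.
#' @export
read_thermogram_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("temperature_C", "cp_excess") %in% names(d)))
    stop("thermogram CSV must have columns temperature_C, cp_excess")
  rate <- 0.2
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    rate <- meta$scan_rate_C_min %||% rate
  }
  thermogram(d$temperature_C, d$cp_excess, rate)
}
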