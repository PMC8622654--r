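#' Construct a current trace
#'
#' A uniformly sampled current record with its acquisition metadata.
#'
#' @param samples Current samples in pA (>= 2 values).
#' @param sampling_rate_Hz Sampling rate in Hz.
#' @param filter_cutoff_Hz Nominal low-pass cutoff applied during
#'   acquisition, in Hz; must satisfy `sampling_rate_Hz > 2 * filter_cutoff_Hz`.
#' @param cond [recording_conditions()] (supplies the applied voltage).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate_Hz = 5000,
                          filter_cutoff_Hz = 1000,
                          cond = recording_conditions(voltage_mV = 200,
                                                      electrolyte_M = 2.0)) {
  stopifnot(is.numeric(samples), length(samples) >= 2L,
            sampling_rate_Hz > 2 * filter_cutoff_Hz)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_Hz = sampling_rate_Hz,
                 filter_cutoff_Hz = filter_cutoff_Hz,
                 cond = cond),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples (%.1f s) at %g Hz, low-pass %g Hz, V = %g mV\n",
              length(x$samples), length(x$samples) / x$sampling_rate_Hz,
              x$sampling_rate_Hz, x$filter_cutoff_Hz, x$cond$voltage_mV))
  invisible(x)
}

# filter rise time (10-90%) of a ~1-pole-equivalent low-pass, in seconds
.rise_time_s <- function(filter_cutoff_Hz) 0.3321 / filter_cutoff_Hz

#' Estimate the closed-state (baseline) current
#'
#' The baseline is the mode of a kernel-smoothed amplitude density, which
#' stays on the closed level as long as the channel is closed at least half
#' of the time; the median is used as a fallback if density estimation
#' fails.
#'
#' @param trace A `current_trace`.
#' @return Baseline current in pA.
#' @export
estimate_baseline <- function(trace) {
  x <- trace$samples
  if (stats::sd(x) == 0) return(x[1])
  d <- tryCatch(stats::density(x, n = 1024), error = function(e) NULL)
  if (is.null(d)) return(stats::median(x))
  d$x[which.max(d$y)]
}

# kernel-density mode locations, highest first, pruned below frac of max
.density_modes <- function(x, frac = 0.05) {
  d <- stats::density(x, n = 1024)
  i <- which(diff(sign(diff(d$y))) == -2) + 1L
  i <- i[d$y[i] >= frac * max(d$y)]
  d$x[i[order(d$y[i], decreasing = TRUE)]]
}

#' Idealize a single-channel record by half-amplitude threshold
#'
#' Detects openings and closures of a single-level pore with the
#' half-amplitude threshold method: a sample switches the state to open when
#' it crosses baseline + 0.5 * amplitude (plus 10% hysteresis) and back to
#' closed on the symmetric downward crossing. Events shorter than
#' `min_duration_s` are merged into the surrounding level. Per-segment mean
#' amplitudes exclude one filter rise time after each transition so that
#' filter-attenuated samples do not bias the level estimate.
#'
#' @param trace A `current_trace`.
#' @param expected_amplitude_pA Open-channel amplitude in pA, or `"auto"` to
#'   estimate it from the amplitude density (distance between the open and
#'   closed modes).
#' @param min_duration_s Minimum accepted event duration in s; default twice
#'   the filter rise time (2 * 0.3321 / filter_cutoff).
#' @param baseline_pA Closed-level current in pA; estimated with
#'   [estimate_baseline()] when `NULL`. Supply it explicitly for records
#'   with ~50% open occupancy, where the amplitude-density mode is
#'   ambiguous.
#' @return An `idealized_trace`: list with `segments` (data.frame
#'   `start_time_s`, `duration_s`, `level_index` 0 = closed / 1 = open,
#'   `mean_amplitude_pA`) and `baseline_pA` (mean of closed-segment samples).
#' @export
idealize_half_amplitude <- function(trace, expected_amplitude_pA = "auto",
                                    min_duration_s = NULL, baseline_pA = NULL) {
  x <- trace$samples
  fs <- trace$sampling_rate_Hz
  if (is.null(min_duration_s))
    min_duration_s <- 2 * .rise_time_s(trace$filter_cutoff_Hz)
  min_samples <- max(1L, round(min_duration_s * fs))

  baseline <- baseline_pA %||% estimate_baseline(trace)
  if (identical(expected_amplitude_pA, "auto")) {
    modes <- .density_modes(x)
    open_mode <- modes[which.max(abs(modes - baseline))]
    amp <- open_mode - baseline
    if (!length(amp) || abs(amp) < .Machine$double.eps)
      stop("could not estimate the open-channel amplitude; supply `expected_amplitude_pA`")
  } else {
    amp <- expected_amplitude_pA
  }
  # robust broadband noise estimate from first differences
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  if (noise_sd > 0 && abs(amp) < 3 * noise_sd)
    stop(sprintf(paste0("amplitude (%.3g pA) below detectability: must exceed ",
                        "3x the noise sd (%.3g pA)"), abs(amp), noise_sd))

  # hysteresis thresholds at half amplitude +/- 10% of amplitude
  thr_hi <- baseline + amp * 0.6
  thr_lo <- baseline + amp * 0.4
  if (amp < 0) { tmp <- thr_hi; thr_hi <- thr_lo; thr_lo <- tmp }
  rel <- if (amp > 0) x else -x
  hi <- if (amp > 0) thr_hi else -thr_hi
  lo <- if (amp > 0) thr_lo else -thr_lo
  state <- rep(NA_real_, length(x))
  state[rel > hi] <- 1
  state[rel < lo] <- 0
  state <- zoo::na.locf(state, na.rm = FALSE)
  if (is.na(state[1])) { # leading in-band samples: nearest level
    first <- which(!is.na(state))[1]
    if (is.na(first)) stop("no threshold crossings: trace never leaves the dead band")
    lead_val <- mean(rel[seq_len(first - 1L)])
    state[seq_len(first - 1L)] <- as.numeric(abs(lead_val - hi) < abs(lead_val - lo))
  }

  r <- rle(state)
  # merge events shorter than min_samples into the surrounding level
  while (length(r$lengths) > 1L && any(r$lengths < min_samples)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_samples) break
    r$values[i] <- if (i == 1L) r$values[2L] else r$values[i - 1L]
    state <- inverse.rle(r)
    r <- rle(state)
  }

  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  n_rise <- ceiling(.rise_time_s(trace$filter_cutoff_Hz) * fs)
  seg_mean <- mapply(function(s, e) {
    s2 <- min(s + n_rise, e)  # drop filter-rise samples after the transition
    mean(x[s2:e])
  }, starts, ends)

  segments <- data.frame(
    start_time_s = (starts - 1L) / fs,
    duration_s = r$lengths / fs,
    level_index = as.integer(r$values),
    mean_amplitude_pA = as.numeric(seg_mean)
  )
  closed_idx <- unlist(mapply(function(s, e, v) if (v == 0) s:e else NULL,
                              starts, ends, r$values))
  baseline_out <- if (length(closed_idx)) mean(x[closed_idx]) else baseline
  structure(list(segments = segments, baseline_pA = baseline_out,
                 sampling_rate_Hz = fs, cond = trace$cond),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  n_open <- sum(x$segments$level_index > 0)
  cat(sprintf("Idealized trace: %d segments (%d openings), baseline %.3f pA, P(open) = %.3f\n",
              nrow(x$segments), n_open, x$baseline_pA, open_probability(x)))
  invisible(x)
}

#' Fraction of time spent in the open state
#'
#' @param ideal An `idealized_trace`.
#' @return Open probability in `[0, 1]`.
#' @export
open_probability <- function(ideal) {
  s <- ideal$segments
  sum(s$duration_s[s$level_index > 0]) / sum(s$duration_s)
}

#' Per-event single-channel conductances
#'
#' One conductance per open segment: g = (mean amplitude - baseline) / V,
#' expressed in pS (amplitude in pA, voltage in mV).
#'
#' @param ideal An `idealized_trace`.
#' @param cond [recording_conditions()]; defaults to the conditions stored
#'   with the trace. The applied voltage must be non-zero.
#' @return Numeric vector of conductances in pS, one per open event.
#' @export
events_to_conductance <- function(ideal, cond = NULL) {
  cond <- cond %||% ideal$cond
  if (cond$voltage_mV == 0) stop("applied voltage is zero: conductance undefined")
  s <- ideal$segments
  open <- s[s$level_index > 0, , drop = FALSE]
  (open$mean_amplitude_pA - ideal$baseline_pA) / cond$voltage_mV * 1000
}

#' Conductance-voltage (G-V) curve
#'
#' @param per_voltage List mapping voltages to conductance samples: either a
#'   named list (names = voltage in mV) of numeric vectors.
#' @return A data.frame of class `gv_curve` with `voltage_mV`, `g_mean_pS`,
#'   `g_sd_pS`, `n`, sorted by voltage.
#' @export
gv_curve <- function(per_voltage) {
  if (!length(per_voltage)) stop("no voltages supplied")
  v <- as.numeric(names(per_voltage))
  if (any(is.na(v))) stop("`per_voltage` must be a named list with voltages (mV) as names")
  if (anyDuplicated(v)) stop("voltages must be distinct")
  out <- data.frame(
    voltage_mV = v,
    g_mean_pS = vapply(per_voltage, mean, 0),
    g_sd_pS = vapply(per_voltage, function(g) if (length(g) > 1) stats::sd(g) else 0, 0),
    n = vapply(per_voltage, length, 0L)
  )
  out <- out[order(out$voltage_mV), ]
  rownames(out) <- NULL
  structure(out, class = c("gv_curve", "data.frame"))
}

#' Relative conductance increment, in percent
#'
#' 100 * (treated - control) / control, computed from fitted peak means.
#'
#' @param control,treated `peak_fit` objects (or lists with a `mean_pS`
#'   element).
#' @return Percent change in single-channel conductance.
#' @export
conductance_increment <- function(control, treated) {
  g0 <- control$mean_pS
  g1 <- treated$mean_pS
  if (!is.finite(g0) || g0 <= 0) stop("control peak mean must be > 0")
  100 * (g1 - g0) / g0
}

#' Read a current trace from CSV
#'
#' Accepts a headered CSV `time_s,current_pA` or a headerless two-column
#' TSV. Acquisition metadata (sampling rate, filter cutoff, voltage) comes
#' from a JSON sidecar `<path>.json` when present, else from the arguments.
#'
#' @param path File path.
#' @param sampling_rate_Hz,filter_cutoff_Hz,voltage_mV Metadata used when no
#'   sidecar is found; the sampling rate defaults to the inverse median time
#'   step of the file.
#' @return A `current_trace`.
#' @export
read_trace_csv <- function(path, sampling_rate_Hz = NULL,
                           filter_cutoff_Hz = 1000, voltage_mV = 200) {
  first <- readLines(path, n = 1L)
  if (grepl("time", first, ignore.case = TRUE)) {
    d <- utils::read.csv(path)
  } else {
    d <- utils::read.table(path, sep = if (grepl(",", first)) "," else "\t")
    names(d) <- c("time_s", "current_pA")
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    sampling_rate_Hz <- meta$sampling_rate %||% meta$sampling_rate_Hz %||% sampling_rate_Hz
    filter_cutoff_Hz <- meta$filter_cutoff %||% meta$filter_cutoff_Hz %||% filter_cutoff_Hz
    voltage_mV <- meta$voltage_mV %||% voltage_mV
  }
  if (is.null(sampling_rate_Hz))
    sampling_rate_Hz <- 1 / stats::median(diff(d[[1]]))
  current_trace(d[[2]], sampling_rate_Hz, filter_cutoff_Hz,
                recording_conditions(voltage_mV = voltage_mV, electrolyte_M = 2.0))
}
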