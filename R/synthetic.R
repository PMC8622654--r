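# Seeded generators for every input class the pipeline consumes. Each one
# embeds its ground truth in the returned object's attributes so analyzers
# can be checked by round trip.

#' Synthetic adsorption titration
#'
#' Forward model of a modifier titration: the true potential change follows
#' the Langmuir isotherm `phi_max * C / (C + K)`; Gaussian noise of sd
#' `noise_sd_mV` is applied in potential space (per replicate and
#' concentration) and then mapped to the observable. In `"boundary"` space
#' the observable is the carrier-probe conductance
#' `G = G0 * exp(-z e dphi / kT)` (multiplicative noise on G, consistent
#' with additive noise in potential space); in `"dipole"` space it is a
#' (I420, I520) fluorescence pair obtained by inverting the ratiometric
#' calibration around a resting dipole potential.
#'
#' @param phi_max_mV True maximal potential change (signed), mV.
#' @param k_uM True desorption constant, uM (> 0).
#' @param concentrations_uM Concentrations, uM (> 0); a C = 0 baseline row
#'   is always added per replicate.
#' @param noise_sd_mV Potential-space noise sd, mV (>= 0).
#' @param n_replicates Number of replicate bilayers/vesicle preparations.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param space `"boundary"` (conductance observable) or `"dipole"`
#'   (fluorescence observable).
#' @param cond,charge Recording conditions and probe valence (boundary
#'   space).
#' @param baseline_nS Baseline (C = 0) conductance per replicate, nS.
#' @param cal [dipole_calibration()] used to invert potentials into ratios
#'   (dipole space).
#' @param resting_phi_d_mV Resting dipole potential at C = 0, mV.
#' @param i520 Reference intensity I520 (a.u.) held constant.
#' @return data.frame of titration points (`replicate`, `concentration_uM`,
#'   and either `conductance_nS` or `I420`/`I520`), with the truth stored in
#'   attributes `phi_max_mV`, `k_uM`.
#' @export
gen_titration <- function(phi_max_mV, k_uM, concentrations_uM,
                          noise_sd_mV = 0, n_replicates = 1L, seed = NULL,
                          space = c("boundary", "dipole"),
                          cond = recording_conditions(),
                          charge = charge_spec(),
                          baseline_nS = 10, cal = dipole_calibration(),
                          resting_phi_d_mV = 400, i520 = 1000) {
  space <- match.arg(space)
  stopifnot(is.finite(phi_max_mV), k_uM > 0, noise_sd_mV >= 0,
            n_replicates >= 1L, all(concentrations_uM > 0))
  if (!is.null(seed)) set.seed(seed)
  concentrations_uM <- sort(unique(concentrations_uM))

  rows <- lapply(seq_len(n_replicates), function(rep_id) {
    truth <- phi_max_mV * concentrations_uM / (concentrations_uM + k_uM)
    dphi <- truth + stats::rnorm(length(truth), 0, noise_sd_mV)
    if (space == "boundary") {
      g <- baseline_nS * conductance_ratio_from_delta_phi(dphi, cond, charge)
      data.frame(replicate = rep_id,
                 concentration_uM = c(0, concentrations_uM),
                 conductance_nS = c(baseline_nS, g))
    } else {
      phi <- resting_phi_d_mV + c(0, dphi)
      R <- cal$slope_b * phi - cal$intercept_a
      if (any(R <= 0))
        stop("calibration/resting potential give non-positive excitation ratios")
      data.frame(replicate = rep_id,
                 concentration_uM = c(0, concentrations_uM),
                 I420 = R * i520, I520 = i520)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "phi_max_mV") <- phi_max_mV
  attr(out, "k_uM") <- k_uM
  attr(out, "space") <- space
  out
}

#' Synthetic single-channel current record
#'
#' Two-state (closed/open) continuous-time Markov gating with exponential
#' dwell times, sampled onto a uniform grid. Each opening is assigned one of
#' the supplied conductance levels (uniformly at random when several are
#' given); the open-level amplitude is `g * V`. Additive Gaussian noise is
#' applied and the record is passed through a 4th-order causal Butterworth
#' low-pass at `filter_cutoff_Hz`, emulating the acquisition chain.
#'
#' @param conductance_pS Open-level conductance(s), pS.
#' @param open_rate_s,close_rate_s Opening and closing rates, 1/s (> 0);
#'   the stationary open probability is `open_rate / (open_rate +
#'   close_rate)`.
#' @param voltage_mV Applied voltage, mV.
#' @param duration_s Record length, s; must give at least ~10 events
#'   (`duration * min(rate) >= 10`).
#' @param sampling_rate_Hz Sampling rate, Hz; must exceed twice the filter
#'   cutoff.
#' @param noise_sd_pA Pre-filter additive noise sd, pA.
#' @param filter_cutoff_Hz Low-pass cutoff, Hz.
#' @param seed Integer seed.
#' @return A `current_trace` with attributes `true_open_fraction` (fraction
#'   of grid samples in the open state), `n_openings`, and
#'   `true_amplitude_pA`.
#' @export
gen_single_channel_trace <- function(conductance_pS = 22,
                                     open_rate_s = 5, close_rate_s = 10,
                                     voltage_mV = 200, duration_s = 60,
                                     sampling_rate_Hz = 5000,
                                     noise_sd_pA = 0.3,
                                     filter_cutoff_Hz = 1000, seed = NULL) {
  stopifnot(open_rate_s > 0, close_rate_s > 0, duration_s > 0,
            all(conductance_pS > 0))
  if (duration_s * min(open_rate_s, close_rate_s) < 10)
    stop("record too short: need duration * min(rate) >= 10 for enough events")
  if (sampling_rate_Hz <= 2 * filter_cutoff_Hz)
    stop("sampling_rate_Hz must exceed 2 * filter_cutoff_Hz")
  if (!is.null(seed)) set.seed(seed)

  p_open <- open_rate_s / (open_rate_s + close_rate_s)
  state0 <- stats::runif(1) < p_open
  # alternating exponential dwells until the record is covered
  n_guess <- ceiling(2.5 * duration_s * open_rate_s * close_rate_s /
                       (open_rate_s + close_rate_s)) + 20L
  dwells <- numeric(0); states <- logical(0); cur <- state0; tot <- 0
  while (tot < duration_s) {
    k <- max(64L, n_guess)
    s_seq <- rep(c(cur, !cur), length.out = k)
    d_seq <- stats::rexp(k, rate = ifelse(s_seq, close_rate_s, open_rate_s))
    dwells <- c(dwells, d_seq); states <- c(states, s_seq)
    tot <- sum(dwells); cur <- !states[length(states)]
  }
  ends <- cumsum(dwells)
  n <- round(duration_s * sampling_rate_Hz)
  tgrid <- (seq_len(n) - 0.5) / sampling_rate_Hz
  dwell_of_sample <- findInterval(tgrid, c(0, ends), rightmost.closed = TRUE)

  # one conductance level per opening
  open_dwells <- which(states)
  level <- numeric(length(dwells))
  level[open_dwells] <-
    conductance_pS[sample.int(length(conductance_pS), length(open_dwells),
                              replace = TRUE)]
  amp_per_dwell <- level * voltage_mV / 1000  # pS * mV -> pA
  x <- amp_per_dwell[dwell_of_sample]
  open_frac <- mean(states[dwell_of_sample])
  if (noise_sd_pA > 0) x <- x + stats::rnorm(n, 0, noise_sd_pA)
  bf <- signal::butter(4, filter_cutoff_Hz / (sampling_rate_Hz / 2), type = "low")
  x <- as.numeric(signal::filter(bf, x))

  tr <- current_trace(x, sampling_rate_Hz, filter_cutoff_Hz,
                      recording_conditions(voltage_mV = voltage_mV,
                                           electrolyte_M = 2.0))
  attr(tr, "true_open_fraction") <- open_frac
  attr(tr, "n_openings") <- sum(states[unique(dwell_of_sample)])
  attr(tr, "true_amplitude_pA") <- conductance_pS * voltage_mV / 1000
  tr
}

#' Synthetic macroscopic (multichannel) record
#'
#' Current at `i_baseline_pA` before the addition; afterwards an exponential
#' approach with time constant `tau_s` to the new plateau
#' `i_baseline_pA * fold_change`. Optional additive Gaussian noise.
#'
#' @param i_baseline_pA Pre-addition steady-state current, pA (> 0).
#' @param fold_change Plateau ratio after/before (> 0).
#' @param tau_s Relaxation time constant, s (> 0).
#' @param addition_time_s Moment of modifier addition, s.
#' @param duration_s Record length, s; must exceed `addition_time_s +
#'   5 * tau_s`.
#' @param noise_sd_pA Additive noise sd, pA.
#' @param sampling_rate_Hz Sampling rate, Hz.
#' @param seed Integer seed.
#' @return A `macroscopic_record` with attribute `true_fold_change`.
#' @export
gen_macroscopic_trace <- function(i_baseline_pA = 10, fold_change = 11.1,
                                  tau_s = 20, addition_time_s = 100,
                                  duration_s = 400, noise_sd_pA = 0,
                                  sampling_rate_Hz = 100, seed = NULL) {
  stopifnot(i_baseline_pA > 0, fold_change > 0, tau_s > 0)
  if (duration_s <= addition_time_s + 5 * tau_s)
    stop("duration must exceed addition_time + 5 * tau")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate_Hz)
  t <- (seq_len(n) - 0.5) / sampling_rate_Hz
  plateau <- i_baseline_pA * fold_change
  x <- ifelse(t < addition_time_s, i_baseline_pA,
              plateau + (i_baseline_pA - plateau) * exp(-(t - addition_time_s) / tau_s))
  if (noise_sd_pA > 0) x <- x + stats::rnorm(n, 0, noise_sd_pA)
  tr <- current_trace(x, sampling_rate_Hz, sampling_rate_Hz / 4,
                      recording_conditions(voltage_mV = 50, electrolyte_M = 2.0,
                                           lipid_composition = "POPC/Chol 67/33"))
  rec <- macroscopic_record(tr, addition_time_s)
  attr(rec, "true_fold_change") <- fold_change
  rec
}

# half-height condition K/(1+K)^2 = 1/8 gives ln K = +/- log(3 + 2*sqrt(2))
.fwhm_const <- 2 * log(3 + 2 * sqrt(2))  # 3.52549...

#' Van't Hoff enthalpy for a target melting-peak width (and back)
#'
#' For a two-state melting transition the full width at half maximum of the
#' excess-heat-capacity peak is, to first order,
#' `FWHM = 2 ln(3 + 2 sqrt(2)) * R * Tm^2 / dH_vH` (~3.5255 R Tm^2 / dH).
#'
#' @param t_m_C Main transition temperature, degC.
#' @param fwhm_C Target full width at half maximum, degC.
#' @return `vant_hoff_enthalpy_for_fwhm`: enthalpy in J/mol;
#'   `vant_hoff_fwhm`: width in degC.
#' @export
vant_hoff_enthalpy_for_fwhm <- function(t_m_C, fwhm_C) {
  tk <- t_m_C + 273.15
  .fwhm_const * .r_gas * tk^2 / fwhm_C
}

#' @rdname vant_hoff_enthalpy_for_fwhm
#' @param dh_vh_J_mol Van't Hoff enthalpy, J/mol.
#' @export
vant_hoff_fwhm <- function(dh_vh_J_mol, t_m_C) {
  tk <- t_m_C + 273.15
  .fwhm_const * .r_gas * tk^2 / dh_vh_J_mol
}

#' Synthetic lipid melting thermogram
#'
#' Two-state van't Hoff main transition:
#' `Cp(T) = (dH_vH^2 / (R T^2)) * K / (1 + K)^2` with
#' `K = exp((dH_vH / R)(1/Tm - 1/T))` (temperatures in K), scaled so its
#' integral equals `dh_cal`. A broad Gaussian pretransition of relative
#' amplitude `pre_amplitude` (fraction of the main apex; 0 disables) is
#' added at `pre_t_C`, then a linear baseline and optional Gaussian noise
#' (sd expressed as a fraction of the main apex height).
#'
#' @param t_m_C Main transition temperature, degC.
#' @param dh_vh_J_mol Van't Hoff enthalpy, J/mol; sets the peak sharpness.
#'   Default gives a 0.5 degC half-width at the default `t_m_C`.
#' @param dh_cal Calorimetric area of the main peak (integral scale).
#' @param pre_t_C Pretransition temperature, degC (< `t_m_C`).
#' @param pre_amplitude Pretransition apex height as a fraction of the main
#'   apex; 0 disables the pretransition.
#' @param pre_width_C Gaussian sd of the pretransition, degC.
#' @param baseline_slope,baseline_intercept Linear instrumental baseline.
#' @param noise_sd Noise sd as a fraction of the main apex height.
#' @param t_range_C Scan range, degC.
#' @param grid_step_C Temperature grid step, degC.
#' @param scan_rate_C_min Scan rate metadata, degC/min.
#' @param seed Integer seed.
#' @return A `thermogram` with attributes `t_m_C`, `fwhm_C` (closed-form),
#'   `pre_t_C` (NA when disabled).
#' @export
gen_thermogram <- function(t_m_C = 41.2,
                           dh_vh_J_mol = vant_hoff_enthalpy_for_fwhm(41.2, 0.5),
                           dh_cal = 1, pre_t_C = 34.0, pre_amplitude = 0.1,
                           pre_width_C = 1.0, baseline_slope = 0,
                           baseline_intercept = 0, noise_sd = 0,
                           t_range_C = c(25, 50), grid_step_C = 0.01,
                           scan_rate_C_min = 0.2, seed = NULL) {
  stopifnot(grid_step_C > 0, dh_vh_J_mol > 0, dh_cal > 0,
            t_range_C[1] < t_m_C, t_m_C < t_range_C[2])
  if (pre_amplitude > 0 && pre_t_C >= t_m_C)
    stop("pretransition must lie below the main transition")
  if (!is.null(seed)) set.seed(seed)

  tC <- seq(t_range_C[1], t_range_C[2], by = grid_step_C)
  tK <- tC + 273.15
  tmK <- t_m_C + 273.15
  K <- exp((dh_vh_J_mol / .r_gas) * (1 / tmK - 1 / tK))
  cp <- (dh_vh_J_mol^2 / (.r_gas * tK^2)) * K / (1 + K)^2
  cp <- cp * dh_cal / pracma::trapz(tC, cp)
  apex <- max(cp)

  if (pre_amplitude > 0)
    cp <- cp + pre_amplitude * apex * exp(-(tC - pre_t_C)^2 / (2 * pre_width_C^2))
  cp <- cp + baseline_intercept + baseline_slope * (tC - t_range_C[1])
  if (noise_sd > 0) cp <- cp + stats::rnorm(length(cp), 0, noise_sd * apex)

  th <- thermogram(tC, cp, scan_rate_C_min)
  attr(th, "t_m_C") <- t_m_C
  attr(th, "fwhm_C") <- vant_hoff_fwhm(dh_vh_J_mol, t_m_C)
  attr(th, "pre_t_C") <- if (pre_amplitude > 0) pre_t_C else NA_real_
  th
}
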