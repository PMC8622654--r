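# Shared fixtures built in code.

std_concentrations <- c(5, 10, 20, 40, 80, 120, 240)

# Langmuir parameter pairs spanning the reported range of drug effects on
# zwitterionic bilayers (signed plateau in mV, desorption constant in uM)
langmuir_pairs <- data.frame(
  phi_max = c(-67, -84, -74, -83, -71, -86),
  k = c(21, 17, 3, 30, 31, 10)
)

# noiseless square-wave current trace: alternating closed/open dwells
square_trace <- function(amp_pA = 4.4, dwell_s = 0.01, n_cycles = 10,
                         fs = 5000, fc = 1000, voltage_mV = 200) {
  one <- c(rep(0, dwell_s * fs), rep(amp_pA, dwell_s * fs))
  current_trace(rep(one, n_cycles), fs, fc,
                recording_conditions(voltage_mV = voltage_mV,
                                     electrolyte_M = 2.0))
}

# quiet wrapper: event-count guidance warnings are irrelevant in most tests
quiet_hist <- function(x, ...) suppressWarnings(build_conductance_histogram(x, ...))
quiet_peaks <- function(h, ...) suppressWarnings(fit_normal_peaks(h, ...))
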