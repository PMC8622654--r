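# Physical constants (CODATA 2018, exact where defined)
.k_boltzmann <- 1.380649e-23   # J/K
.e_charge    <- 1.602176634e-19 # C
.r_gas       <- 8.31446261815324 # J/(mol K)

#' Recording conditions shared by the electrophysiology stages
#'
#' Bundles the experimental state that every conductance-to-potential
#' conversion needs: absolute temperature, applied transmembrane voltage,
#' electrolyte molarity, pH, and a free-text lipid composition label.
#'
#' @param temperature_K Absolute temperature in K. Default 298.15 K (25 degC,
#'   room temperature).
#' @param voltage_mV Applied transmembrane voltage in mV. Default 50 mV, the
#'   holding voltage used for carrier-probe and macroscopic recordings;
#'   single-channel work typically uses larger values (e.g. 200 mV).
#' @param electrolyte_M Electrolyte concentration in mol/L (e.g. 0.1 or 2.0 M
#'   KCl).
#' @param ph Solution pH.
#' @param lipid_composition Label such as `"POPC"`, `"POPC/Chol 67/33"`.
#' @return An object of class `recording_conditions`.
#' @export
#' @examples
#' recording_conditions(voltage_mV = 200, electrolyte_M = 2.0)
recording_conditions <- function(temperature_K = 298.15, voltage_mV = 50,
                                 electrolyte_M = 0.1, ph = 7.4,
                                 lipid_composition = "POPC") {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K), temperature_K > 0)
  stopifnot(is.numeric(voltage_mV), length(voltage_mV) == 1L,
            is.finite(voltage_mV))
  stopifnot(is.numeric(electrolyte_M), length(electrolyte_M) == 1L,
            is.finite(electrolyte_M), electrolyte_M > 0)
  structure(list(temperature_K = temperature_K, voltage_mV = voltage_mV,
                 electrolyte_M = electrolyte_M, ph = ph,
                 lipid_composition = lipid_composition),
            class = "recording_conditions")
}

#' @export
print.recording_conditions <- function(x, ...) {
  cat(sprintf("Recording conditions: %s, %.2f K, V = %g mV, %.2g M KCl, pH %.1f\n",
              x$lipid_composition, x$temperature_K, x$voltage_mV,
              x$electrolyte_M, x$ph))
  invisible(x)
}

#' Valence of the permeant probe-ion complex
#'
#' The lipophilic carrier complex whose membrane conductance reports
#' boundary-potential changes. The default `z = +1` corresponds to the
#' K+-nonactin complex.
#'
#' @param z Signed integer valence; must be non-zero.
#' @return An object of class `charge_spec`.
#' @export
charge_spec <- function(z = 1L) {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z), z == round(z), z != 0)
  structure(list(z = as.integer(z)), class = "charge_spec")
}

#' Thermal voltage kT/e in mV
#'
#' @param temperature_K Absolute temperature in K.
#' @return kT/e in mV (25.693 mV at 298.15 K).
#' @export
thermal_voltage_mV <- function(temperature_K = 298.15) {
  stopifnot(is.finite(temperature_K), temperature_K > 0)
  .k_boltzmann * temperature_K / .e_charge * 1000
}
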