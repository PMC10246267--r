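# Physical constants (SI)
.FARADAY <- 96485.33212   # C / mol
.RGAS    <- 8.314462618   # J / (mol K)
.E0      <- 1.602176634e-19  # C, elementary charge

#' Default recording temperature
#'
#' All recordings emulated by this package are taken at 11.5 degC
#' (284.65 K), the temperature used for cut-open-oocyte work on Nav1.4.
#' @export
NAV_DEFAULT_TEMP_K <- 284.65

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_K absolute temperature (K)
#' @return RT/F in mV (about 24.53 mV at 284.65 K)
#' @export
thermal_voltage_mV <- function(temperature_K = NAV_DEFAULT_TEMP_K) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  1000 * .RGAS * temperature_K / .FARADAY
}

# internal: stop() with a classed condition so callers/tests can be specific
.nav_stop <- function(msg, class) {
  stop(structure(class = c(class, "navgate_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
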