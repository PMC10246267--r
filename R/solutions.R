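#' Recording solution pair
#'
#' Describes the permeant-ion composition on both sides of the membrane
#' plus the bath temperature. Concentrations are total Na+ and K+ in mM;
#' impermeant substitutes (NMG, MES) are implicit and never modelled.
#' The standard conditions are 57.5 mM Na+ outside / 12 mM Na+ inside for
#' ionic recordings, bionic 57.5 (or 90) Na+ out / 120 K+ in for
#' selectivity work, and all-NMG (all zero) for gating currents.
#'
#' @param na_out,k_out,na_in,k_in concentrations in mM, all >= 0
#' @param temperature_K bath temperature in kelvin (default 284.65 K,
#'   i.e. 11.5 degC)
#' @return an object of class `solution_pair`
#' @examples
#' solution_pair(na_out = 57.5, na_in = 12)            # ionic
#' solution_pair(na_out = 57.5, k_in = 120)            # bionic
#' solution_pair()                                     # all-NMG (gating)
#' @export
solution_pair <- function(na_out = 0, k_out = 0, na_in = 0, k_in = 0,
                          temperature_K = NAV_DEFAULT_TEMP_K) {
  conc <- c(na_out = na_out, k_out = k_out, na_in = na_in, k_in = k_in)
  if (!all(is.finite(conc)) || any(conc < 0))
    .nav_stop("solution concentrations must be finite and >= 0",
              "navgate_invalid_solution")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    .nav_stop("temperature must be a positive number of kelvin",
              "navgate_invalid_solution")
  structure(list(na_out = na_out, k_out = k_out,
                 na_in = na_in, k_in = k_in,
                 temperature_K = temperature_K),
            class = "solution_pair")
}

#' @export
print.solution_pair <- function(x, ...) {
  cat(sprintf(
    "<solution_pair> out: %g Na / %g K mM; in: %g Na / %g K mM; T = %.2f K\n",
    x$na_out, x$k_out, x$na_in, x$k_in, x$temperature_K))
  invisible(x)
}

.is_bionic <- function(sol) sol$k_out == 0 && sol$na_in == 0 &&
  sol$na_out > 0 && sol$k_in > 0
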