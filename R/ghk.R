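#' Goldman-Hodgkin-Katz current for a Na+/K+ solution pair
#'
#' Constant-field flux for monovalent cations,
#' \deqn{I_S = p_S P_{abs} \frac{z^2F^2V}{RT}
#'       \frac{[S]_i - [S]_o e^{-zFV/RT}}{1 - e^{-zFV/RT}},}
#' summed over Na+ and K+. `p_na` and `p_k` are dimensionless relative
#' permeabilities (open-state Na+ is 1 by convention) and `p_abs` sets the
#' absolute scale (cm^3/s per channel when concentrations are read as
#' mol/cm^3). Outward current is positive. At `V = 0` the analytic limit
#' \eqn{p_S P_{abs} z F ([S]_i - [S]_o)} is used; the implementation is
#' continuous through 0 mV.
#'
#' @param p_na,p_k relative permeabilities, >= 0
#' @param v_mV membrane potential in mV (finite scalar or vector)
#' @param sol a [solution_pair()]
#' @param p_abs absolute permeability scale (default 1; the simulator
#'   carries the per-fixture scale)
#' @return current per channel in amperes when `p_abs` is in cm^3/s
#'   (arbitrary units otherwise), same length as `v_mV`
#' @examples
#' sol <- solution_pair(na_out = 120, k_in = 120)
#' ghk_current(1, 1, 0, sol)   # symmetric bionic at 0 mV -> 0
#' @export
ghk_current <- function(p_na, p_k, v_mV, sol, p_abs = 1) {
  if (!inherits(sol, "solution_pair"))
    .nav_stop("`sol` must be a solution_pair", "navgate_invalid_input")
  if (!all(is.finite(v_mV)))
    .nav_stop("voltage must be finite", "navgate_invalid_input")
  if (!is.finite(p_na) || !is.finite(p_k) || p_na < 0 || p_k < 0)
    .nav_stop("permeabilities must be finite and >= 0",
              "navgate_invalid_input")
  vt <- thermal_voltage_mV(sol$temperature_K)     # mV
  u  <- v_mV / vt                                 # zFV/RT for z = +1
  # concentrations mM -> mol/cm^3
  flux1 <- function(ci_mM, co_mM) {
    ci <- ci_mM * 1e-6; co <- co_mM * 1e-6
    out <- numeric(length(u))
    small <- abs(u) < 1e-10
    if (any(!small)) {
      us <- u[!small]
      out[!small] <- .FARADAY * us *
        (ci - co * exp(-us)) / (-expm1(-us))
    }
    if (any(small)) out[small] <- .FARADAY * (ci - co)
    out
  }
  p_abs * (p_na * flux1(sol$na_in, sol$na_out) +
           p_k  * flux1(sol$k_in,  sol$k_out))
}

#' Zero-current (reversal) potential of the GHK flux sum
#'
#' Finds the root of [ghk_current()] in `interval` by bisection
#' (`stats::uniroot`). Under bionic conditions this matches the closed
#' form \eqn{V_{rev} = (RT/F)\,\ln(P_{Na}[Na]_o / (P_K [K]_i))} used by
#' [permeability_ratio()]; the root finder is kept general so the two
#' routes can be cross-checked.
#'
#' @inheritParams ghk_current
#' @param interval search interval in mV
#' @return reversal potential in mV
#' @export
ghk_reversal <- function(p_na, p_k, sol, interval = c(-300, 300)) {
  f <- function(v) ghk_current(p_na, p_k, v, sol)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    .nav_stop("reversal not bracketed in interval", "navgate_no_reversal")
  stats::uniroot(f, interval, tol = 1e-10)$root
}
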