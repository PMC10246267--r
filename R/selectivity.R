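#' Instantaneous I-V points at one depolarization time
#'
#' From an `"instantaneous_iv"` family (fixed depolarization duration,
#' varied tail voltage), samples the current a fixed short latency after
#' the tail step — after the capacitive blank, before the occupancies
#' have moved — giving the I-V relation of whatever mixture of
#' conducting states is occupied at that instant.
#'
#' @param ts `traceset` from the `"instantaneous_iv"` protocol
#' @param t_depol_ms which depolarization duration to extract
#' @param latency_ms sampling latency after the tail step (default 0.2)
#' @param blank_ms capacitive blank; `latency_ms` must exceed it
#' @param current current column
#' @return data.frame `v_tail_mV`, `i_uA`
#' @export
instantaneous_iv <- function(ts, t_depol_ms, latency_ms = 0.2,
                             blank_ms = 0.15, current = "i_uA") {
  if (latency_ms <= blank_ms)
    .nav_stop("sampling latency lies inside the capacitive blank",
              "navgate_bad_input")
  td <- .ts_info(ts, "t_depol_ms")
  sel <- which(abs(td - t_depol_ms) < 1e-9)
  if (!length(sel))
    .nav_stop("no sweeps with that depolarization duration",
              "navgate_bad_input")
  v <- i <- numeric(length(sel))
  for (j in seq_along(sel)) {
    sw <- ts$sweeps[[sel[j]]]
    ep <- .ts_epoch(sw, "tail")
    if (is.null(ep)) .nav_stop("sweep is missing its tail epoch",
                               "navgate_missing_epoch")
    tr <- .sweep_trace(sw)
    i[j] <- stats::approx(tr$time_ms, tr[[current]],
                          xout = ep$t0_ms + latency_ms)$y
    v[j] <- sw$info$tail_mV
  }
  ord <- order(v)
  data.frame(v_tail_mV = v[ord], i_uA = i[ord])
}

#' Reversal potential as a function of depolarization time
#'
#' For every depolarization duration present in the family, builds the
#' instantaneous I-V and intersects its linear fit with the voltage
#' axis.
#'
#' @inheritParams instantaneous_iv
#' @param n_side points each side of the zero crossing in the linear fit
#' @return data.frame `t_ms`, `v_rev_mV`, `se_mV`
#' @export
reversal_vs_time <- function(ts, latency_ms = 0.2, blank_ms = 0.15,
                             n_side = 2, current = "i_uA") {
  td <- sort(unique(.ts_info(ts, "t_depol_ms")))
  td <- td[is.finite(td)]
  if (length(td) < 3)
    .nav_stop("need >= 3 depolarization times", "navgate_bad_input")
  out <- lapply(td, function(t1) {
    iv <- instantaneous_iv(ts, t1, latency_ms, blank_ms, current)
    r <- .linear_reversal(iv$v_tail_mV, iv$i_uA, n_side)
    data.frame(t_ms = t1, v_rev_mV = r$v_rev, se_mV = r$se)
  })
  do.call(rbind, out)
}

#' Na+/K+ permeability ratio from a bionic reversal potential
#'
#' Inverts the GHK reversal relation
#' \eqn{V_{rev} = (RT/F) \ln(P_{Na}[Na]_o / (P_K [K]_i))}:
#' \deqn{P_{Na}/P_K = ([K]_i / [Na]_o)\, e^{V_{rev} F / RT}.}
#' Only valid under bionic conditions (Na+ outside only, K+ inside
#' only); other solutions raise an error pointing to [ghk_reversal()]
#' for the full-GHK route.
#'
#' @param v_rev_mV reversal potential(s) in mV
#' @param sol a bionic [solution_pair()]
#' @return P_Na/P_K (same length as `v_rev_mV`)
#' @export
permeability_ratio <- function(v_rev_mV, sol) {
  if (!.is_bionic(sol))
    .nav_stop("permeability_ratio needs bionic solutions (Na out / K in); use ghk_reversal() for the general case",
              "navgate_not_bionic")
  vt <- thermal_voltage_mV(sol$temperature_K)
  (sol$k_in / sol$na_out) * exp(v_rev_mV / vt)
}

#' Time course of the Na+/K+ permeability ratio
#'
#' Converts a reversal-vs-time series to P_Na/P_K(t), fits a 1- or
#' 2-component exponential decay toward an asymptote, and (optionally)
#' compares the fast permeability time constant against a supplied set
#' of inactivation time constants with a Welch t test.
#'
#' @param series data.frame from [reversal_vs_time()]
#' @param sol bionic [solution_pair()]
#' @param tau_inact_ms optional vector of inactivation time constants
#' @return a `perm_time_course`: `t_ms`, `v_rev_mV`, `p_ratio`,
#'   `p_start`, `p_inf` (fitted asymptote), `tau_perm_fast_ms`, `fit`,
#'   `welch` (htest or NULL), `constant` flag
#' @export
permeability_time_course <- function(series, sol, tau_inact_ms = NULL) {
  if (nrow(series) < 4)
    .nav_stop("need >= 4 time points", "navgate_bad_input")
  p <- permeability_ratio(series$v_rev_mV, sol)
  t <- series$t_ms
  fit <- .fit_association(t, p)   # y0 + sum a_i (1 - e^(-t/theta))
  # a decay toward p_inf is an association with negative amplitudes;
  # p(0) = y0, p_inf = y0 + sum(a)
  p_inf <- fit$y0 + sum(fit$amplitudes)
  rng <- diff(range(p))
  constant <- rng < 0.02 * max(abs(p))
  tau_fast <- if (constant) NA_real_ else fit$theta_fast
  welch <- NULL
  if (!is.null(tau_inact_ms) && !constant && is.finite(tau_fast)) {
    welch <- if (length(tau_inact_ms) > 1)
      stats::t.test(tau_inact_ms, mu = tau_fast)
    else NULL
  }
  structure(list(t_ms = t, v_rev_mV = series$v_rev_mV, p_ratio = p,
                 p_start = fit$y0, p_inf = p_inf,
                 tau_perm_fast_ms = tau_fast,
                 tau_perm_fast_se = fit$theta_fast_se,
                 fit = fit, welch = welch, constant = constant),
            class = "perm_time_course")
}

#' @export
print.perm_time_course <- function(x, ...) {
  cat(sprintf("<perm_time_course> P_Na/P_K %.2f -> %.2f, fast tau %.3g ms%s\n",
              x$p_start, x$p_inf, x$tau_perm_fast_ms,
              if (x$constant) " (constant series)" else ""))
  invisible(x)
}
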