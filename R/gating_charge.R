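#' Two-exponential decomposition of an off-gating current
#'
#' Off-gating currents after a conditioning depolarization decay with a
#' fast component (freely returning charge) and, once channels have
#' inactivated, a slow component carrying the immobilized DIII/DIV
#' charge. This is [fit_exponentials()] with `n = 2` and the steady
#' level forced to zero.
#'
#' @param sweep sweep or data.frame
#' @param off_window `(t0, t1)` ms of the repolarization epoch; default
#'   the epoch tagged "off"
#' @param blank_ms dead time after the step
#' @param current current column
#' @return an `exp_decomposition` (components fast to slow)
#' @export
decompose_off_gating <- function(sweep, off_window = NULL, blank_ms = 0.15,
                                 current = "i_uA") {
  if (is.null(off_window)) {
    ep <- .ts_epoch(sweep, "off") %||% .ts_epoch(sweep, "post")
    if (is.null(ep)) .nav_stop("no off window and no off epoch",
                               "navgate_bad_window")
    off_window <- c(ep$t0_ms, ep$t1_ms)
  }
  fit_exponentials(sweep, n = 2, window = off_window, blank_ms = blank_ms,
                   fix_ss_zero = TRUE, current = current)
}

#' Immobilized charge fraction from an off-gating decomposition
#'
#' \deqn{f_{imm} = |A_{slow}\tau_{slow}| / Q_{total}.}
#' `Q_total` is either supplied directly (nC, e.g. the integral of the
#' off-gating current, the default analysis mode) or computed as the sum
#' of the fitted components `|A_f tau_f| + |A_s tau_s|`
#' (`total = "components"`).
#'
#' The slow (immobilized) component must live on the immobilization
#' time scale: a fitted component counts as slow only if its time
#' constant is at least `slow_min_ms` (off-gating after short, barely
#' inactivating prepulses decays on sub-millisecond scales only, and a
#' two-component fit of such a record splits it into two *fast*
#' components, neither of which is trapped charge).
#'
#' @param d an `exp_decomposition` with 2 components
#' @param total `"components"` or a positive total charge in nC
#' @param slow_min_ms smallest time constant that counts as immobilized
#' @return fraction in `[0, 1]`
#' @export
immobilized_fraction <- function(d, total = "components",
                                 slow_min_ms = 1) {
  comps <- d$components
  qs <- abs(comps$A * comps$tau)        # uA * ms = nC
  slow <- comps$tau >= slow_min_ms & comps$tau > min(comps$tau)
  q_slow <- sum(qs[slow])
  q_tot <- if (identical(total, "components")) sum(qs) else as.numeric(total)
  if (!is.finite(q_tot) || q_tot <= 0)
    .nav_stop("total charge must be > 0", "navgate_bad_input")
  min(max(q_slow / q_tot, 0), 1)
}

# integral |Q| of a current over a window, baseline-subtracted (trapezoid)
.integrate_charge <- function(sweep, window, blank_ms = 0.15,
                              current = "i_uA", baseline = NULL) {
  tr <- .sweep_trace(sweep)
  sel <- .in_window(tr$time_ms, c(window[1] + blank_ms, window[2]))
  t <- tr$time_ms[sel]; i <- tr[[current]][sel]
  if (is.null(baseline)) {
    bs <- .in_window(tr$time_ms, c(window[2] - 0.1 * diff(window), window[2]))
    baseline <- mean(tr[[current]][bs])
  }
  i <- i - baseline
  sum(diff(t) * (utils::head(i, -1) + utils::tail(i, -1)) / 2)
}

#' Charge immobilization versus conditioning duration
#'
#' Runs [decompose_off_gating()] on every sweep of a conditioning
#' duration family, computes the immobilized fraction per duration, and
#' fits a single-exponential onset.
#'
#' @param ts `traceset` from the `"immobilization_family"` protocol
#' @param mode `"integral"` (denominator = off-current integral, the
#'   default) or `"components"`
#' @param blank_ms dead time after the repolarizing step
#' @param current current column
#' @return an `immobilization_curve`: `durations_ms`, `fraction`,
#'   `onset_tau_ms`, `asymptote`, per-sweep decompositions
#' @export
immobilization_course <- function(ts, mode = c("integral", "components"),
                                  blank_ms = 0.05, current = "i_uA",
                                  slow_min_ms = 1) {
  mode <- match.arg(mode)
  durs <- .ts_info(ts, "dur_ms")
  if (length(durs) < 4 || anyNA(durs))
    .nav_stop("need >= 4 conditioning durations", "navgate_bad_input")
  frac <- numeric(length(durs)); fits <- vector("list", length(durs))
  for (i in seq_along(ts$sweeps)) {
    ep <- .ts_epoch(ts$sweeps[[i]], "off")
    d <- decompose_off_gating(ts$sweeps[[i]], c(ep$t0_ms, ep$t1_ms),
                              blank_ms = blank_ms, current = current)
    fits[[i]] <- d
    frac[i] <- if (mode == "components")
      immobilized_fraction(d, slow_min_ms = slow_min_ms)
    else {
      q <- abs(.integrate_charge(ts$sweeps[[i]], c(ep$t0_ms, ep$t1_ms),
                                 blank_ms = blank_ms, current = current))
      immobilized_fraction(d, total = q, slow_min_ms = slow_min_ms)
    }
  }
  ord <- order(durs)
  durs <- durs[ord]; frac <- frac[ord]; fits <- fits[ord]
  onset <- .fit_association(durs, frac, max_k = 1)
  structure(list(durations_ms = durs, fraction = frac, fits = fits,
                 onset_tau_ms = onset$theta[1],
                 asymptote = onset$y0 + sum(onset$amplitudes)),
            class = "immobilization_curve")
}

#' Q-V curve from a voltage family of gating-current sweeps
#'
#' Integrates the on-gating current per test voltage (window from the
#' step until |I_g| falls below 1 percent of its peak, or the epoch
#' end), normalizes to the maximal charge, and fits the rising two-state
#' Boltzmann \eqn{Q_{norm} = 1/(1 + e^{-z_Q F (V - V_{Q1/2})/RT})}.
#'
#' @param ts `traceset` of a voltage family recorded in gating solutions
#' @param blank_ms dead time after the step (default 0: at strong
#'   depolarizations most of the charge moves within the first 100 us,
#'   and P/N-subtracted gating records resolve from the step itself)
#' @param current current column
#' @return a `boltzmann_curve`; the per-voltage charges are in
#'   `$charge_nC`
#' @export
qv_curve <- function(ts, blank_ms = 0, current = "i_uA") {
  vs <- .ts_info(ts, "test_mV")
  if (length(vs) < 6)
    .nav_stop("need >= 6 voltages for a Q-V curve", "navgate_bad_input")
  q <- numeric(length(vs))
  for (i in seq_along(ts$sweeps)) {
    ep <- .ts_epoch(ts$sweeps[[i]], "test") %||%
      .ts_epoch(ts$sweeps[[i]], "cond")
    tr <- .sweep_trace(ts$sweeps[[i]])
    sel <- .in_window(tr$time_ms, c(ep$t0_ms + blank_ms, ep$t1_ms))
    t <- tr$time_ms[sel]; ig <- tr[[current]][sel]
    pk <- max(abs(ig))
    below <- which(abs(ig) < 0.01 * pk & t > t[which.max(abs(ig))])
    t_end <- if (length(below)) t[below[1]] else ep$t1_ms
    keep <- t <= t_end
    q[i] <- sum(diff(t[keep]) * (utils::head(ig[keep], -1) +
                                   utils::tail(ig[keep], -1)) / 2)
  }
  ord <- order(vs)
  vs <- vs[ord]; q <- q[ord]
  qn <- q / max(abs(q))
  bc <- boltzmann_fit(vs, qn, direction = "rising", with_base = FALSE,
                      temperature_K = .ts_solution(ts)$temperature_K)
  bc$charge_nC <- q
  bc
}
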