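# --- window helpers -------------------------------------------------------

# accept a traceset sweep (list with $trace) or a bare data.frame with
# time_ms and a current column
.sweep_trace <- function(sweep) {
  if (is.data.frame(sweep)) return(sweep)
  if (is.list(sweep) && !is.null(sweep$trace)) return(sweep$trace)
  .nav_stop("expected a sweep or a data.frame(time_ms, i_uA)",
            "navgate_bad_sweep")
}

# half-open on the right so the sample sitting exactly on an epoch
# boundary (which already carries the next epoch's voltage) is excluded
.in_window <- function(t, w) t >= w[1] & t < w[2] - 1e-12

#' Peak and steady-state current of a sweep
#'
#' The peak is the signed extremum of the baseline-subtracted current in
#' `peak_window` (baseline = mean over the 1 ms immediately before the
#' window); the steady-state level is the mean over `steady_window`
#' (default: the last 10 percent of the peak window). A blank of
#' `blank_ms` after the window start is skipped so clamp transients do
#' not masquerade as peaks.
#'
#' @param sweep a traceset sweep or data.frame with `time_ms`, `i_uA`
#' @param peak_window,steady_window `(t0, t1)` in ms; if omitted and the
#'   sweep carries epoch roles, the "test" epoch is used
#' @param blank_ms dead time after the step (default 0.15 ms)
#' @param current column to analyse (default `"i_uA"`)
#' @param baseline_mode `"pre"` (mean of the 1 ms before the window,
#'   the default) or `"zero"` (absolute currents; appropriate after P/N
#'   subtraction when channels may already conduct before the step)
#' @return list with `i_peak`, `i_ss`, `ratio` ( = i_ss / i_peak),
#'   `baseline`
#' @export
peak_and_steady <- function(sweep, peak_window = NULL, steady_window = NULL,
                            blank_ms = 0.15, current = "i_uA",
                            baseline_mode = c("pre", "zero")) {
  baseline_mode <- match.arg(baseline_mode)
  tr <- .sweep_trace(sweep)
  if (is.null(peak_window)) {
    ep <- .ts_epoch(sweep, "test") %||% .ts_epoch(sweep, "depol")
    if (is.null(ep)) .nav_stop("no peak window and no test epoch",
                               "navgate_bad_window")
    peak_window <- c(ep$t0_ms, ep$t1_ms)
  }
  if (is.null(steady_window))
    steady_window <- c(peak_window[2] - 0.1 * diff(peak_window),
                       peak_window[2])
  t <- tr$time_ms; i <- tr[[current]]
  base_sel <- t >= peak_window[1] - 1 & t < peak_window[1]
  baseline <- if (baseline_mode == "pre" && any(base_sel))
    mean(i[base_sel]) else 0
  psel <- .in_window(t, c(peak_window[1] + blank_ms, peak_window[2]))
  ssel <- .in_window(t, steady_window)
  if (!any(psel) || !any(ssel))
    .nav_stop("empty analysis window", "navgate_bad_window")
  ib <- i - baseline
  i_peak <- ib[psel][which.max(abs(ib[psel]))]
  i_ss <- mean(ib[ssel])
  list(i_peak = i_peak, i_ss = i_ss, ratio = i_ss / i_peak,
       baseline = baseline)
}

# --- exponential decomposition (variable projection) ----------------------

.varpro_rss <- function(log_tau, tt, y, fix_ss) {
  taus <- exp(log_tau)
  X <- exp(-outer(tt, 1 / taus))
  if (!fix_ss) X <- cbind(X, 1)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(list(rss = Inf))
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

# numerical jacobian-based standard errors for (A_i, tau_i[, i_ss])
.exp_se <- function(tt, y, A, tau, iss, fix_ss) {
  f <- function(p) {
    k <- length(tau)
    a <- p[seq_len(k)]; tv <- p[k + seq_len(k)]
    yhat <- rowSums(exp(-outer(tt, 1 / tv)) *
                      matrix(a, length(tt), k, byrow = TRUE))
    if (!fix_ss) yhat <- yhat + p[2 * k + 1]
    yhat
  }
  p0 <- c(A, tau, if (!fix_ss) iss)
  J <- matrix(0, length(tt), length(p0))
  h <- pmax(abs(p0), 1e-6) * 1e-6
  for (j in seq_along(p0)) {
    pp <- p0; pp[j] <- pp[j] + h[j]
    pm <- p0; pm[j] <- pm[j] - h[j]
    J[, j] <- (f(pp) - f(pm)) / (2 * h[j])
  }
  r <- y - f(p0)
  dof <- max(length(tt) - length(p0), 1)
  s2 <- sum(r^2) / dof
  cv <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, length(p0)))
  sqrt(pmax(diag(cv), 0))
}

#' Fit a 1- or 2-exponential decay (plus steady level) to a sweep
#'
#' Nonlinear least squares of
#' \eqn{I(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + I_{SS}}
#' by variable projection over the time constants (amplitudes and offset
#' solved linearly), with a multi-start grid over log-spaced time
#' constants. With `n = "auto"` the two-component model is accepted only
#' if it improves the fit by an F-test at `f_test_p`.
#'
#' @param sweep sweep or data.frame (`time_ms` + current column)
#' @param n 1, 2 or `"auto"`
#' @param window `(t0, t1)` ms; fitting starts `blank_ms` after `t0`
#' @param blank_ms dead time skipped after the window start
#' @param fix_ss_zero force the steady level to 0 (off-gating currents)
#' @param f_test_p threshold for upgrading 1 -> 2 components
#' @param current current column name
#' @return an `exp_decomposition`: `components` (data.frame `A`, `tau`,
#'   fast to slow, with standard errors), `i_ss`, `window`, `rss`,
#'   `n_points`
#' @export
fit_exponentials <- function(sweep, n = 1, window = NULL, blank_ms = 0.15,
                             fix_ss_zero = FALSE, f_test_p = 0.01,
                             current = "i_uA") {
  tr <- .sweep_trace(sweep)
  if (is.null(window)) window <- range(tr$time_ms)
  sel <- .in_window(tr$time_ms, c(window[1] + blank_ms, window[2]))
  tt <- tr$time_ms[sel] - (window[1] + blank_ms)
  y <- tr[[current]][sel]
  auto <- identical(n, "auto")
  if (!auto && !(n %in% c(1, 2)))
    .nav_stop("n must be 1, 2 or 'auto'", "navgate_bad_input")
  if (length(tt) < 10 * if (auto) 2 else n)
    .nav_stop("too few points in window for the requested model",
              "navgate_bad_window")

  fit_n <- function(k) {
    span <- max(tt)
    cand <- span * c(0.01, 0.03, 0.1, 0.3, 1)
    starts <- if (k == 1) as.list(log(cand)) else {
      out <- list()
      for (i in seq_along(cand)) for (j in seq_along(cand))
        if (j > i) out[[length(out) + 1]] <- log(c(cand[i], cand[j]))
      out
    }
    lo <- log(max(min(diff(tt)), 1e-6) / 2); hi <- log(span * 50)
    obj <- function(p) {
      if (any(p < lo) || any(p > hi)) return(1e30)
      .varpro_rss(p, tt, y, fix_ss_zero)$rss
    }
    best <- NULL
    for (s in starts) {
      o <- if (k == 1) {
        op <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
        list(par = op$minimum, value = op$objective)
      } else stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
      if (k == 1) break
    }
    if (!is.finite(best$value))
      .nav_stop(sprintf("exponential fit failed to converge (n=%d, %d starts, window %.3g-%.3g ms)",
                        k, length(starts), window[1], window[2]),
                "navgate_fit_failure")
    vp <- .varpro_rss(best$par, tt, y, fix_ss_zero)
    taus <- exp(best$par)
    A <- unname(vp$coef[seq_len(k)])
    iss <- if (fix_ss_zero) 0 else unname(vp$coef[k + 1])
    ord <- order(taus)
    se <- .exp_se(tt, y, A[ord], taus[ord], iss, fix_ss_zero)
    list(A = A[ord], tau = taus[ord], i_ss = iss, rss = best$value,
         se = se)
  }

  f1 <- fit_n(1)
  res <- if (auto || n == 2) {
    f2 <- fit_n(2)
    if (auto) {
      dof2 <- length(tt) - (4 + !fix_ss_zero)
      Fst <- ((f1$rss - f2$rss) / 2) / (f2$rss / max(dof2, 1))
      p <- stats::pf(Fst, 2, max(dof2, 1), lower.tail = FALSE)
      if (is.finite(p) && p < f_test_p) f2 else f1
    } else f2
  } else f1

  k <- length(res$tau)
  comps <- data.frame(A = res$A, tau = res$tau,
                      A_se = res$se[seq_len(k)],
                      tau_se = res$se[k + seq_len(k)])
  structure(list(components = comps, i_ss = res$i_ss,
                 i_ss_se = if (fix_ss_zero) 0 else res$se[2 * k + 1],
                 window = window, rss = res$rss, n_points = length(tt)),
            class = "exp_decomposition")
}

#' @export
print.exp_decomposition <- function(x, ...) {
  cat(sprintf("<exp_decomposition> %d component(s), i_ss = %.4g, rss = %.3g\n",
              nrow(x$components), x$i_ss, x$rss))
  print(x$components, digits = 4)
  invisible(x)
}

#' Amplitude-weighted time constant
#'
#' \eqn{\tau_W = (|A_1|\tau_1 + |A_2|\tau_2) / (|A_1| + |A_2|)}; a single
#' component returns its own time constant. Invariant to rescaling all
#' amplitudes, and always inside `[min tau, max tau]`.
#'
#' @param d an `exp_decomposition` (or data.frame with `A`, `tau`)
#' @return weighted time constant in ms
#' @export
weighted_tau <- function(d) {
  comps <- if (inherits(d, "exp_decomposition")) d$components else d
  w <- abs(comps$A)
  if (sum(w) == 0) .nav_stop("all amplitudes are zero", "navgate_bad_input")
  sum(w * comps$tau) / sum(w)
}

#' Tail-current kinetics versus depolarization duration
#'
#' For a variable-duration family (protocol `"tail_duration_family"`),
#' fits every tail (model order auto-selected), computes the weighted
#' time constant per depolarization duration, and fits the resulting
#' course with 1- or 2-component exponential association
#' \eqn{\tau_W(t) = y_0 + \sum_i a_i (1 - e^{-t/\theta_i})}. The fast
#' association time constant is returned for comparison against the
#' inactivation time constant.
#'
#' @param ts a `traceset` from the tail-duration protocol
#' @param blank_ms dead time after the tail step
#' @param current current column
#' @return a `tail_course`: `durations_ms`, `tau_w_ms`, per-tail fits,
#'   association fit (`assoc`), `tau_assoc_fast_ms`
#' @export
tail_time_course <- function(ts, blank_ms = 0.15, current = "i_uA") {
  durs <- .ts_info(ts, "dur_ms")
  if (length(durs) < 4 || anyNA(durs))
    .nav_stop("need >= 4 depolarization durations", "navgate_bad_input")
  fits <- vector("list", length(ts$sweeps))
  tw <- numeric(length(ts$sweeps))
  for (i in seq_along(ts$sweeps)) {
    ep <- .ts_epoch(ts$sweeps[[i]], "tail")
    if (is.null(ep)) .nav_stop("sweep is missing its tail epoch",
                               "navgate_missing_epoch")
    fits[[i]] <- fit_exponentials(ts$sweeps[[i]], n = "auto",
                                  window = c(ep$t0_ms, ep$t1_ms),
                                  blank_ms = blank_ms, current = current)
    tw[i] <- weighted_tau(fits[[i]])
  }
  ord <- order(durs)
  durs <- durs[ord]; tw <- tw[ord]; fits <- fits[ord]
  assoc <- .fit_association(durs, tw)
  structure(list(durations_ms = durs, tau_w_ms = tw, fits = fits,
                 assoc = assoc,
                 tau_assoc_fast_ms = assoc$theta_fast,
                 tau_assoc_fast_se = assoc$theta_fast_se),
            class = "tail_course")
}

# exponential association by the same variable-projection trick
.fit_association <- function(t, y, max_k = 2) {
  rss_for <- function(lth) {
    th <- exp(lth)
    X <- cbind(1, 1 - exp(-outer(t, 1 / th)))
    fit <- stats::lm.fit(X, y)
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }
  span <- max(t)
  fit_k <- function(k) {
    cand <- span * c(0.02, 0.1, 0.5, 2)
    starts <- if (k == 1) as.list(log(cand)) else {
      out <- list()
      for (i in seq_along(cand)) for (j in seq_along(cand))
        if (j > i) out[[length(out) + 1]] <- log(c(cand[i], cand[j]))
      out
    }
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, function(p) rss_for(p)$rss,
                        method = if (k == 1) "Brent" else "Nelder-Mead",
                        lower = if (k == 1) log(span * 1e-3) else -Inf,
                        upper = if (k == 1) log(span * 1e3) else Inf,
                        control = list(reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(theta = exp(best$par), rss = best$value,
         coef = rss_for(best$par)$coef)
  }
  n1 <- fit_k(1)
  ans <- if (length(t) >= 6 && max_k >= 2) {
    n2 <- fit_k(2)
    dof <- length(t) - 5
    Fst <- ((n1$rss - n2$rss) / 2) / (n2$rss / max(dof, 1))
    p <- stats::pf(Fst, 2, max(dof, 1), lower.tail = FALSE)
    if (is.finite(p) && p < 0.05) n2 else n1
  } else n1
  ans$coef <- unname(ans$coef)
  amp <- ans$coef[-1]
  # fast theta among components with non-negligible amplitude
  keep <- abs(amp) > 0.01 * max(abs(amp), 1e-12)
  theta_fast <- if (any(keep)) min(ans$theta[keep]) else NA_real_
  # crude SE from the curvature of the profiled RSS in log theta
  se <- tryCatch({
    lt <- log(theta_fast); h <- 0.05
    i_fast <- which(ans$theta == theta_fast)[1]
    pr <- function(d) {
      th <- ans$theta; th[i_fast] <- exp(lt + d)
      X <- cbind(1, 1 - exp(-outer(t, 1 / th)))
      sum(stats::lm.fit(X, y)$residuals^2)
    }
    d2 <- (pr(h) - 2 * pr(0) + pr(-h)) / h^2
    s2 <- ans$rss / max(length(t) - (2 * length(ans$theta) + 1), 1)
    if (d2 > 0) theta_fast * sqrt(2 * s2 / d2) else NA_real_
  }, error = function(e) NA_real_)
  list(y0 = ans$coef[1], amplitudes = amp, theta = ans$theta,
       rss = ans$rss, theta_fast = theta_fast, theta_fast_se = se)
}
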