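#' Two-state Boltzmann fit
#'
#' Fits either the rising form used for G-V and Q-V curves,
#' \deqn{y = y_{max} / (1 + e^{-z F (V - V_{1/2}) / RT}),}
#' or the falling availability form used for h-infinity curves,
#' \deqn{y = Base + (1 - Base) / (1 + e^{z F (V - V_{1/2}) / RT}),}
#' which tends to 1 at hyperpolarized potentials. `z` is reported
#' positive in both conventions. The linear parameters (scale, base) are
#' profiled out; `V_1/2` and `log z` are optimized from a coarse grid of
#' starts. Standard errors come from the local quadratic expansion of
#' the residual sum of squares.
#'
#' @param x voltages (mV)
#' @param y observed normalized values
#' @param direction `"rising"` (G-V / Q-V) or `"falling"` (h-infinity)
#' @param with_base fit a non-zero floor (`Base`); default TRUE only for
#'   falling fits
#' @param temperature_K temperature defining RT/F
#' @return a `boltzmann_curve`: `x`, `y`, `v_half`, `z_app`, `base`,
#'   `scale`, `fitted`, standard errors `v_half_se`, `z_se`
#' @export
boltzmann_fit <- function(x, y, direction = c("rising", "falling"),
                          with_base = NULL,
                          temperature_K = NAV_DEFAULT_TEMP_K) {
  direction <- match.arg(direction)
  if (is.null(with_base)) with_base <- direction == "falling"
  stopifnot(length(x) == length(y), length(x) >= 4)
  vt <- thermal_voltage_mV(temperature_K)
  sgn <- if (direction == "rising") 1 else -1
  basis <- function(vh, z) 1 / (1 + exp(-sgn * z * (x - vh) / vt))
  lin <- function(p) {
    g <- basis(p[1], exp(p[2]))
    X <- if (with_base) cbind(g, 1) else cbind(g)
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    # a negative floor is unphysical for availability data: refit with
    # the base clamped to zero
    if (with_base && cf[2] < 0) {
      f0 <- stats::lm.fit(cbind(g), y)
      cf <- c(f0$coefficients, 0)
      return(list(rss = sum(f0$residuals^2), coef = cf, g = g))
    }
    # tiny ridge on the sigmoid amplitude breaks the tie on flat input
    # (no inactivation): the fit then collapses onto base = mean(y)
    list(rss = sum(fit$residuals^2) + 1e-7 * sum(y^2) * cf[1]^2,
         coef = cf, g = g)
  }
  starts <- expand.grid(vh = stats::quantile(x, c(0.2, 0.5, 0.8)),
                        lz = log(c(0.5, 1.5, 4)))
  # apparent charge restricted to a physically meaningful window; an
  # unbounded z runs away on step-like input and the fit degenerates
  obj <- function(p) {
    if (p[1] < min(x) - 100 || p[1] > max(x) + 100 ||
        p[2] < log(0.05) || p[2] > log(12)) return(1e30)
    lin(p)$rss
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 1000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value))
    .nav_stop("Boltzmann fit failed to converge", "navgate_fit_failure")
  sol <- lin(best$par)
  v_half <- unname(best$par[1]); z <- unname(exp(best$par[2]))
  scale <- unname(sol$coef[1])
  base <- if (with_base) unname(sol$coef[2]) else 0
  fitted <- scale * sol$g + base
  # SEs from numerical curvature of rss over (v_half, log z)
  se <- tryCatch({
    h <- c(0.1, 0.01)
    H <- matrix(0, 2, 2)
    f0 <- best$value
    for (a in 1:2) for (b in 1:2) {
      ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
      H[a, b] <- (lin(best$par + ea + eb)$rss - lin(best$par + ea)$rss -
                    lin(best$par + eb)$rss + f0) / (h[a] * h[b])
    }
    dof <- max(length(x) - (2 + ncol(if (with_base) cbind(1, 1) else cbind(1))), 1)
    cv <- 2 * (f0 / dof) * solve(H)
    c(sqrt(max(cv[1, 1], 0)), z * sqrt(max(cv[2, 2], 0)))
  }, error = function(e) c(NA_real_, NA_real_))
  structure(list(x = x, y = y, v_half = v_half, z_app = z,
                 base = base, scale = scale, fitted = fitted,
                 v_half_se = se[1], z_se = se[2],
                 direction = direction, rss = best$value),
            class = "boltzmann_curve")
}

#' @export
print.boltzmann_curve <- function(x, ...) {
  cat(sprintf("<boltzmann_curve> %s: V1/2 = %.2f mV (se %.2f), z = %.2f e0 (se %.2f), base = %.3f\n",
              x$direction, x$v_half, x$v_half_se, x$z_app, x$z_se, x$base))
  invisible(x)
}
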