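# Occupancy over one constant-voltage epoch, p(t) = expm(A t) p0.
# Uses the eigendecomposition of A (vectorized over all sample times,
# exact for diagonalizable generators); falls back to per-step matrix
# exponentials (Matrix::expm, scaling-and-squaring) if A is close to
# defective. Both routes are exact propagators for piecewise-constant
# voltage, no ODE stepping involved.
.occupancy_epoch <- function(A, p0, tvec) {
  n <- nrow(A)
  eg <- eigen(A)
  Vm <- eg$vectors
  ok <- is.finite(rcond(Vm)) && rcond(Vm) > 1e-12
  if (ok) {
    c0 <- solve(Vm, p0)
    E <- exp(outer(eg$values, tvec))          # n x length(tvec)
    occ <- Re(Vm %*% (E * c0))
  } else {
    occ <- matrix(NA_real_, n, length(tvec))
    dts <- diff(c(0, tvec))
    # uniform grids (the usual case) need a single matrix exponential
    uni <- length(dts) > 1 && diff(range(dts[-1])) < 1e-12
    M <- if (uni) as.matrix(Matrix::expm(A * dts[2])) else NULL
    p <- p0
    for (j in seq_along(tvec)) {
      p <- if (uni && j > 1) as.numeric(M %*% p)
           else as.numeric(as.matrix(Matrix::expm(A * dts[j])) %*% p)
      occ[, j] <- p
    }
  }
  rownames(occ) <- rownames(A)
  occ
}

#' Propagate a gating scheme through a voltage-clamp protocol
#'
#' Advances the master equation exactly per constant-voltage epoch
#' (eigendecomposition / matrix exponential of the generator) and emits,
#' per sweep, the state occupancies, the ionic current
#' \eqn{I_{ion} = N \sum_s P_s(t)\, I_{GHK}(s, V)} and the gating current
#' \eqn{I_g = N e_0 \sum_{i\to j} q_{ij} k_{ij}(V) P_i(t)}
#' (both in uA, outward positive).
#'
#' @param scheme a [gating_scheme()]
#' @param protocol a [nav_protocol()]
#' @param sol a [solution_pair()]; its temperature sets RT/F
#' @param init `"equilibrium"` (stationary distribution at the holding
#'   potential) or a named occupancy vector summing to 1
#' @param keep_occupancy keep the per-sample occupancy matrix on each
#'   sweep (needed by conservation checks; default TRUE)
#' @return a `traceset` (see [write_traceset()]) whose sweeps carry
#'   `time_ms`, `v_mV`, `i_ionic_uA`, `i_gating_uA`, `i_uA`
#' @export
propagate <- function(scheme, protocol, sol, init = "equilibrium",
                      keep_occupancy = TRUE) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(protocol, "nav_protocol"),
            inherits(sol, "solution_pair"))
  vt <- thermal_voltage_mV(sol$temperature_K)
  sn <- scheme$states$name
  if (identical(init, "equilibrium")) {
    p0 <- steady_state(scheme, protocol$holding_mV, sol$temperature_K)
  } else {
    if (is.null(names(init))) names(init) <- sn
    if (abs(sum(init) - 1) > 1e-8)
      .nav_stop("init occupancy must sum to 1", "navgate_bad_init")
    p0 <- init[sn]
  }
  from_i <- match(scheme$transitions$from, sn)
  sweeps <- lapply(protocol$sweeps, function(sw) {
    e <- sw$epochs
    t1 <- cumsum(e$dur_ms); t0 <- c(0, t1[-length(t1)])
    total <- t1[length(t1)]
    tg <- seq(0, total, by = protocol$sample_ms)
    ep_of <- findInterval(tg, t0, rightmost.closed = FALSE)
    ep_of[ep_of > nrow(e)] <- nrow(e)
    occ <- matrix(NA_real_, length(sn), length(tg), dimnames = list(sn, NULL))
    ii <- ig <- numeric(length(tg))
    p <- p0
    for (k in seq_len(nrow(e))) {
      A <- .rate_matrix(scheme, e$v_mV[k], vt)
      sel <- which(ep_of == k)
      tloc <- tg[sel] - t0[k]
      if (length(sel)) {
        occ[, sel] <- .occupancy_epoch(A, p, tloc)
        # currents with this epoch's voltage (right-continuous at steps)
        gs <- vapply(seq_along(sn), function(s)
          ghk_current(scheme$states$p_na[s], scheme$states$p_k[s],
                      e$v_mV[k], sol, scheme$p_abs), 0)
        ii[sel] <- as.numeric(crossprod(occ[, sel, drop = FALSE], gs)) *
          scheme$n_channels * 1e6
        kr <- .rates_at(scheme, e$v_mV[k], vt)
        qk <- scheme$transitions$q_gating * kr
        ig[sel] <- as.numeric(
          crossprod(occ[from_i, sel, drop = FALSE], qk)) *
          scheme$n_channels * .E0 * 1e9
      }
      # state at the exact end of the epoch
      p <- as.numeric(.occupancy_epoch(A, p, e$dur_ms[k]))
    }
    out <- list(trace = data.frame(time_ms = tg,
                                   v_mV = e$v_mV[ep_of],
                                   i_ionic_uA = ii,
                                   i_gating_uA = ig,
                                   i_cap_uA = 0,
                                   i_uA = ii + ig),
                epochs = cbind(e, t0_ms = t0, t1_ms = t1),
                info = sw$info)
    if (keep_occupancy) out$occupancy <- occ
    out
  })
  structure(list(sweeps = sweeps,
                 meta = list(scheme = scheme$name,
                             protocol = protocol$name,
                             holding_mV = protocol$holding_mV,
                             sample_ms = protocol$sample_ms,
                             sol = unclass(sol)[c("na_out", "k_out",
                                                  "na_in", "k_in",
                                                  "temperature_K")])),
            class = "traceset")
}

#' @export
print.traceset <- function(x, ...) {
  cat(sprintf("<traceset> %d sweeps (%s / %s), dt %g ms\n",
              length(x$sweeps),
              x$meta$fixture %||% x$meta$scheme %||% "?",
              x$meta$protocol %||% "?", x$meta$sample_ms))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
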