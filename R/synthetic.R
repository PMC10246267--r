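#' Band-limited Gaussian noise model
#'
#' White Gaussian noise passed through a one-pole low-pass (a cheap
#' stand-in for the 20 kHz Bessel of the acquisition chain) and rescaled
#' to the requested rms. The same seed and configuration always produce
#' bit-identical traces.
#'
#' @param rms_uA noise rms in uA (0 disables noise)
#' @param bandwidth_kHz low-pass corner (default 20 kHz)
#' @param seed integer seed; mandatory when `rms_uA > 0`
#' @return object of class `noise_model`
#' @export
noise_model <- function(rms_uA = 0, bandwidth_kHz = 20, seed = NULL) {
  if (rms_uA < 0) .nav_stop("noise rms must be >= 0", "navgate_bad_noise")
  if (rms_uA > 0 && is.null(seed))
    .nav_stop("a seed is mandatory when noise is enabled",
              "navgate_bad_noise")
  structure(list(rms_uA = rms_uA, bandwidth_kHz = bandwidth_kHz,
                 seed = seed), class = "noise_model")
}

# deterministic band-limited noise; restores the caller's RNG state
.noise_vector <- function(n, dt_ms, noise, stream) {
  if (is.null(noise) || noise$rms_uA == 0) return(numeric(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed((noise$seed + 7919L * stream) %% .Machine$integer.max)
  x <- stats::rnorm(n)
  a <- exp(-2 * pi * noise$bandwidth_kHz * dt_ms)  # kHz * ms
  y <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  y * noise$rms_uA / stats::sd(y)
}

# clamp-limited capacitive transient of a linear capacitor:
# single exponential with the clamp time constant at every voltage step
.capacitive_current <- function(epochs, tg, cap_nF, tau_ms) {
  ic <- numeric(length(tg))
  if (cap_nF <= 0) return(ic)
  dv <- diff(c(epochs$v_mV[1], epochs$v_mV))   # jump entering each epoch
  for (k in seq_len(nrow(epochs))) {
    if (dv[k] == 0) next
    t0 <- epochs$t0_ms[k]
    sel <- tg >= t0
    # nF * mV / ms = 1e-3 uA
    ic[sel] <- ic[sel] + 1e-3 * cap_nF * dv[k] / tau_ms *
      exp(-(tg[sel] - t0) / tau_ms)
  }
  ic
}

#' P/N leak-subtraction specification
#'
#' `n` subtraction sweeps are simulated from `holding_mV`, each scaled
#' `1/(sign * n)` of the main waveform's deviation from its holding; the
#' summed responses remove the linear capacitive component exactly and
#' leave nonlinear gating charge. The defaults follow the recording
#' practice emulated here: P/-4 from -130 mV for ionic/mixed records and
#' P/4 from +20 mV for gating-only records.
#'
#' @param n number of subtraction sweeps (positive integer)
#' @param holding_mV subtraction holding potential
#' @param sign +1 (P/N, same polarity) or -1 (P/-N)
#' @export
pn_spec <- function(n = 4, holding_mV = -130, sign = -1) {
  stopifnot(n >= 1, sign %in% c(-1, 1))
  structure(list(n = as.integer(n), holding_mV = holding_mV, sign = sign),
            class = "pn_spec")
}

#' Generate a synthetic cut-open-oocyte recording
#'
#' Runs [propagate()] for the fixture's gating scheme, adds the
#' clamp-limited capacitive transient of the linear membrane capacitance
#' and band-limited noise, and (optionally) applies online P/N leak
#' subtraction by simulating the scaled subtraction sweeps from the
#' subtraction holding potential. The returned (and optionally written)
#' traces are what the analysis stages consume.
#'
#' @param fixture fixture name (see [fixture_catalog()]) or the list
#'   returned by [load_fixture()]
#' @param protocol a [nav_protocol()]
#' @param sol a [solution_pair()]
#' @param noise a [noise_model()] (default: none)
#' @param pn a [pn_spec()] or NULL for no subtraction
#' @param out_dir if given, the traceset is also written there with
#'   [write_traceset()]
#' @return a `traceset`; sweeps carry `i_uA` (recorded current after
#'   subtraction) plus the noiseless components for reference
#' @export
generate_recording <- function(fixture, protocol, sol,
                               noise = noise_model(0), pn = NULL,
                               out_dir = NULL) {
  fx <- if (is.character(fixture)) load_fixture(fixture) else fixture
  ts <- propagate(fx$scheme, protocol, sol)
  cap <- fx$cap_nF %||% 0
  tau <- fx$clamp_tau_ms %||% 0.075
  subtract <- !is.null(pn)
  if (subtract && !inherits(pn, "pn_spec"))
    .nav_stop("`pn` must come from pn_spec()", "navgate_bad_pn")

  for (i in seq_along(ts$sweeps)) {
    sw <- ts$sweeps[[i]]
    tg <- sw$trace$time_ms
    ic <- .capacitive_current(sw$epochs, tg, cap, tau)
    itot <- sw$trace$i_ionic_uA + sw$trace$i_gating_uA + ic +
      .noise_vector(length(tg), protocol$sample_ms, noise, stream = i)
    if (subtract) {
      dv <- sw$epochs$v_mV - protocol$holding_mV
      if (any(abs(pn$holding_mV + dv / (pn$sign * pn$n)) > 250))
        .nav_stop("P/N subtraction pulses exceed protocol voltage bounds",
                  "navgate_bad_pn")
      sub_ep <- sw$epochs
      sub_ep$v_mV <- pn$holding_mV + dv / (pn$sign * pn$n)
      sub_proto <- nav_protocol(list(list(epochs = sub_ep[c("v_mV", "dur_ms",
                                                            "role")],
                                          info = sw$info)),
                                holding_mV = pn$holding_mV,
                                sample_ms = protocol$sample_ms,
                                name = "pn_subtraction")
      sub <- propagate(fx$scheme, sub_proto, sol, keep_occupancy = FALSE)
      st <- sub$sweeps[[1]]$trace
      sub_i <- st$i_ionic_uA + st$i_gating_uA +
        .capacitive_current(sub$sweeps[[1]]$epochs, tg, cap, tau)
      # baseline at the subtraction holding, then scaled accumulation
      base <- st$i_ionic_uA[1] + st$i_gating_uA[1]
      for (r in seq_len(pn$n)) {
        nz <- .noise_vector(length(tg), protocol$sample_ms, noise,
                            stream = 1000L * i + r)
        itot <- itot - pn$sign * (sub_i - base + nz)
      }
    }
    sw$trace$i_cap_uA <- ic
    sw$trace$i_uA <- itot
    ts$sweeps[[i]] <- sw
  }
  ts$meta$fixture <- fx$name
  ts$meta$noise <- if (is.null(noise)) NULL else unclass(noise)
  ts$meta$pn <- if (subtract) unclass(pn) else NULL
  ts$meta$cap_nF <- cap
  ts$meta$clamp_tau_ms <- tau
  if (!is.null(out_dir)) write_traceset(ts, out_dir)
  ts
}
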