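# Independent oracles and small builders shared across the suite.

# --- scheme builders ------------------------------------------------------

two_state_scheme <- function(k_co = 1, k_oc = 1, z_co = 0.5, z_oc = -0.5,
                             q = 1, p_na = 1, p_k = 0, n_channels = 1,
                             p_abs = 1) {
  gating_scheme(
    states = data.frame(name = c("C", "O"),
                        p_na = c(0, p_na), p_k = c(0, p_k)),
    transitions = data.frame(from = c("C", "O"), to = c("O", "C"),
                             k0 = c(k_co, k_oc), z_eff = c(z_co, z_oc),
                             q_gating = c(q, -q)),
    n_channels = n_channels, p_abs = p_abs, name = "two-state")
}

three_state_scheme <- function(k = c(1.2, 0.7, 0.4, 0.9),
                               z = c(0.5, -0.5, 0.3, -0.3)) {
  gating_scheme(
    states = data.frame(name = c("A", "B", "C"),
                        p_na = c(0, 0, 1), p_k = 0),
    transitions = data.frame(
      from = c("A", "B", "B", "C"), to = c("B", "A", "C", "B"),
      k0 = k, z_eff = z, q_gating = c(1, -1, 0.5, -0.5)),
    name = "three-state")
}

# --- Gillespie oracle -----------------------------------------------------

# Aggregate direct-method stochastic simulation of a labelled-state
# scheme at fixed voltage: the brute-force counterpart of the matrix
# exponential. Returns occupancy fractions at the requested times.
gillespie_occupancy <- function(scheme, v_mV, p0, times_ms, n_channels,
                                temperature_K = NAV_DEFAULT_TEMP_K) {
  vt <- thermal_voltage_mV(temperature_K)
  sn <- scheme$states$name
  k <- scheme$transitions$k0 * exp(scheme$transitions$z_eff * v_mV / vt)
  from <- match(scheme$transitions$from, sn)
  to <- match(scheme$transitions$to, sn)
  counts <- as.vector(stats::rmultinom(1, n_channels, p0))
  out <- matrix(NA_real_, length(sn), length(times_ms),
                dimnames = list(sn, NULL))
  t_now <- 0; j <- 1
  repeat {
    rates <- k * counts[from]
    total <- sum(rates)
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    while (j <= length(times_ms) && times_ms[j] < t_now + dt) {
      out[, j] <- counts / n_channels; j <- j + 1
    }
    if (j > length(times_ms)) break
    t_now <- t_now + dt
    ev <- sample.int(length(rates), 1, prob = rates)
    counts[from[ev]] <- counts[from[ev]] - 1L
    counts[to[ev]] <- counts[to[ev]] + 1L
  }
  out
}

# --- geometry fixtures ----------------------------------------------------

# write a PDB of stacked rings: each element of `rings` is
# list(z, radial, resname, resno, chain) with 8 atoms per ring
write_ring_pdb <- function(rings, path = tempfile(fileext = ".pdb"),
                           n_atoms = 8, element = "C") {
  lines <- character(); serial <- 0
  for (rg in rings) {
    for (k in seq_len(n_atoms)) {
      ang <- 2 * pi * (k - 1) / n_atoms
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, "CB", rg$resname %||% "ALA", rg$chain %||% "A",
        (rg$resno %||% 1) + 0L,
        rg$radial * cos(ang), rg$radial * sin(ang), rg$z, element))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard solutions used throughout
sol_ionic  <- function() solution_pair(na_out = 57.5, na_in = 12)
sol_bionic <- function() solution_pair(na_out = 57.5, k_in = 120)
sol_gating <- function() solution_pair()
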