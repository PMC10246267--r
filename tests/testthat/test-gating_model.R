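test_that("scheme validation catches structural defects", {
  st <- data.frame(name = c("C", "O"), p_na = c(0, 1), p_k = 0)
  expect_error(gating_scheme(st, data.frame(from = "C", to = "O", k0 = 1,
                                            z_eff = 0, q_gating = 1)),
               class = "navgate_bad_scheme")   # missing reverse
  tr <- data.frame(from = c("C", "O"), to = c("O", "C"), k0 = c(1, 1),
                   z_eff = 0, q_gating = c(1, 1))
  expect_error(gating_scheme(st, tr), class = "navgate_bad_scheme") # q not antisymmetric
  tr$q_gating <- c(1, -1); tr$k0 <- c(-1, 1)
  expect_error(gating_scheme(st, tr), class = "navgate_bad_scheme") # negative rate
  st4 <- data.frame(name = c("A", "B", "X", "Y"), p_na = 0, p_k = 0)
  tr4 <- data.frame(from = c("A", "B", "X", "Y"), to = c("B", "A", "Y", "X"),
                    k0 = 1, z_eff = 0, q_gating = 0)
  expect_error(gating_scheme(st4, tr4), class = "navgate_bad_scheme") # disconnected
})

test_that("steady state: symmetry, null-space vs long-time propagation", {
  sym <- two_state_scheme(k_co = 0.8, k_oc = 0.8, z_co = 0, z_oc = 0)
  expect_equal(unname(steady_state(sym, 0)), c(0.5, 0.5), tolerance = 1e-12)

  sc <- three_state_scheme()
  v <- -20
  ss <- steady_state(sc, v)
  # oracle: propagate far beyond the slowest relaxation
  A <- navgate:::.rate_matrix(sc, v, thermal_voltage_mV())
  tau_max <- 1 / min(abs(Re(eigen(A)$values[-which.min(abs(eigen(A)$values))])))
  pr <- nav_protocol(list(list(epochs = data.frame(v_mV = v,
                                                   dur_ms = 50 * tau_max,
                                                   role = "test"),
                               info = list())),
                     holding_mV = v, sample_ms = tau_max)
  long <- propagate(sc, pr, sol_ionic(), init = c(1, 0, 0))
  occ <- long$sweeps[[1]]$occupancy
  expect_equal(unname(occ[, ncol(occ)]), unname(ss), tolerance = 1e-6)
})

test_that("reducible chains are reported with their components", {
  st <- data.frame(name = c("A", "B"), p_na = 0, p_k = 0)
  tr <- data.frame(from = c("A", "B"), to = c("B", "A"), k0 = c(0, 0),
                   z_eff = 0, q_gating = 0)
  # both k0 = 0: graph connectivity fails at build time already
  expect_error(gating_scheme(st, tr), class = "navgate_bad_scheme")
})

test_that("two-state relaxation matches the closed form to 1e-6", {
  sc <- two_state_scheme(k_co = 0.9, k_oc = 0.05, z_co = 0.6, z_oc = -0.6)
  sol <- sol_ionic()
  vt <- thermal_voltage_mV(sol$temperature_K)
  pr <- nav_protocol(list(list(epochs = data.frame(
    v_mV = c(-120, 0), dur_ms = c(5, 10), role = c("hold", "test")),
    info = list())), holding_mV = -120, sample_ms = 0.01)
  ts <- propagate(sc, pr, sol)
  kf <- 0.9 * exp(0.6 * 0 / vt); kb <- 0.05 * exp(-0.6 * 0 / vt)
  tau <- 1 / (kf + kb); p_inf <- kf / (kf + kb)
  tr <- ts$sweeps[[1]]$trace
  occO <- ts$sweeps[[1]]$occupancy["O", ]
  sel <- tr$time_ms >= 5
  t_rel <- tr$time_ms[sel] - 5
  p0 <- occO[which(tr$time_ms == 5)[1]]
  expect_equal(unname(occO[sel]),
               p_inf + (p0 - p_inf) * exp(-t_rel / tau), tolerance = 1e-6)
})

test_that("holding at the stationary voltage leaves currents and occupancy flat", {
  sc <- two_state_scheme(k_co = 0.5, k_oc = 0.5, z_co = 0.4, z_oc = -0.4,
                         n_channels = 1e8, p_abs = 2e-14)
  pr <- nav_protocol(list(list(epochs = data.frame(v_mV = 0, dur_ms = 20,
                                                   role = "test"),
                               info = list())), holding_mV = 0,
                     sample_ms = 0.05)
  ts <- propagate(sc, pr, solution_pair(na_out = 120, na_in = 120))
  occ <- ts$sweeps[[1]]$occupancy
  expect_lt(max(abs(occ - occ[, 1])), 1e-10)
  expect_lt(max(abs(ts$sweeps[[1]]$trace$i_gating_uA)), 1e-9)
})

test_that("occupancy is conserved to 1e-9 at every sample, across protocols", {
  sol <- sol_ionic()
  for (proto in list(protocol_builtin("step", test_mV = 60),
                     protocol_builtin("tail_duration_family",
                                      durations_ms = c(0.5, 2, 5, 12)))) {
    for (fx in c("WT", "DIIIAA", "IQM")) {
      ts <- propagate(load_fixture(fx)$scheme, proto, sol)
      for (sw in ts$sweeps)
        expect_lt(max(abs(colSums(sw$occupancy) - 1)), 1e-9)
    }
  }
})

test_that("on- and off-gating charge cancel after full recovery (0.1%)", {
  sc <- load_fixture("WT")$scheme
  pr <- nav_protocol(list(list(epochs = data.frame(
    v_mV = c(-130, 20, -130), dur_ms = c(5, 23, 120),
    role = c("hold", "test", "off")), info = list())),
    holding_mV = -130, sample_ms = 0.002)
  ts <- propagate(sc, pr, sol_gating())
  tr <- ts$sweeps[[1]]$trace
  on <- tr$time_ms >= 5 & tr$time_ms < 28
  off <- tr$time_ms >= 28
  trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  q_on <- trapz(tr$time_ms[on], tr$i_gating_uA[on])
  q_off <- trapz(tr$time_ms[off], tr$i_gating_uA[off])
  expect_lt(abs(q_on + q_off) / abs(q_on), 1e-3)
})

test_that("matrix-exponential propagation agrees with Gillespie within 3 SE", {
  sc <- three_state_scheme()
  v <- -10; n_ch <- 1e5
  p0 <- c(A = 1, B = 0, C = 0)
  times <- c(0.5, 1, 2, 4)
  set.seed(101)
  mc <- gillespie_occupancy(sc, v, p0, times, n_ch)
  pr <- nav_protocol(list(list(epochs = data.frame(v_mV = v, dur_ms = 5,
                                                   role = "test"),
                               info = list())), holding_mV = v,
                     sample_ms = 0.5)
  ts <- propagate(sc, pr, sol_ionic(), init = p0)
  occ <- ts$sweeps[[1]]$occupancy
  for (j in seq_along(times)) {
    det <- occ[, which(ts$sweeps[[1]]$trace$time_ms == times[j])]
    se <- sqrt(pmax(det * (1 - det), 1e-12) / n_ch)
    expect_true(all(abs(mc[, j] - det) <= 3 * se + 1e-12),
                info = sprintf("t = %g ms", times[j]))
  }
})

test_that("rate overflow errors name the transition", {
  sc <- two_state_scheme(z_co = 120, z_oc = -120)
  err <- tryCatch(steady_state(sc, 200), error = identity)
  expect_s3_class(err, "navgate_rate_overflow")
  expect_match(conditionMessage(err), "C->O")
})

test_that("WT fixture: closed at rest, inward transient decays below 3% of peak", {
  fx <- load_fixture("WT")
  ss <- steady_state(fx$scheme, -120)
  expect_gt(ss["C1"] + ss["C2"], 0.99)
  ts <- propagate(fx$scheme, protocol_builtin("step", test_mV = 60,
                                              test_dur_ms = 30), sol_ionic())
  ps <- peak_and_steady(ts$sweeps[[1]], current = "i_ionic_uA")
  expect_lte(abs(ps$ratio), 0.03)
})

test_that("schemes round-trip through JSON", {
  sc <- load_fixture("DIIIAA")$scheme
  f <- tempfile(fileext = ".json")
  write_scheme(sc, f)
  sc2 <- read_scheme(f)
  expect_equal(sc2$states, sc$states)
  expect_equal(sc2$transitions, sc$transitions, tolerance = 1e-12)
  expect_equal(sc2$n_channels, sc$n_channels)
})
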