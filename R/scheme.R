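#' Labelled-state Markov gating scheme
#'
#' A gating scheme is a set of labelled states, each carrying relative
#' ion permeabilities, connected by voltage-dependent transitions with the
#' single-barrier rate law
#' \deqn{k(V) = k_0 \exp(z_{eff} F V / RT).}
#' Each directed transition also carries a gating charge `q_gating`
#' (elementary charges moved outward when the transition fires); the
#' reverse of every transition must be listed explicitly (use `k0 = 0`
#' for an absorbing-by-parameter edge) and its `q_gating` must be the
#' negative of the forward one, which makes the displaced charge a state
#' function and guarantees on/off charge conservation.
#'
#' @param states data.frame with columns `name`, `p_na`, `p_k`
#'   (dimensionless relative permeabilities, 0 for non-conducting states)
#' @param transitions data.frame with columns `from`, `to`, `k0` (1/ms),
#'   `z_eff` (elementary charges in the rate law, signed) and `q_gating`
#'   (elementary charges, signed)
#' @param n_channels number of channels in the (virtual) membrane patch
#' @param p_abs absolute permeability scale passed to [ghk_current()]
#'   (cm^3/s per channel)
#' @param name optional scheme label
#' @return an object of class `gating_scheme`
#' @seealso [propagate()], [steady_state()], [load_fixture()]
#' @export
gating_scheme <- function(states, transitions, n_channels = 1,
                          p_abs = 1, name = "scheme") {
  states <- as.data.frame(states)
  transitions <- as.data.frame(transitions)
  need_s <- c("name", "p_na", "p_k")
  need_t <- c("from", "to", "k0", "z_eff", "q_gating")
  if (!all(need_s %in% names(states)))
    .nav_stop("states need columns name, p_na, p_k", "navgate_bad_scheme")
  if (!all(need_t %in% names(transitions)))
    .nav_stop("transitions need columns from, to, k0, z_eff, q_gating",
              "navgate_bad_scheme")
  if (anyDuplicated(states$name))
    .nav_stop("duplicate state names", "navgate_bad_scheme")
  if (any(states$p_na < 0) || any(states$p_k < 0))
    .nav_stop("state permeabilities must be >= 0", "navgate_bad_scheme")
  if (any(!is.finite(transitions$k0)) || any(transitions$k0 < 0))
    .nav_stop("all k0 must be finite and >= 0", "navgate_bad_scheme")
  bad <- setdiff(c(transitions$from, transitions$to), states$name)
  if (length(bad))
    .nav_stop(paste("unknown states in transitions:",
                    paste(bad, collapse = ", ")), "navgate_bad_scheme")
  key <- paste(transitions$from, transitions$to, sep = "->")
  rkey <- paste(transitions$to, transitions$from, sep = "->")
  if (anyDuplicated(key))
    .nav_stop("duplicate transitions", "navgate_bad_scheme")
  miss <- setdiff(rkey, key)
  if (length(miss))
    .nav_stop(paste("missing reverse transitions for:",
                    paste(miss, collapse = ", "),
                    "(declare them with k0 = 0 if absorbing)"),
              "navgate_bad_scheme")
  # q_gating antisymmetry -> displaced charge is a state function
  qr <- transitions$q_gating[match(rkey, key)]
  if (any(abs(transitions$q_gating + qr) > 1e-9))
    .nav_stop("q_gating of each reverse transition must be the negative of the forward one",
              "navgate_bad_scheme")
  # connectivity of the undirected graph (edges where either direction > 0)
  adj <- matrix(FALSE, nrow(states), nrow(states),
                dimnames = list(states$name, states$name))
  on <- transitions$k0 > 0
  adj[cbind(transitions$from[on], transitions$to[on])] <- TRUE
  adj <- adj | t(adj)
  reach <- adj | diag(TRUE, nrow(adj))
  for (i in seq_len(nrow(adj))) reach <- reach | (reach %*% reach) > 0
  if (!all(reach[1, ]))
    .nav_stop("state graph is not connected", "navgate_bad_scheme")
  structure(list(states = states, transitions = transitions,
                 n_channels = n_channels, p_abs = p_abs, name = name),
            class = "gating_scheme")
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat(sprintf("<gating_scheme> %s: %d states, %d directed transitions, %.3g channels\n",
              x$name, nrow(x$states), nrow(x$transitions), x$n_channels))
  invisible(x)
}

# Directed rate constants at a voltage. Errors on exponent overflow,
# naming the transition, as a guard against runaway z_eff * V products.
.rates_at <- function(scheme, v_mV, vt) {
  ex <- scheme$transitions$z_eff * v_mV / vt
  if (any(ex > 500)) {
    i <- which.max(ex)
    .nav_stop(sprintf("rate overflow for transition %s->%s at %g mV",
                      scheme$transitions$from[i], scheme$transitions$to[i],
                      v_mV), "navgate_rate_overflow")
  }
  scheme$transitions$k0 * exp(ex)
}

# Generator matrix A with dp/dt = A %*% p (columns = source states)
.rate_matrix <- function(scheme, v_mV, vt) {
  sn <- scheme$states$name
  n <- length(sn)
  A <- matrix(0, n, n, dimnames = list(sn, sn))
  k <- .rates_at(scheme, v_mV, vt)
  from <- match(scheme$transitions$from, sn)
  to <- match(scheme$transitions$to, sn)
  for (i in seq_along(k)) {
    A[to[i], from[i]] <- A[to[i], from[i]] + k[i]
    A[from[i], from[i]] <- A[from[i], from[i]] - k[i]
  }
  A
}

#' Stationary occupancy of a gating scheme at a fixed voltage
#'
#' Solves the null space of the generator matrix (normalized to sum 1).
#' This equals the long-time limit of [propagate()] at the same voltage
#' when the chain is irreducible there.
#'
#' @param scheme a [gating_scheme()]
#' @param v_mV voltage in mV
#' @param temperature_K temperature for the rate law
#' @return named occupancy vector summing to 1
#' @export
steady_state <- function(scheme, v_mV,
                         temperature_K = NAV_DEFAULT_TEMP_K) {
  vt <- thermal_voltage_mV(temperature_K)
  A <- .rate_matrix(scheme, v_mV, vt)
  n <- nrow(A)
  # communicating classes of the k(V) > 0 graph; the stationary
  # distribution is unique iff exactly one class is closed (states in
  # transient classes drain into it and carry zero stationary weight)
  k <- .rates_at(scheme, v_mV, vt)
  sn <- scheme$states$name
  adj <- matrix(FALSE, n, n, dimnames = list(sn, sn))
  on <- k > 0
  adj[cbind(scheme$transitions$from[on], scheme$transitions$to[on])] <- TRUE
  reach <- adj | diag(TRUE, n)
  for (i in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  mutual <- reach & t(reach)
  comp <- .components(mutual)
  closed <- Filter(function(cl) {
    out <- reach[cl, setdiff(sn, cl), drop = FALSE]
    !any(out)
  }, comp)
  if (length(closed) != 1)
    .nav_stop(paste0("chain reducible at ", v_mV,
                     " mV with multiple closed classes: ",
                     paste(vapply(comp, paste, "", collapse = "+"),
                           collapse = " | ")),
              "navgate_reducible")
  cl <- closed[[1]]
  Ai <- A[cl, cl, drop = FALSE]
  m <- length(cl)
  p <- setNames(numeric(n), sn)
  if (m == 1) p[cl] <- 1 else {
    M <- rbind(Ai[-m, , drop = FALSE], rep(1, m))
    p[cl] <- solve(M, c(rep(0, m - 1), 1))
  }
  p <- pmax(p, 0); p <- p / sum(p)
  p[sn]
}

.components <- function(mutual) {
  n <- nrow(mutual); left <- seq_len(n); out <- list()
  while (length(left)) {
    grp <- which(mutual[left[1], ])
    out[[length(out) + 1]] <- rownames(mutual)[grp]
    left <- setdiff(left, grp)
  }
  out
}

#' Read / write a gating scheme as versioned JSON
#'
#' @param path file path
#' @return `read_scheme()` returns a [gating_scheme()];
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema) || !startsWith(x$schema, "navgate-scheme/"))
    .nav_stop("not a navgate scheme file", "navgate_bad_scheme")
  gating_scheme(x$states, x$transitions, n_channels = x$n_channels,
                p_abs = x$p_abs, name = x$name)
}

#' @rdname read_scheme
#' @param scheme a [gating_scheme()]
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(
    list(schema = "navgate-scheme/1", name = scheme$name,
         n_channels = scheme$n_channels, p_abs = scheme$p_abs,
         states = scheme$states, transitions = scheme$transitions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
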