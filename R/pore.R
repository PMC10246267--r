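# rotation taking `axis` to +z (Rodrigues)
.axis_rotation <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3],
         a[1] * z[2] - a[2] * z[1])
  c2 <- sum(a * z)
  if (abs(c2 - 1) < 1e-12) return(diag(3))
  if (abs(c2 + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c2)
}

# largest sphere centred at (cx, cy) in the slice plane z = z0:
# r = min_i ( |center - atom_i| - vdw_i )
.slice_radius <- function(cx, cy, z0, ax, ay, az, ar) {
  min(sqrt((ax - cx)^2 + (ay - cy)^2 + (az - z0)^2) - ar)
}

#' Trace the pore-radius profile of a channel structure
#'
#' HOLE-style maximal-inscribed-sphere tracing: starting from a seed
#' point inside the lumen, the profile advances in `step_A` slices along
#' the pore axis; in every slice the sphere centre is optimized in-plane
#' (multi-start Nelder-Mead, warm-started from the previous slice) to
#' maximize the distance to the nearest atom surface. The trace runs in
#' both directions until the radius exceeds `escape_A` (pore mouth) or
#' the centre drifts more than `max_drift_A` sideways (broken lumen).
#'
#' @param structure a [load_structure()] result
#' @param seed_point numeric xyz inside the lumen (Angstrom)
#' @param axis pore-axis hint (default +z)
#' @param step_A axial slice spacing
#' @param escape_A radius at which the trace is considered to have left
#'   the pore
#' @param n_starts number of in-plane multi-start perturbations (>= 16)
#' @param max_drift_A lateral drift at which the trace errors out
#' @return a `pore_profile`: data.frame `z` (along the axis), `radius_A`,
#'   `cx`, `cy` (centres, axis frame), plus the rotation used
#' @export
trace_pore <- function(structure, seed_point, axis = c(0, 0, 1),
                       step_A = 0.25, escape_A = 10, n_starts = 16,
                       max_drift_A = 10) {
  at <- structure$atoms
  R <- .axis_rotation(axis)
  xyz <- t(R %*% t(as.matrix(at[, c("x", "y", "z")])))
  sp <- as.numeric(R %*% seed_point)
  ax <- xyz[, 1]; ay <- xyz[, 2]; az <- xyz[, 3]; ar <- at$radius
  r0 <- .slice_radius(sp[1], sp[2], sp[3], ax, ay, az, ar)
  if (r0 <= 0)
    .nav_stop("seed point lies inside an atom", "navgate_bad_seed")

  optimize_slice <- function(z0, warm) {
    near <- abs(az - z0) < escape_A + max(ar) + 2
    if (!any(near)) return(NULL)
    f <- function(p) -.slice_radius(p[1], p[2], z0, ax[near], ay[near],
                                    az[near], ar[near])
    starts <- rbind(warm,
                    t(vapply(seq_len(n_starts), function(k) {
                      ang <- 2 * pi * k / n_starts
                      warm + (0.5 + (k %% 3) * 0.75) * c(cos(ang), sin(ang))
                    }, c(0, 0))))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(c = best$par, r = -best$value)
  }

  run_dir <- function(dir) {
    out <- list(); warm <- sp[1:2]; z0 <- sp[3]
    repeat {
      z0 <- z0 + dir * step_A
      s <- optimize_slice(z0, warm)
      if (is.null(s)) break
      drift <- sqrt(sum((s$c - sp[1:2])^2))
      if (s$r > escape_A) break
      if (drift > max_drift_A)
        .nav_stop(sprintf("pore trace escaped sideways at z = %.2f (last good radius %.2f A)",
                          z0, s$r), "navgate_trace_escape")
      out[[length(out) + 1]] <- c(z = z0, radius_A = s$r, cx = s$c[1],
                                  cy = s$c[2])
      warm <- s$c
    }
    out
  }

  seed_sl <- optimize_slice(sp[3], sp[1:2])
  up <- run_dir(+1); down <- run_dir(-1)
  prof <- rbind(do.call(rbind, rev(down)),
                c(z = sp[3], radius_A = seed_sl$r, cx = seed_sl$c[1],
                  cy = seed_sl$c[2]),
                do.call(rbind, up))
  prof <- as.data.frame(prof)
  structure(list(profile = prof, rotation = R, step_A = step_A,
                 seed_point = seed_point),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> %d slices, z in [%.1f, %.1f] A, min radius %.2f A\n",
              nrow(x$profile), min(x$profile$z), max(x$profile$z),
              min(x$profile$radius_A)))
  invisible(x)
}

#' Detect constriction minima and two-tier pairs in a pore profile
#'
#' Local minima of the radius profile with topographic prominence of at
#' least `prominence_A` are reported; pairs of neighbouring minima whose
#' axial separation is at most `max_separation_A` (about one alpha-helix
#' turn plus margin) are flagged as a two-tier gate.
#'
#' @param profile a [trace_pore()] result
#' @param prominence_A minimum prominence (default 0.3 A)
#' @param max_separation_A maximum axial separation for pairing
#' @return list with `minima` (data.frame `z`, `radius_A`, `prominence_A`)
#'   and `pairs` (data.frame `z1`, `z2`, `separation_A`), either possibly
#'   empty
#' @export
find_constrictions <- function(profile, prominence_A = 0.3,
                               max_separation_A = 8) {
  pr <- profile$profile
  if (nrow(pr) < 20)
    .nav_stop("profile too short (need >= 20 slices)", "navgate_bad_input")
  r <- pr$radius_A; n <- length(r)
  is_min <- which(diff(sign(diff(r))) > 0) + 1
  prom <- vapply(is_min, function(i) {
    left <- r[seq_len(i - 1)]; right <- r[seq(i + 1, n)]
    lb <- if (length(left)) {
      lower <- which(left < r[i]);
      max(left[seq(from = if (length(lower)) max(lower) + 1 else 1,
                   to = i - 1)])
    } else Inf
    rb <- if (length(right)) {
      lower <- which(right < r[i])
      max(right[seq_len(if (length(lower)) min(lower) - 1 else length(right))])
    } else Inf
    min(lb, rb) - r[i]
  }, 0)
  keep <- is.finite(prom) & prom >= prominence_A
  minima <- data.frame(z = pr$z[is_min[keep]],
                       radius_A = r[is_min[keep]],
                       prominence_A = prom[keep],
                       cx = pr$cx[is_min[keep]], cy = pr$cy[is_min[keep]])
  minima <- minima[order(minima$z), , drop = FALSE]
  pairs <- NULL
  if (nrow(minima) >= 2) {
    sep <- diff(minima$z)
    j <- which(sep <= max_separation_A)
    if (length(j))
      pairs <- data.frame(z1 = minima$z[j], z2 = minima$z[j + 1],
                          separation_A = sep[j])
  }
  list(minima = minima,
       pairs = if (is.null(pairs)) data.frame(z1 = numeric(0),
                                              z2 = numeric(0),
                                              separation_A = numeric(0))
               else pairs)
}

#' Residues lining a constriction minimum
#'
#' Returns the residues owning any atom whose van der Waals surface lies
#' within `margin_A` of the inscribed sphere at the minimum,
#' deduplicated (one entry per residue).
#'
#' @param structure the [load_structure()] result used for the trace
#' @param profile the [trace_pore()] result
#' @param minimum one row of `find_constrictions()$minima`
#' @param margin_A contact margin (default 1.5 A)
#' @return data.frame `resname`, `resno`, `chain`, `domain`, `distance_A`
#' @export
lining_residues <- function(structure, profile, minimum, margin_A = 1.5) {
  at <- structure$atoms
  R <- profile$rotation
  xyz <- t(R %*% t(as.matrix(at[, c("x", "y", "z")])))
  d <- sqrt((xyz[, 1] - minimum$cx)^2 + (xyz[, 2] - minimum$cy)^2 +
              (xyz[, 3] - minimum$z)^2) - at$radius - minimum$radius_A
  sel <- which(d <= margin_A)
  if (!length(sel)) return(data.frame(resname = character(0),
                                      resno = integer(0),
                                      chain = character(0),
                                      domain = character(0),
                                      distance_A = numeric(0)))
  res <- data.frame(resname = at$resname[sel], resno = at$resno[sel],
                    chain = at$chain[sel], domain = at$domain[sel],
                    distance_A = d[sel])
  res <- res[order(res$distance_A), ]
  res[!duplicated(res[c("resno", "chain")]), , drop = FALSE]
}
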