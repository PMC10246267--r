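test_that("a single ring gives the analytic inscribed-sphere radius", {
  f <- write_ring_pdb(list(list(z = 0, radial = 5)))
  st <- load_structure(f)
  expect_equal(nrow(st$atoms), 8)
  expect_equal(unique(st$atoms$radius), 1.70)
  pp <- trace_pore(st, c(0, 0, 0), step_A = 0.25)
  i0 <- which.min(abs(pp$profile$z))
  expect_equal(pp$profile$radius_A[i0], 5 - 1.7, tolerance = 0.01)
})

test_that("two stacked rings produce two minima with analytic radii, one pair", {
  rings <- list(
    list(z = -14, radial = 12), list(z = -10, radial = 9),
    list(z = -5.4, radial = 4.5), list(z = -2.7, radial = 7),
    list(z = 0, radial = 4.0), list(z = 4, radial = 8),
    list(z = 8, radial = 11))
  f <- write_ring_pdb(rings)
  st <- load_structure(f)
  pp <- trace_pore(st, c(0, 0, -2.7), step_A = 0.25)
  cons <- find_constrictions(pp)
  expect_gte(nrow(cons$minima), 2)
  r_at <- function(z) cons$minima$radius_A[which.min(abs(cons$minima$z - z))]
  expect_equal(r_at(0), 2.3, tolerance = 0.01)
  expect_equal(r_at(-5.4), 2.8, tolerance = 0.01)
  expect_equal(nrow(cons$pairs), 1)
  expect_equal(cons$pairs$separation_A, 5.4, tolerance = 0.3)

  # monotone funnel: no minima at all (trim to the strictly widening
  # section; below the funnel tip the lumen opens again and a boundary
  # minimum would be a geometric artifact, not a constriction)
  fun <- write_ring_pdb(list(list(z = 0, radial = 4), list(z = 3, radial = 5.5),
                             list(z = 6, radial = 7), list(z = 9, radial = 9)))
  ppf <- trace_pore(load_structure(fun), c(0, 0, 0), step_A = 0.25)
  ppf$profile <- ppf$profile[ppf$profile$z >= 0, ]
  expect_equal(nrow(find_constrictions(ppf)$minima), 0)
})

test_that("lining residues are exactly the constructed ring memberships", {
  rings <- list(
    list(z = -10, radial = 10, resname = "GLY", resno = 900),
    list(z = -5.4, radial = 4.5, resname = "LEU", resno = 416, chain = "A"),
    list(z = -2.7, radial = 7, resname = "GLY", resno = 901),
    list(z = 0, radial = 4.0, resname = "ILE", resno = 412, chain = "B"),
    list(z = 4, radial = 10, resname = "GLY", resno = 902))
  f <- write_ring_pdb(rings)
  st <- load_structure(f)
  pp <- trace_pore(st, c(0, 0, -2.7), step_A = 0.25)
  cons <- find_constrictions(pp)
  top <- cons$minima[which.min(abs(cons$minima$z - 0)), ]
  bot <- cons$minima[which.min(abs(cons$minima$z + 5.4)), ]
  expect_setequal(unique(lining_residues(st, pp, top)$resno), 412)
  expect_setequal(unique(lining_residues(st, pp, bot)$resno), 416)
})

test_that("maximality: no random probe sphere beats the traced radius", {
  f <- write_ring_pdb(list(list(z = -3, radial = 6), list(z = 0, radial = 4.5),
                           list(z = 3, radial = 6)))
  st <- load_structure(f)
  pp <- trace_pore(st, c(0, 0, 0), step_A = 0.5)
  at <- st$atoms
  set.seed(3)
  for (k in 1:200) {
    i <- sample(nrow(pp$profile), 1)
    c0 <- c(pp$profile$cx[i] + rnorm(1, 0, 0.8),
            pp$profile$cy[i] + rnorm(1, 0, 0.8), pp$profile$z[i])
    r_probe <- min(sqrt((at$x - c0[1])^2 + (at$y - c0[2])^2 +
                          (at$z - c0[3])^2) - at$radius)
    expect_lte(r_probe, pp$profile$radius_A[i] + 1e-6)
  }
})

test_that("profiles are invariant under rigid motion (0.05 A)", {
  rings <- list(list(z = -5.4, radial = 4.5), list(z = -2.7, radial = 7),
                list(z = 0, radial = 4.0), list(z = 3, radial = 8))
  f <- write_ring_pdb(rings)
  st <- load_structure(f)
  pp0 <- trace_pore(st, c(0, 0, -2.7), step_A = 0.25)

  th <- 0.4; axis_new <- c(sin(th), 0, cos(th))
  R <- navgate:::.axis_rotation(axis_new)   # rotate frame: z -> axis_new
  st2 <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% R   # inverse rotation
  st2$atoms$x <- xyz[, 1] + 3
  st2$atoms$y <- xyz[, 2] - 2
  st2$atoms$z <- xyz[, 3] + 1
  seed2 <- as.numeric(c(0, 0, -2.7) %*% R) + c(3, -2, 1)
  pp2 <- trace_pore(st2, seed2, axis = as.numeric(c(0, 0, 1) %*% R),
                    step_A = 0.25)
  m0 <- find_constrictions(pp0)$minima
  m2 <- find_constrictions(pp2)$minima
  expect_equal(nrow(m0), nrow(m2))
  expect_equal(sort(m0$radius_A), sort(m2$radius_A), tolerance = 0.05)
})

test_that("structure loading guards: unknown elements, bad seeds, formats", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(sprintf("ATOM      1  XX  UNK A   1    %8.3f%8.3f%8.3f  1.00  0.00           X",
                       0, 0, 0), "END"), f)
  expect_error(load_structure(f), class = "navgate_unknown_element")

  fr <- write_ring_pdb(list(list(z = 0, radial = 5)))
  st <- load_structure(fr)
  expect_error(trace_pore(st, c(5, 0, 0)), class = "navgate_bad_seed")
})

test_that("synthetic stand-in pores reproduce the published two-tier gate layout", {
  # geometric stand-ins (see inst/extdata/structures): NOT the deposited
  # coordinates, but built so the identified residues line the two
  # bottom-of-S6 constrictions one helix turn apart
  pdb <- system.file("extdata", "structures",
                     "navpas_6a95_synthetic_pore.pdb", package = "navgate")
  st <- load_structure(pdb, domains = list(DI = "A", DII = "B",
                                           DIII = "C", DIV = "D"))
  pp <- trace_pore(st, c(0, 0, 7), step_A = 0.25)
  cons <- find_constrictions(pp)
  # the narrowest region is the S6 gate, not the selectivity filter
  expect_lt(min(cons$minima$radius_A),
            pp$profile$radius_A[which.min(abs(pp$profile$z - 15.5))])
  expect_gte(nrow(cons$pairs), 1)
  pair <- cons$pairs[1, ]
  expect_lte(pair$separation_A, 8)
  top <- cons$minima[which.min(abs(cons$minima$z - pair$z2)), ]
  bot <- cons$minima[which.min(abs(cons$minima$z - pair$z1)), ]
  lr_top <- lining_residues(st, pp, top)
  lr_bot <- lining_residues(st, pp, bot)
  expect_setequal(lr_top$resno, c(412, 737, 1108, 1407))
  expect_setequal(lr_bot$resno, c(416, 741, 1112, 1411))
  both <- rbind(lr_top, lr_bot)
  expect_equal(nrow(both), 8)                      # two per domain
  expect_true(all(table(both$domain) == 2))

  # the mmCIF stand-in parses and gives the Nav1.7 numbering
  cif <- system.file("extdata", "structures",
                     "nav17_7xvf_synthetic_pore.cif", package = "navgate")
  st7 <- load_structure(cif)
  pp7 <- trace_pore(st7, c(0, 0, 7), step_A = 0.25)
  cons7 <- find_constrictions(pp7)
  expect_gte(nrow(cons7$pairs), 1)
  top7 <- cons7$minima[which.min(abs(cons7$minima$z - 0)), ]
  expect_setequal(lining_residues(st7, pp7, top7)$resno,
                  c(398, 964, 1453, 1756))
})
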