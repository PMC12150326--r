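test_that("raw scan windows fold onto (-180, 180] and folding is idempotent", {
  expect_equal(fold_angle(350), -10)
  expect_equal(fold_angle(540), 180)
  expect_equal(fold_angle(-180), 180)

  # 180-540 scan window with inequivalent endpoints (methoxy hysteresis):
  # both fold to 180 and the lower energy must win
  chi <- seq(180, 540, by = 10)
  e <- 5 * (1 + cos(2 * chi * pi / 180))
  e[1] <- e[1] + 0.7  # start-of-scan endpoint sits higher
  p <- fold_to_principal(torsion_profile(chi, e, window = "raw"))
  expect_true(all(p$angles > -180 & p$angles <= 180))
  expect_equal(length(p$angles), 36)
  expect_equal(p$energies[p$angles == 180],
               5 * (1 + cos(2 * pi)) - min(e))
  # idempotent up to the re-reference already applied
  p2 <- fold_to_principal(p)
  expect_equal(p2$angles, p$angles)
  expect_equal(p2$energies, p$energies)

  half <- torsion_profile(seq(0, 170, 10), rep(1, 18), window = "raw")
  expect_error(fold_to_principal(half), "incomplete scan")
})

test_that("enantiomer symmetrization takes the pointwise mirror minimum", {
  chi <- seq(-170, 180, by = 10)
  e <- 5 * (1 + cos(2 * chi * pi / 180))
  e[chi == 100] <- e[chi == 100] + 0.4  # E(100) above E(-100)
  p <- torsion_profile(chi, e, window = "principal")
  s <- symmetrize_enantiomers(p)
  expect_true(all(s$angles >= 0 & s$angles <= 180))
  expect_equal(s$energies[s$angles == 100],
               5 * (1 + cos(200 * pi / 180)))
  # output never exceeds either mirror input, and an already-symmetric
  # profile is unchanged on [0, 180]
  for (a in s$angles) {
    ins <- p$energies[abs(abs(p$angles) - a) < 1e-9]
    expect_lte(s$energies[s$angles == a], min(ins) + 1e-12)
  }
  sym <- torsion_profile(chi, 5 * (1 + cos(2 * chi * pi / 180)), "principal")
  s2 <- symmetrize_enantiomers(sym)
  expect_equal(s2$energies, sym$energies[sym$angles >= 0])

  orphan <- torsion_profile(c(-170, -100, 0, 100, 120, 180),
                            c(1, 0, 5, 0, 2, 4), window = "principal")
  expect_error(symmetrize_enantiomers(orphan), "missing mirror")
})

test_that("stationary points of a cos(2 chi) well are located and refined exactly", {
  chi <- seq(-170, 180, by = 10)
  p <- torsion_profile(chi, 5 * (1 - cos(2 * chi * pi / 180)), "principal")
  sp <- locate_stationary_points(p)
  mins <- sp$chi[sp$kind == "minimum"]
  maxs <- sp[sp$kind == "maximum", ]
  expect_equal(sort(mins), c(0, 180))
  expect_equal(sort(maxs$chi), c(-90, 90))
  expect_equal(maxs$energy, c(10, 10), tolerance = 1e-3)

  # symmetric 3-point data refine to the exact vertex
  v <- atropos:::.parabola_vertex(c(80, 90, 100), c(9.6985, 10, 9.6985))
  expect_equal(v$x, 90)
  expect_equal(v$y, 10)

  # minima and maxima alternate around the circle
  g <- gen_torsion_profile(101.1, 35, 30.2, asym = 0.3)
  sp2 <- locate_stationary_points(fold_to_principal(g$profile))
  kinds <- sp2$kind[order(sp2$chi)]
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("the enantiomerization barrier is the lower of the two path maxima", {
  # double well: minima at +/-100, syn maximum 35 at 0, anti 30.2 at 180
  g <- gen_torsion_profile(100, 35, 30.2)
  p <- fold_to_principal(g$profile)
  b <- enantiomerization_barrier(p)
  expect_equal(b$path, "anti")
  expect_equal(b$barrier, 30.2, tolerance = 0.05)
  expect_equal(abs(b$chi_gs), 100, tolerance = 1)

  # mirror symmetry: the barrier does not depend on which enantiomer
  # hosts the global minimum (map E(chi) -> E(-chi) on the same grid)
  m <- p$energies[match(round(fold_angle(-p$angles), 6),
                        round(p$angles, 6))]
  b2 <- enantiomerization_barrier(
    torsion_profile(p$angles, m, window = "principal"))
  expect_equal(b2$barrier, b$barrier, tolerance = 1e-9)

  achiral <- torsion_profile(seq(-170, 180, 10),
                             5 * (1 - cos(seq(-170, 180, 10) * pi / 180)),
                             "principal")
  expect_error(enantiomerization_barrier(achiral), "no chiral axis")
})

test_that("grid + parabolic refinement agrees with a dense brute-force scan", {
  cases <- list(c(101.1, 35, 30.2), c(100, 35, 30.2), c(112.9, 28, 17),
                c(60, 12, 25), c(129.1, 20, 6.8))
  for (cs in cases) {
    g <- gen_torsion_profile(cs[1], cs[2], cs[3])
    got <- enantiomerization_barrier(fold_to_principal(g$profile))
    want <- brute_force_barrier(g$truth$energy_fn, by = 0.1)
    expect_equal(got$barrier, want$barrier, tolerance = 0.1)
    expect_equal(got$path, want$path)
    expect_equal(abs(got$chi_gs), abs(want$chi_gs), tolerance = 1)
  }
})

test_that("free-energy barriers assemble from validated stationary points", {
  gs <- stationary_point(101, 0.0, 0.5, 0, "minimum")
  ts <- stationary_point(180, 30.0, 0.7, 1, "maximum")
  expect_equal(free_energy_barrier(gs, ts), 30.2)
  ts2 <- stationary_point(0, 34.0, 1.1, 1, "maximum")
  expect_equal(free_energy_barrier(gs, list(ts2, ts)), 30.2)

  bad_ts <- stationary_point(180, 30, 0.7, 0, "maximum")
  expect_error(free_energy_barrier(gs, bad_ts), "1 imaginary")
  bad_gs <- stationary_point(101, 0, 0.5, 1, "minimum")
  expect_error(free_energy_barrier(bad_gs, ts), "ground state invalid")
  below <- stationary_point(180, -5, 0.2, 1, "maximum")
  expect_error(free_energy_barrier(gs, below), "ordering error")
})

test_that("axis stability classes use half-open 22/30 boundaries monotonically", {
  expect_equal(classify_axis(6.8)$label, 1L)
  expect_equal(classify_axis(22.1)$label, 2L)
  expect_equal(classify_axis(30.2)$label, 3L)
  expect_equal(classify_axis(22)$label, 2L)
  expect_equal(classify_axis(30)$label, 3L)
  # step function: monotone non-decreasing in the barrier
  dgs <- seq(0, 45, by = 0.5)
  labels <- vapply(dgs, function(d) classify_axis(d)$label, integer(1))
  expect_true(all(diff(labels) >= 0))
  expect_error(classify_axis(-1), "non-negative")
  expect_error(classify_axis(Inf), "finite")
})

test_that("torsion scan tables read back as profiles", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# compound=demo", "chi_deg,energy_kcal", "180,10", "190,8",
               "200,5"), path)
  p <- read_torsion_scan(path)
  expect_s3_class(p, "torsion_profile")
  expect_equal(p$angles, c(180, 190, 200))
  expect_equal(p$energies, c(5, 3, 0))
})
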