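test_that("Boltzmann weights follow the closed-form ratios with a 1% cutoff", {
  ens <- function(...) conformer_ensemble(list(...), temperature = 298.15)
  w <- boltzmann_weights(ens(conformer("a", dG = 1), conformer("b", dG = 1)))
  expect_equal(unname(w), c(0.5, 0.5))

  # exp(0.41 / RT) ~ 2.00 at 298.15 K
  w2 <- boltzmann_weights(ens(conformer("a", dG = 0),
                              conformer("b", dG = 0.41)))
  expect_equal(unname(w2), c(0.666, 0.334), tolerance = 1e-2)

  # a 3 kcal/mol conformer is ~0.6% and is dropped by the 1% threshold
  w3 <- boltzmann_weights(ens(conformer("a", dG = 0),
                              conformer("b", dG = 3)))
  expect_equal(w3, c(a = 1))

  # electronic-energy weighting reads dE, and a missing energy errors
  w4 <- boltzmann_weights(ens(conformer("a", dG = 0, dE = 0),
                              conformer("b", dG = 5, dE = 0)),
                          energy = "electronic")
  expect_equal(unname(w4), c(0.5, 0.5))
  expect_error(
    boltzmann_weights(ens(conformer("a", dG = 0), conformer("b", dG = 1)),
                      energy = "electronic"),
    "lacks")
})

test_that("weights sum to 1 and are invariant to an additive energy shift", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    e <- c(0, runif(n - 1, 0, 6))
    mk <- function(shift) conformer_ensemble(
      lapply(seq_len(n), function(j) conformer(letters[j], dG = e[j] + shift)))
    w0 <- boltzmann_weights(mk(0))
    w7 <- boltzmann_weights(mk(7.3))
    expect_equal(sum(w0), 1)
    expect_equal(w0, w7)
  }
})

test_that("weighted spectra are convex pointwise combinations", {
  s <- gen_spectrum(c(1200, 1500), ir_amp = c(1, 0.5), vcd_amp = c(1, -0.6))
  spectra <- list(a = s$vcd, b = s$vcd)
  w <- c(a = 0.3, b = 0.7)
  expect_equal(weighted_spectrum(spectra, w)$intensity, s$vcd$intensity)

  neg <- spectrum_table(s$vcd$wavenumber, -s$vcd$intensity, kind = "VCD")
  zero <- weighted_spectrum(list(a = s$vcd, b = neg), c(a = 0.5, b = 0.5))
  expect_equal(zero$intensity, rep(0, length(zero$wavenumber)))

  # linearity against the pointwise combination
  s2 <- gen_spectrum(c(1100, 1650), ir_amp = c(0.8, 1), vcd_amp = c(-1, 0.4))
  mix <- weighted_spectrum(list(a = s$vcd, b = s2$vcd), c(a = 0.25, b = 0.75))
  expect_equal(mix$intensity,
               0.25 * s$vcd$intensity + 0.75 * s2$vcd$intensity)

  expect_error(weighted_spectrum(list(a = s$ir, b = s$vcd),
                                 c(a = 0.5, b = 0.5)),
               "kind mismatch")
})

test_that("experimental VCD block processing cancels baselines and zeroes the anchor", {
  grid <- seq(900, 2100, by = 2)
  sig <- gen_spectrum(c(1200, 1500), ir_amp = c(1, 1), vcd_amp = c(1, -0.8),
                      grid = grid)$vcd
  base <- 0.05 + 1e-5 * (grid - 900)   # slow instrument drift
  e1 <- spectrum_table(grid, sig$intensity + base, kind = "VCD")
  e2 <- spectrum_table(grid, -sig$intensity + base, kind = "VCD")
  out <- process_experimental_vcd(list(e1), list(e2), anchor = 2000)
  anchor_val <- sig$intensity[grid == 2000]
  expect_equal(out$intensity, sig$intensity - anchor_val)
  expect_equal(out$intensity[grid == 2000], 0)

  # identical enantiomer blocks cancel to zero
  same <- process_experimental_vcd(list(e1, e1), list(e1), anchor = 2000)
  expect_equal(same$intensity, rep(0, length(grid)))

  # constant-offset input becomes all zeros after anchoring
  flat <- spectrum_table(grid, rep(3, length(grid)), kind = "VCD")
  fz <- process_experimental_vcd(list(flat), list(spectrum_table(
    grid, rep(1, length(grid)), kind = "VCD")))
  expect_equal(fz$intensity, rep(0, length(grid)))

  expect_error(process_experimental_vcd(list(e1), list(e2), anchor = 2500),
               "anchor")
})

test_that("wavenumber scaling moves bands and the search recovers the factor", {
  s <- gen_spectrum(1700, ir_amp = 1, vcd_amp = 1,
                    grid = seq(1000, 1800, 1))
  sc <- scale_wavenumbers(s$ir, 0.97)
  expect_equal(sc$wavenumber[which.max(sc$intensity)], 1649)
  expect_equal(scale_wavenumbers(s$ir, 1)$wavenumber, s$ir$wavenumber)
  expect_error(scale_wavenumbers(s$ir, 0.5), "guard range")

  calc <- gen_spectrum(c(1150, 1350, 1600), ir_amp = c(1, 0.7, 0.9),
                       vcd_amp = c(1, -1, 0.5), grid = seq(950, 1750, 1))$ir
  obs <- scale_wavenumbers(calc, 0.975)
  found <- scale_wavenumbers(calc, search = TRUE, reference = obs)
  expect_equal(found$sigma, 0.975, tolerance = 0.0011)
})

test_that("spectral similarity is a normalized, symmetric, scale-free inner product", {
  s <- gen_spectrum(c(1200, 1500), ir_amp = c(1, 0.5),
                    vcd_amp = c(1, -0.6))$vcd
  expect_equal(spectral_similarity(s, s), 1)
  neg <- spectrum_table(s$wavenumber, -s$intensity, kind = "VCD")
  expect_equal(spectral_similarity(s, neg), -1)

  a <- gen_spectrum(1100, ir_amp = 1, vcd_amp = 1, gamma = 4)$vcd
  b <- gen_spectrum(1600, ir_amp = 1, vcd_amp = 1, gamma = 4)$vcd
  expect_lt(abs(spectral_similarity(a, b)), 0.02)

  s2 <- gen_spectrum(c(1150, 1450), ir_amp = c(1, 1),
                     vcd_amp = c(0.7, 0.9))$vcd
  expect_equal(spectral_similarity(s, s2), spectral_similarity(s2, s))
  s_scaled <- spectrum_table(s$wavenumber, 17 * s$intensity, kind = "VCD")
  expect_equal(spectral_similarity(s_scaled, s2), spectral_similarity(s, s2))

  out_of_window <- spectrum_table(seq(2500, 2600, 1), rep(1, 101), "VCD")
  expect_error(spectral_similarity(s, out_of_window), "overlap")
})

test_that("absolute configuration is assigned by the sign of the VCD match", {
  calc <- gen_spectrum(c(1100, 1300, 1550), ir_amp = c(1, 1, 1),
                       vcd_amp = c(1, -0.8, 0.6))$vcd
  set.seed(12)
  noisy <- spectrum_table(calc$wavenumber,
                          calc$intensity +
                            rnorm(length(calc$wavenumber),
                                  0, 0.02 * max(abs(calc$intensity))),
                          kind = "VCD")
  rep_aR <- assign_configuration(calc, noisy)
  expect_equal(rep_aR$assignment, "aR")
  expect_gt(rep_aR$margin, 1.9)

  mirrored <- spectrum_table(calc$wavenumber, -calc$intensity, kind = "VCD")
  expect_equal(assign_configuration(calc, mirrored)$assignment, "aS")

  ortho <- gen_spectrum(1425, ir_amp = 1, vcd_amp = 1, gamma = 3)$vcd
  expect_equal(assign_configuration(calc, ortho)$assignment, "inconclusive")

  ir <- gen_spectrum(1100, ir_amp = 1, vcd_amp = 1)$ir
  expect_error(assign_configuration(ir, calc), "VCD")
})

test_that("mixture fractions are recovered exactly without noise and within 0.05 with noise", {
  basis <- mixture_basis()
  exact <- fit_mixture_fraction(mixed_spectrum(basis, 0.5), basis$monomer,
                                basis$aggregate)
  expect_equal(exact$fraction, 0.5, tolerance = 1e-6)

  pure <- fit_mixture_fraction(mixed_spectrum(basis, 0), basis$monomer,
                               basis$aggregate)
  expect_equal(pure$fraction, 0, tolerance = 1e-6)

  noisy <- fit_mixture_fraction(mixed_spectrum(basis, 0.125, noise = 0.02,
                                               seed = 99),
                                basis$monomer, basis$aggregate)
  expect_equal(noisy$fraction, 0.125, tolerance = 0.03)

  expect_error(
    fit_mixture_fraction(mixed_spectrum(basis, 0.5), basis$monomer,
                         spectrum_table(basis$monomer$wavenumber,
                                        2 * basis$monomer$intensity, "VCD")),
    "unidentifiable")
})

test_that("mixture recovery stays within 0.05 across fractions and seeds", {
  basis <- mixture_basis()
  for (f in c(0.125, 0.25, 0.5)) {
    errs <- vapply(1:100, function(seed) {
      fit <- fit_mixture_fraction(
        mixed_spectrum(basis, f, noise = 0.02, seed = seed),
        basis$monomer, basis$aggregate)
      abs(fit$fraction - f)
    }, numeric(1))
    expect_lt(max(errs), 0.05)
  }
})

test_that("mirrored ensembles negate the weighted VCD but not the IR", {
  mk <- function(enantiomer) {
    a <- gen_spectrum(c(1150, 1500), ir_amp = c(1, 0.6),
                      vcd_amp = c(0.9, -0.5), enantiomer = enantiomer)
    b <- gen_spectrum(c(1250, 1600), ir_amp = c(0.8, 1),
                      vcd_amp = c(-0.4, 1), enantiomer = enantiomer)
    list(a = a, b = b)
  }
  w <- c(a = 0.6, b = 0.4)
  aR <- mk("aR"); aS <- mk("aS")
  vcd_aR <- weighted_spectrum(list(a = aR$a$vcd, b = aR$b$vcd), w)
  vcd_aS <- weighted_spectrum(list(a = aS$a$vcd, b = aS$b$vcd), w)
  ir_aR <- weighted_spectrum(list(a = aR$a$ir, b = aR$b$ir), w)
  ir_aS <- weighted_spectrum(list(a = aS$a$ir, b = aS$b$ir), w)
  expect_equal(vcd_aS$intensity, -vcd_aR$intensity)
  expect_equal(ir_aS$intensity, ir_aR$intensity)
})

test_that("spectrum tables read from CSV with kind metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# kind=VCD", "wavenumber_cm1,intensity",
               "1000,0.1", "1005,-0.2"), path)
  s <- read_spectrum(path)
  expect_equal(s$kind, "VCD")
  expect_equal(s$intensity, c(0.1, -0.2))
})
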