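# Independent oracles and small fixture builders used across test files.

# Brute-force enantiomerization barrier on a dense grid of an analytic
# profile: no stationary-point logic, no refinement — just arc maxima.
brute_force_barrier <- function(efun, by = 0.1) {
  chi <- seq(-180, 180 - by, by = by)
  e <- efun(chi)
  gs <- chi[which.min(e)]
  on_syn <- abs(chi) < abs(gs)
  on_anti <- abs(chi) > abs(gs)
  syn <- max(e[on_syn]) - min(e)
  anti <- max(e[on_anti]) - min(e)
  list(barrier = min(syn, anti),
       path = if (syn <= anti) "syn" else "anti",
       chi_gs = gs)
}

# Total-variation distance between an empirical width-degree histogram of
# angles and an analytic density over the same bins.
tv_to_density <- function(angles, dens_fun, width = 5) {
  h <- bin_dihedrals(angles, width)
  p_emp <- h$count / sum(h$count)
  p_true <- vapply(h$midpoint, dens_fun, numeric(1))
  p_true <- p_true / sum(p_true)
  0.5 * sum(abs(p_emp - p_true))
}

# A small rigid motion: random rotation (QR-orthogonalized) + translation.
random_rigid_motion <- function(g) {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- stats::rnorm(3, sd = 5)
  geometry(g$atoms, sweep(g$coords %*% Q, 2, -shift), name = g$name)
}

# Distinct monomer / aggregate band sets reused by the mixture tests.
mixture_basis <- function() {
  list(
    monomer = gen_spectrum(c(1100, 1250, 1400, 1600),
                           ir_amp = c(1, 0.8, 0.6, 1),
                           vcd_amp = c(1, -0.7, 0.5, -1))$vcd,
    aggregate = gen_spectrum(c(1050, 1200, 1350, 1550),
                             ir_amp = c(0.9, 1, 0.5, 0.8),
                             vcd_amp = c(-0.8, 1, -0.6, 0.9))$vcd)
}

# Mix the basis at aggregate fraction f with fractional amplitude noise.
mixed_spectrum <- function(basis, f, noise = 0, scale = 0.5, seed = NULL) {
  y <- scale * ((1 - f) * basis$monomer$intensity +
                  f * basis$aggregate$intensity)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise * max(abs(y)))
  }
  spectrum_table(basis$monomer$wavenumber, y, kind = "VCD")
}
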