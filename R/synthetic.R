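#' Synthetic torsional energy profile with known ground truth
#'
#' Builds a truncated cosine series
#' `E(chi) = sum_{n=1..3} c_n (1 + cos(n chi)) + asym * sin(chi)`
#' whose coefficients are solved from three linear conditions: E is
#' stationary at the requested ground-state dihedral chi0, and the syn
#' (0 degree) and anti (180 degree) orientations sit at the requested
#' barrier heights above the chi0 well. With `asym = 0` the profile is
#' exactly mirror-symmetric, `E(chi) = E(-chi)`, as enantiomeric poses
#' must be; a small `asym` emulates scan hysteresis. Gaussian noise of
#' sd `noise_sd` is added to the sampled energies.
#'
#' The symmetric special case chi0 = 90 with equal barriers B reduces to
#' the single-term well `E = (B/2) (1 + cos 2 chi)`.
#'
#' @param chi0 ground-state dihedral, degrees, in (0, 180).
#' @param syn_barrier barrier at the planar syn orientation (0 deg),
#'   kcal/mol above the well.
#' @param anti_barrier barrier at the anti orientation (180 deg), kcal/mol.
#' @param asym amplitude of the mirror-breaking `sin(chi)` term, kcal/mol.
#' @param increment sampling grid increment, degrees.
#' @param noise_sd Gaussian energy noise, kcal/mol.
#' @param window `"raw"` (scan-style 180-540 window) or `"principal"`.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return A list with `profile` (a [torsion_profile()]) and `truth`
#'   (coefficients, analytic minima, syn/anti path maxima and the
#'   enantiomerization barrier from a dense 0.01-degree evaluation, plus
#'   `energy_fn`, the analytic profile as a function of degrees).
#' @export
gen_torsion_profile <- function(chi0, syn_barrier, anti_barrier,
                                asym = 0, increment = 10, noise_sd = 0,
                                window = c("raw", "principal"),
                                seed = NULL) {
  window <- match.arg(window)
  if (chi0 <= 0 || chi0 >= 180) stop("chi0 must lie strictly in (0, 180)")
  if (syn_barrier <= 0 || anti_barrier <= 0) stop("barriers must be positive")
  x0 <- chi0 * pi / 180
  # rows: stationarity at chi0; syn barrier; anti barrier
  A <- rbind(c(sin(x0), 2 * sin(2 * x0), 3 * sin(3 * x0)),
             c(1 - cos(x0), 1 - cos(2 * x0), 1 - cos(3 * x0)),
             c(-(1 + cos(x0)), 1 - cos(2 * x0), -(1 + cos(3 * x0))))
  cf <- tryCatch(solve(A, c(0, syn_barrier, anti_barrier)),
                 error = function(e)
                   stop("infeasible (chi0, barrier) combination: ",
                        conditionMessage(e)))
  efun <- function(chi_deg) {
    x <- chi_deg * pi / 180
    cf[1] * (1 + cos(x)) + cf[2] * (1 + cos(2 * x)) + cf[3] * (1 + cos(3 * x)) +
      asym * sin(x)
  }
  # curvature at chi0 must be positive (a genuine well) and the well must
  # be the global minimum of the series
  curv <- -(cf[1] * cos(x0) + 4 * cf[2] * cos(2 * x0) + 9 * cf[3] * cos(3 * x0))
  dense <- seq(-180, 180, by = 0.01)
  ed <- efun(dense)
  if (asym == 0 && (curv <= 0 || min(ed) < efun(chi0) - 1e-6))
    stop("infeasible (chi0, barrier) combination: chi0 is not the global ",
         "minimum of the solved cosine series")
  gmin <- dense[which.min(ed)]
  pos_min <- dense[dense > 0][which.min(ed[dense > 0])]
  neg_min <- dense[dense < 0][which.min(ed[dense < 0])]
  on_syn <- abs(dense) < abs(pos_min)
  on_anti <- abs(dense) > abs(pos_min)
  syn_max <- max(ed[on_syn]) - min(ed)
  anti_max <- max(ed[on_anti]) - min(ed)
  truth <- list(coefficients = cf,
                chi_min = c(neg_min, pos_min),
                chi_global_min = gmin,
                syn_path_max = syn_max, anti_path_max = anti_max,
                barrier = min(syn_max, anti_max),
                path = if (syn_max <= anti_max) "syn" else "anti",
                energy_fn = efun)
  grid <- if (window == "raw") seq(180, 540, by = increment)
          else seq(-180 + increment, 180, by = increment)
  e <- efun(fold_angle(grid))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    e <- e + stats::rnorm(length(e), 0, noise_sd)
  }
  prof <- torsion_profile(grid, e, window = window,
                          compound = "synthetic", increment = increment)
  list(profile = prof, truth = truth)
}

#' Synthetic racemization time courses with known rates
#'
#' Emulates variable-temperature chiral-HPLC monitoring of an enantiopure
#' sample: `ee(t) = ee0 * exp(-2 k(T) t)` with the one-way rate k(T)
#' given by the Eyring equation from the true barrier (either a fixed
#' `dg` or the pair `dH`/`dS`). Time points span `n_halflives` ee
#' half-lives at each temperature. Additive Gaussian noise of sd
#' `noise_sd` (fraction of ee0) is applied and values are floored at
#' 1e-6.
#'
#' @param temperatures K (one course per temperature).
#' @param dg true activation free energy, kcal/mol (temperature
#'   independent), or NULL when using `dH`/`dS`.
#' @param dH,dS true activation enthalpy (kcal/mol) and entropy
#'   (kcal/mol/K); used when `dg` is NULL.
#' @param n_points time points per course.
#' @param n_halflives course duration in ee half-lives.
#' @param ee0 initial enantiomeric excess.
#' @param noise_sd Gaussian ee noise, as a fraction of `ee0`.
#' @param seed RNG seed; same seed, same output.
#' @return A list with `timecourses` (list of
#'   [racemization_timecourse()]s, named by temperature) and `truth`
#'   (per-temperature true `k` and `dg`).
#' @export
gen_racemization <- function(temperatures, dg = NULL, dH = NULL, dS = NULL,
                             n_points = 12, n_halflives = 5, ee0 = 1,
                             noise_sd = 0, seed = NULL) {
  stopifnot(length(temperatures) >= 1L, all(temperatures > 0),
            n_points >= 3L, noise_sd >= 0, abs(ee0) <= 1)
  if (is.null(dg) && (is.null(dH) || is.null(dS)))
    stop("supply dg, or both dH and dS")
  if (!is.null(seed)) set.seed(seed)
  dg_at <- function(temp) if (!is.null(dg)) dg else dH - temp * dS
  courses <- list(); ks <- numeric(0); dgs <- numeric(0)
  for (temp in temperatures) {
    k <- eyring_rate(dg_at(temp), temp)$k
    half <- log(2) / (2 * k)
    t <- seq(0, n_halflives * half, length.out = n_points)
    ee <- ee0 * exp(-2 * k * t)
    if (noise_sd > 0) ee <- ee + stats::rnorm(n_points, 0, noise_sd * abs(ee0))
    ee <- pmin(pmax(ee, 1e-6), 1)
    courses[[as.character(temp)]] <-
      racemization_timecourse(t, ee = ee, temperature = temp)
    ks <- c(ks, k); dgs <- c(dgs, dg_at(temp))
  }
  list(timecourses = courses,
       truth = list(k = stats::setNames(ks, temperatures),
                    dg = stats::setNames(dgs, temperatures)))
}

#' Synthetic Lorentzian band spectra for one enantiomer
#'
#' Sum-of-Lorentzians model `sum_i A_i * gamma^2 / ((nu - nu_i)^2 +
#' gamma^2)`: the IR uses the positive absorption amplitudes, the VCD the
#' signed rotational amplitudes. The aS enantiomer has the identical IR
#' and the pointwise-negated VCD. Noise is Gaussian with sd `noise_sd`
#' times the maximum absolute intensity of each spectrum.
#'
#' @param centers band centers, cm^-1.
#' @param ir_amp positive IR absorption amplitudes (one per band).
#' @param vcd_amp signed VCD amplitudes (one per band).
#' @param gamma Lorentzian half-width, cm^-1.
#' @param grid wavenumber grid, cm^-1 (default 900-1800 at 1 cm^-1).
#' @param noise_sd noise fraction of the maximum |intensity|.
#' @param enantiomer `"aR"` or `"aS"`.
#' @param seed RNG seed.
#' @return A list with `ir` and `vcd` [spectrum_table()]s.
#' @export
gen_spectrum <- function(centers, ir_amp, vcd_amp, gamma = 8,
                         grid = seq(900, 1800, by = 1), noise_sd = 0,
                         enantiomer = c("aR", "aS"), seed = NULL) {
  enantiomer <- match.arg(enantiomer)
  stopifnot(length(centers) == length(ir_amp),
            length(centers) == length(vcd_amp), gamma > 0,
            all(ir_amp >= 0))
  if (min(grid) > min(centers) || max(grid) < max(centers))
    stop("grid must cover all band centers")
  if (!is.null(seed)) set.seed(seed)
  lor <- function(amp) {
    y <- numeric(length(grid))
    for (i in seq_along(centers))
      y <- y + amp[i] * gamma^2 / ((grid - centers[i])^2 + gamma^2)
    y
  }
  ir <- lor(ir_amp)
  vcd <- lor(vcd_amp) * if (enantiomer == "aS") -1 else 1
  if (noise_sd > 0) {
    ir <- ir + stats::rnorm(length(grid), 0, noise_sd * max(abs(ir)))
    vcd <- vcd + stats::rnorm(length(grid), 0, noise_sd * max(abs(vcd)))
  }
  list(ir = spectrum_table(grid, ir, kind = "IR"),
       vcd = spectrum_table(grid, vcd, kind = "VCD"))
}

#' Metropolis-sampled dihedral series from a torsional profile
#'
#' Samples the Boltzmann density `p(chi) proportional to exp(-E(chi)/RT)`
#' on the circle with a Metropolis chain: Gaussian proposals of sd
#' `step` (5 degrees by default), energies linearly interpolated between
#' profile grid points with periodic wrap, the first 10 percent of the
#' chain discarded as burn-in. The chain starts at the profile's grid
#' minimum.
#'
#' @param profile a principal-window [torsion_profile()].
#' @param temperature K.
#' @param n number of retained samples.
#' @param step proposal sd, degrees.
#' @param burn_frac fraction of the total chain discarded (default 0.1).
#' @param state `"bound"` or `"unbound"` label for the output.
#' @param compound compound label.
#' @param seed RNG seed; same seed, same series.
#' @return A [dihedral_series()] with `n` samples.
#' @export
gen_dihedral_series <- function(profile, temperature, n, step = 5,
                                burn_frac = 0.1, state = "unbound",
                                compound = "", seed = NULL) {
  stopifnot(inherits(profile, "torsion_profile"), n >= 1L,
            temperature > 0, step > 0, burn_frac >= 0, burn_frac < 1)
  if (profile$window != "principal")
    stop("gen_dihedral_series needs a principal-window profile")
  if (!is.null(seed)) set.seed(seed)
  # periodic linear interpolation table over one full wrap
  xs <- c(profile$angles, profile$angles[1L] + 360)
  ys <- c(profile$energies, profile$energies[1L])
  rt <- eyring_constants$R * temperature
  slope <- diff(ys) / diff(xs)
  efun <- function(chi) {
    x <- chi - 360 * floor((chi - xs[1L]) / 360)  # into [xs[1], xs[1]+360)
    i <- findInterval(x, xs, rightmost.closed = TRUE)
    ys[i] + slope[i] * (x - xs[i])
  }
  total <- ceiling(n / (1 - burn_frac))
  prop <- stats::rnorm(total, 0, step)
  logu <- log(stats::runif(total))
  chain <- numeric(total)
  x <- profile$angles[which.min(profile$energies)]
  ex <- efun(x)
  for (i in seq_len(total)) {
    cand <- x + prop[i]
    ec <- efun(cand)
    if (logu[i] < (ex - ec) / rt) {
      x <- cand; ex <- ec
    }
    chain[i] <- x
  }
  keep <- chain[(total - n + 1L):total]
  dihedral_series(seq_len(n), fold_angle(keep), state = state,
                  compound = compound)
}

#' Synthetic NCI-60-style screen panel with known correlations
#'
#' Each compound's per-line log10 endpoint is
#' `base_log10 + loadings %*% mechanism + residual`, where the latent
#' mechanism vectors are iid standard normal per cell line and residuals
#' are iid `N(0, residual_sd^2)`. The implied population correlation
#' between compounds a and b is
#' `(l_a . l_b) / sqrt((|l_a|^2 + sd^2)(|l_b|^2 + sd^2))`, returned as
#' the ground-truth correlation matrix.
#'
#' @param loadings numeric matrix, compounds x mechanisms; row names are
#'   the compound labels.
#' @param n_lines number of cell lines (>= 3).
#' @param residual_sd residual sd, log10 units.
#' @param base_log10 baseline log10 molar endpoint.
#' @param endpoint `"GI50"` or `"TGI"` label for the fingerprints.
#' @param seed RNG seed.
#' @return A list with `fingerprints` (named list of
#'   [screen_fingerprint()]s) and `truth` (`correlation` matrix).
#' @export
gen_screen_panel <- function(loadings, n_lines = 55, residual_sd = 0.2,
                             base_log10 = -6, endpoint = "GI50",
                             seed = NULL) {
  loadings <- as.matrix(loadings)
  if (n_lines < 3L) stop("at least 3 cell lines required")
  if (is.null(rownames(loadings)))
    rownames(loadings) <- paste0("compound", seq_len(nrow(loadings)))
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(loadings)
  mech <- matrix(stats::rnorm(n_lines * m), n_lines, m)
  lines <- sprintf("CL%02d", seq_len(n_lines))
  fps <- list()
  for (i in seq_len(nrow(loadings))) {
    val <- base_log10 + drop(mech %*% loadings[i, ]) +
      stats::rnorm(n_lines, 0, residual_sd)
    fps[[rownames(loadings)[i]]] <-
      screen_fingerprint(lines, val, endpoint = endpoint)
  }
  G <- loadings %*% t(loadings)
  v <- diag(G) + residual_sd^2
  truth_cor <- G / sqrt(outer(v, v))
  diag(truth_cor) <- 1
  list(fingerprints = fps, truth = list(correlation = truth_cor))
}
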