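#' Wavenumber-gridded spectrum
#'
#' @param wavenumber cm^-1, strictly increasing.
#' @param intensity arbitrary units; IR absorbance (non-negative in
#'   practice) or signed VCD delta-absorbance.
#' @param kind `"IR"` or `"VCD"`.
#' @param resolution nominal resolution note, cm^-1.
#' @return An object of class `spectrum_table`.
#' @export
spectrum_table <- function(wavenumber, intensity, kind = c("IR", "VCD"),
                           resolution = NA_real_) {
  kind <- match.arg(kind)
  wavenumber <- as.numeric(wavenumber); intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity lengths differ")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 kind = kind, resolution = resolution),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("<spectrum_table> %s, %d points, %g-%g cm^-1\n", x$kind,
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Read a spectrum table
#'
#' CSV with header `wavenumber_cm1,intensity`; `# kind=VCD` (or IR)
#' comment lines set the kind unless overridden.
#'
#' @param path input path.
#' @param kind `"IR"` or `"VCD"`; overrides any comment.
#' @return A [spectrum_table()].
#' @export
read_spectrum <- function(path, kind = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(kind)) {
    m <- grep("^#\\s*kind\\s*=", lines, value = TRUE)
    kind <- if (length(m)) toupper(trimws(sub("^#\\s*kind\\s*=", "", m[1L])))
            else "IR"
  }
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  spectrum_table(d$wavenumber_cm1, d$intensity, kind = kind)
}

#' Resample a spectrum onto a new grid by linear interpolation
#'
#' @param s a [spectrum_table()].
#' @param grid target wavenumbers, cm^-1 (within the spectrum's range).
#' @return A [spectrum_table()] on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "spectrum_table"))
  grid <- sort(as.numeric(grid))
  y <- stats::approx(s$wavenumber, s$intensity, xout = grid, rule = 2)$y
  spectrum_table(grid, y, kind = s$kind, resolution = s$resolution)
}

# common grid = the finer of the two grids, restricted to the overlap
.common_grid <- function(a, b, window = NULL) {
  lo <- max(min(a$wavenumber), min(b$wavenumber))
  hi <- min(max(a$wavenumber), max(b$wavenumber))
  if (!is.null(window)) {
    lo <- max(lo, min(window)); hi <- min(hi, max(window))
  }
  if (lo >= hi) stop("spectral windows do not overlap")
  step_a <- stats::median(diff(a$wavenumber))
  step_b <- stats::median(diff(b$wavenumber))
  finer <- if (step_a <= step_b) a else b
  g <- finer$wavenumber[finer$wavenumber >= lo & finer$wavenumber <= hi]
  if (length(g) < 2L) stop("fewer than 2 grid points in the overlap window")
  g
}

#' Boltzmann weights of a conformer ensemble
#'
#' `w_i = exp(-dE_i / RT) / sum_j exp(-dE_j / RT)` using the chosen
#' energy (free or electronic). Conformers whose weight falls below
#' `threshold` are dropped and the remainder renormalized to sum 1 — the
#' conventional "contributing 1 percent or greater" cutoff.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param energy `"free"` or `"electronic"`.
#' @param threshold minimum retained weight (default 0.01).
#' @return Named numeric vector of weights (names = conformer ids),
#'   summing to 1.
#' @export
boltzmann_weights <- function(ensemble, energy = c("free", "electronic"),
                              threshold = 0.01) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  energy <- match.arg(energy)
  field <- if (energy == "free") "dG" else "dE"
  e <- vapply(ensemble$conformers, function(cf) {
    v <- cf[[field]]
    if (is.null(v) || !is.finite(v))
      stop("conformer '", cf$id, "' lacks a finite ", energy, " energy")
    v
  }, numeric(1))
  rt <- eyring_constants$R * ensemble$temperature
  w <- exp(-(e - min(e)) / rt)
  w <- w / sum(w)
  names(w) <- vapply(ensemble$conformers, `[[`, character(1), "id")
  keep <- w >= threshold
  if (!any(keep)) stop("threshold removed every conformer")
  w <- w[keep] / sum(w[keep])
  w
}

#' Conformer with energies, chiral-axis dihedral and spectra
#'
#' @param id unique identifier.
#' @param dG relative free energy, kcal/mol (reference conformer 0).
#' @param dE relative electronic energy, kcal/mol.
#' @param chi chiral-axis dihedral, degrees.
#' @param ir,vcd optional [spectrum_table()]s.
#' @return An object of class `conformer`.
#' @export
conformer <- function(id, dG = NULL, dE = NULL, chi = NA_real_,
                      ir = NULL, vcd = NULL) {
  if (is.null(dG) && is.null(dE))
    stop("a conformer needs at least one of dG/dE")
  structure(list(id = as.character(id), dG = dG, dE = dE, chi = chi,
                 ir = ir, vcd = vcd),
            class = "conformer")
}

#' Conformer ensemble
#'
#' @param conformers list of [conformer()]s with unique ids.
#' @param temperature K.
#' @param window energy window note, kcal/mol (informational; a 7
#'   kcal/mol search window is typical).
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(conformers, temperature = 298.15,
                               window = NA_real_) {
  stopifnot(length(conformers) >= 1L,
            all(vapply(conformers, inherits, logical(1), "conformer")))
  ids <- vapply(conformers, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("conformer ids must be unique")
  if (temperature <= 0) stop("temperature must be positive (K)")
  structure(list(conformers = conformers, temperature = temperature,
                 window = window),
            class = "conformer_ensemble")
}

#' Weight-average spectra on a common grid
#'
#' @param spectra named list of [spectrum_table()]s (same kind).
#' @param weights named weights summing to 1; names must match `spectra`.
#' @return The pointwise weighted sum as a [spectrum_table()] on the
#'   finest common grid.
#' @export
weighted_spectrum <- function(spectra, weights) {
  stopifnot(length(spectra) >= 1L)
  if (is.null(names(spectra)) || is.null(names(weights)))
    stop("spectra and weights must be named by conformer id")
  if (!all(names(weights) %in% names(spectra)))
    stop("weights refer to unknown spectra: ",
         paste(setdiff(names(weights), names(spectra)), collapse = ", "))
  spectra <- spectra[names(weights)]
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  kinds <- unique(vapply(spectra, `[[`, character(1), "kind"))
  if (length(kinds) != 1L)
    stop("kind mismatch: cannot average IR and VCD spectra together")
  grid <- Reduce(function(g, s) .common_grid(spectrum_table(g, g * 0, kinds), s),
                 spectra[-1L], init = spectra[[1L]]$wavenumber)
  y <- 0
  for (nm in names(weights))
    y <- y + weights[[nm]] * resample_spectrum(spectra[[nm]], grid)$intensity
  spectrum_table(grid, y, kind = kinds)
}

#' Process experimental VCD blocks
#'
#' The measurement protocol: average the 1-hour data blocks for each
#' enantiomer, form the half-difference `(E1bar - E2bar) / 2` (which
#' cancels instrument baseline common to both enantiomers), then offset
#' the result to zero at the anchor wavenumber (2000 cm^-1 by default, a
#' signal-free region).
#'
#' @param blocks_e1,blocks_e2 lists of [spectrum_table()]s, one or more
#'   blocks per enantiomer.
#' @param anchor wavenumber at which the output is zeroed, cm^-1.
#' @return A VCD [spectrum_table()] whose value at `anchor` is exactly 0.
#' @export
process_experimental_vcd <- function(blocks_e1, blocks_e2, anchor = 2000) {
  if (inherits(blocks_e1, "spectrum_table")) blocks_e1 <- list(blocks_e1)
  if (inherits(blocks_e2, "spectrum_table")) blocks_e2 <- list(blocks_e2)
  stopifnot(length(blocks_e1) >= 1L, length(blocks_e2) >= 1L)
  all_blocks <- c(blocks_e1, blocks_e2)
  ref <- all_blocks[[1L]]$wavenumber
  same <- all(vapply(all_blocks, function(s)
    length(s$wavenumber) == length(ref) &&
      all(abs(s$wavenumber - ref) < 1e-9), logical(1)))
  if (!same) {
    warning("blocks are on different grids; resampling to the first block")
    all_blocks <- lapply(all_blocks, resample_spectrum, grid = ref)
    blocks_e1 <- all_blocks[seq_along(blocks_e1)]
    blocks_e2 <- all_blocks[-seq_along(blocks_e1)]
  }
  avg <- function(blocks)
    Reduce(`+`, lapply(blocks, `[[`, "intensity")) / length(blocks)
  half_diff <- (avg(blocks_e1) - avg(blocks_e2)) / 2
  i <- which(abs(ref - anchor) < 1e-9)
  if (length(i) == 0L)
    stop("anchor wavenumber ", anchor, " cm^-1 is not on the block grid")
  spectrum_table(ref, half_diff - half_diff[i[1L]], kind = "VCD")
}

#' Scale the wavenumber axis of a computed spectrum
#'
#' Harmonic DFT frequencies overestimate observed band positions; a
#' multiplicative x-axis scale factor (typically 0.96-0.99 depending on
#' functional/basis) aligns them. `search = TRUE` scans sigma over
#' [0.96, 1.00] in steps of 0.001 and returns the factor maximizing the
#' similarity to `reference`.
#'
#' @param s a [spectrum_table()].
#' @param sigma scale factor in [0.9, 1.1].
#' @param search if TRUE, scan for the best factor against `reference`.
#' @param reference experimental [spectrum_table()] (search mode only).
#' @param window similarity window for the search, cm^-1.
#' @return Scaled [spectrum_table()]; in search mode a list with
#'   `spectrum`, `sigma` and `similarity`.
#' @export
scale_wavenumbers <- function(s, sigma = 1, search = FALSE,
                              reference = NULL, window = c(1000, 1700)) {
  stopifnot(inherits(s, "spectrum_table"))
  if (!search) {
    if (sigma < 0.9 || sigma > 1.1)
      stop("sigma outside the guard range [0.9, 1.1]")
    return(spectrum_table(s$wavenumber * sigma, s$intensity, kind = s$kind,
                          resolution = s$resolution))
  }
  if (is.null(reference)) stop("search mode needs a reference spectrum")
  sigmas <- seq(0.96, 1.00, by = 0.001)
  sims <- vapply(sigmas, function(sg)
    spectral_similarity(scale_wavenumbers(s, sg), reference, window = window),
    numeric(1))
  best <- which.max(sims)
  list(spectrum = scale_wavenumbers(s, sigmas[best]),
       sigma = sigmas[best], similarity = sims[best])
}

#' Normalized inner-product similarity of two spectra
#'
#' Carbo-like index `sum(a*b) / sqrt(sum(a^2) * sum(b^2))` after
#' resampling both spectra to the finer common grid inside the window.
#' Symmetric, scale-invariant in each argument, and in [-1, 1].
#'
#' @param a,b [spectrum_table()]s.
#' @param window comparison window, cm^-1 (default 1000-1700, the
#'   fingerprint region).
#' @return Similarity in [-1, 1].
#' @export
spectral_similarity <- function(a, b, window = c(1000, 1700)) {
  stopifnot(inherits(a, "spectrum_table"), inherits(b, "spectrum_table"))
  g <- .common_grid(a, b, window = window)
  ya <- resample_spectrum(a, g)$intensity
  yb <- resample_spectrum(b, g)$intensity
  na <- sqrt(sum(ya^2)); nb <- sqrt(sum(yb^2))
  if (na == 0 || nb == 0) return(0)
  sum(ya * yb) / (na * nb)
}

#' Assign absolute configuration from a VCD comparison
#'
#' The calculated VCD of the aR enantiomer and its negation (the aS
#' prediction) are each compared with the experimental spectrum; the sign
#' winner gives the assignment, and the margin (difference of the two
#' similarities, in [-2, 2]) the confidence. Margins below
#' `confidence_floor` are inconclusive.
#'
#' @param calc_aR calculated VCD [spectrum_table()] for the aR enantiomer.
#' @param experimental measured VCD [spectrum_table()].
#' @param window comparison window, cm^-1.
#' @param confidence_floor minimum |margin| for a hard call (default 0.1).
#' @return A list of class `similarity_report`: `assignment` (`"aR"`,
#'   `"aS"` or `"inconclusive"`), `similarity` (of the winning
#'   hypothesis), `margin`, `window`.
#' @export
assign_configuration <- function(calc_aR, experimental,
                                 window = c(1000, 1700),
                                 confidence_floor = 0.1) {
  stopifnot(inherits(calc_aR, "spectrum_table"),
            inherits(experimental, "spectrum_table"))
  if (calc_aR$kind != "VCD" || experimental$kind != "VCD")
    stop("configuration assignment needs VCD spectra on both sides")
  s_aR <- spectral_similarity(calc_aR, experimental, window = window)
  calc_aS <- spectrum_table(calc_aR$wavenumber, -calc_aR$intensity,
                            kind = "VCD")
  s_aS <- spectral_similarity(calc_aS, experimental, window = window)
  margin <- s_aR - s_aS  # equals 2 * s_aR by antisymmetry
  assignment <- if (abs(margin) < confidence_floor) "inconclusive"
                else if (margin > 0) "aR" else "aS"
  structure(list(assignment = assignment,
                 similarity = max(s_aR, s_aS), margin = margin,
                 window = window),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report> assignment %s (similarity %.3f, margin %.3f, window %g-%g cm^-1)\n",
    x$assignment, x$similarity, x$margin, x$window[1], x$window[2]))
  invisible(x)
}

#' Fit the monomer/aggregate mixture fraction of a spectrum
#'
#' Models the observed spectrum as a scaled convex combination
#' `s * ((1 - f) * monomer + f * aggregate)` and minimizes the squared
#' residual over the scale `s > 0` and the aggregate (dimer) fraction
#' `f` in [0, 1]. For fixed f the optimal scale is closed-form, leaving
#' a 1-D bounded search in f.
#'
#' @param experimental observed [spectrum_table()].
#' @param monomer,aggregate basis [spectrum_table()]s (not proportional).
#' @param window fit window, cm^-1 (NULL = full overlap).
#' @return A list of class `mixture_fit`: `fraction` (f), `percent`,
#'   `scale`, `residual` (L2 norm).
#' @export
fit_mixture_fraction <- function(experimental, monomer, aggregate,
                                 window = NULL) {
  stopifnot(inherits(experimental, "spectrum_table"),
            inherits(monomer, "spectrum_table"),
            inherits(aggregate, "spectrum_table"))
  g <- .common_grid(monomer, aggregate, window = window)
  g <- g[g >= min(experimental$wavenumber) & g <= max(experimental$wavenumber)]
  if (length(g) < 3L) stop("overlap window too small for mixture fitting")
  y <- resample_spectrum(experimental, g)$intensity
  m <- resample_spectrum(monomer, g)$intensity
  a <- resample_spectrum(aggregate, g)$intensity
  cosang <- sum(m * a) / sqrt(sum(m^2) * sum(a^2))
  if (abs(cosang) > 1 - 1e-9)
    stop("unidentifiable: monomer and aggregate spectra are proportional")
  rss <- function(f) {
    basis <- (1 - f) * m + f * a
    denom <- sum(basis^2)
    s <- if (denom > 0) max(sum(y * basis) / denom, 0) else 0
    sum((y - s * basis)^2)
  }
  opt <- stats::optimize(rss, interval = c(0, 1), tol = 1e-9)
  # optimize() never evaluates the exact endpoints; check them explicitly
  cand <- rbind(c(opt$minimum, opt$objective), c(0, rss(0)), c(1, rss(1)))
  f <- cand[which.min(cand[, 2]), 1]
  basis <- (1 - f) * m + f * a
  s <- max(sum(y * basis) / sum(basis^2), 0)
  structure(list(fraction = f, percent = 100 * f, scale = s,
                 residual = sqrt(sum((y - s * basis)^2))),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> aggregate fraction %.3f (%.1f%%), scale %.3g, residual %.3g\n",
    x$fraction, x$percent, x$scale, x$residual))
  invisible(x)
}
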