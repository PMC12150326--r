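#' Torsional energy profile
#'
#' A periodic map from the chiral-axis dihedral chi (degrees) to relative
#' energy (kcal/mol). Profiles come in two representations: the raw scan
#' window as produced by an iterative relaxed scan (e.g. 180-540 degrees)
#' and the principal window (-180, 180].
#'
#' Energies are always re-referenced so that the profile minimum is 0.
#'
#' @param angles numeric, degrees, strictly increasing within one window.
#' @param energies numeric, kcal/mol, same length as `angles`.
#' @param window `"raw"` or `"principal"`.
#' @param compound optional compound label.
#' @param increment scan increment in degrees (informational).
#' @return An object of class `torsion_profile`.
#' @export
torsion_profile <- function(angles, energies, window = c("raw", "principal"),
                            compound = "", increment = NA_real_) {
  window <- match.arg(window)
  angles <- as.numeric(angles); energies <- as.numeric(energies)
  if (length(angles) != length(energies))
    stop("angles and energies must have the same length")
  if (length(angles) < 2L) stop("a profile needs at least 2 points")
  if (any(diff(angles) <= 0))
    stop("angles must be strictly increasing within the window")
  if (!all(is.finite(energies))) stop("energies must be finite")
  if (window == "principal" && (any(angles <= -180) || any(angles > 180)))
    stop("principal-window angles must lie in (-180, 180]")
  structure(list(angles = angles,
                 energies = energies - min(energies),
                 window = window, compound = as.character(compound),
                 increment = increment),
            class = "torsion_profile")
}

#' @export
print.torsion_profile <- function(x, ...) {
  cat("<torsion_profile>",
      if (nzchar(x$compound)) x$compound else "(unlabelled)",
      "-", length(x$angles), "points,", x$window, "window [",
      min(x$angles), ",", max(x$angles), "] deg, Emax",
      round(max(x$energies), 2), "kcal/mol\n")
  invisible(x)
}

#' Read a torsional scan table
#'
#' Two-column CSV/TSV with header `chi_deg,energy_kcal`; lines starting
#' with `#` are metadata comments.
#'
#' @param path input path.
#' @param window window tag passed to [torsion_profile()].
#' @return A [torsion_profile()].
#' @export
read_torsion_scan <- function(path, window = "raw") {
  first <- grep("^[^#]", readLines(path, warn = FALSE), value = TRUE)[1L]
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  if (!all(c("chi_deg", "energy_kcal") %in% names(d)))
    stop("scan table must have columns chi_deg and energy_kcal")
  torsion_profile(d$chi_deg, d$energy_kcal, window = window)
}

#' Fold a raw scan window onto the principal window (-180, 180]
#'
#' Angles are mapped by `chi' = ((chi + 180) mod 360) - 180` and sorted.
#' When the raw window's endpoints are 360 degrees apart they fold onto
#' the same angle; the lower of the two energies is kept (iterative
#' relaxed scans can end on a different methoxy rotamer than they start
#' on, so the endpoints need not be equivalent). Energies are
#' re-referenced to min = 0.
#'
#' @param p a [torsion_profile()].
#' @return A principal-window [torsion_profile()].
#' @export
fold_to_principal <- function(p) {
  stopifnot(inherits(p, "torsion_profile"))
  chi <- fold_angle(p$angles)
  e <- p$energies
  o <- order(chi)
  chi <- chi[o]; e <- e[o]
  # resolve fold duplicates: keep the lower energy at each angle
  key <- round(chi, 6)
  if (anyDuplicated(key)) {
    keep <- !logical(length(key))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      keep[idx] <- FALSE
      keep[idx[which.min(e[idx])]] <- TRUE
    }
    chi <- chi[keep]; e <- e[keep]
  }
  # circular coverage check: the folded grid must tile the full circle
  gaps <- diff(c(chi, chi[1L] + 360))
  if (max(gaps) > 2 * stats::median(gaps) + 1e-9)
    stop("incomplete scan: folded window does not cover 360 degrees ",
         "(largest angular gap ", round(max(gaps), 3), " deg)")
  torsion_profile(chi, e, window = "principal",
                  compound = p$compound, increment = p$increment)
}

#' Symmetrize a profile over the two enantiomers
#'
#' For an axially chiral rotor the poses at chi and -chi are enantiomeric
#' and strictly isoenergetic; scan hysteresis makes the computed energies
#' differ. The symmetrized profile takes the lower energy of each mirror
#' pair, `E_sym(chi) = min(E(chi), E(-chi))`, reported on [0, 180] and
#' re-referenced to min = 0. 0 and 180 are their own mirrors.
#'
#' @param p a principal-window [torsion_profile()] containing both members
#'   of every mirror pair.
#' @param tol angle-matching tolerance in degrees.
#' @return A [torsion_profile()] over [0, 180] (window tag `"principal"`).
#' @export
symmetrize_enantiomers <- function(p, tol = 1e-6) {
  stopifnot(inherits(p, "torsion_profile"))
  if (p$window != "principal")
    stop("symmetrize_enantiomers needs a principal-window profile; ",
         "call fold_to_principal() first")
  chi <- p$angles; e <- p$energies
  pos <- sort(unique(round(abs(chi), 6)))
  esym <- numeric(length(pos))
  orphans <- numeric(0)
  for (i in seq_along(pos)) {
    a <- pos[i]
    hit_p <- which(abs(chi - a) <= tol)
    hit_m <- which(abs(chi + a) <= tol)
    if (a <= tol || abs(a - 180) <= tol) {
      # self-paired: -180 folds to +180, 0 to 0
      esym[i] <- min(e[c(hit_p, hit_m)])
    } else if (length(hit_p) == 0L || length(hit_m) == 0L) {
      orphans <- c(orphans, if (length(hit_p) == 0L) -a else a)
      esym[i] <- NA_real_
    } else {
      esym[i] <- min(e[hit_p], e[hit_m])
    }
  }
  if (length(orphans))
    stop("cannot pair enantiomeric grid points; missing mirror angles: ",
         paste(round(-abs(orphans), 3), collapse = ", "))
  torsion_profile(pos, esym, window = "principal",
                  compound = p$compound, increment = p$increment)
}

# Parabola through (x1,y1),(x2,y2),(x3,y3); returns vertex location,
# vertex value and curvature (quadratic coefficient).
.parabola_vertex <- function(x, y) {
  dx1 <- x[1] - x[2]; dx3 <- x[3] - x[2]
  # y = a + b*t + c*t^2 with t = x - x[2]
  c2 <- ((y[1] - y[2]) / dx1 - (y[3] - y[2]) / dx3) / (dx1 - dx3)
  b <- (y[1] - y[2]) / dx1 - c2 * dx1
  if (abs(c2) < 1e-12)
    return(list(x = x[2], y = y[2], curv = c2, flat = TRUE))
  t0 <- -b / (2 * c2)
  list(x = x[2] + t0, y = y[2] + b * t0 + c2 * t0^2, curv = c2, flat = FALSE)
}

#' Locate stationary points of a periodic torsional profile
#'
#' Interior and wrap-around local minima and maxima are found by discrete
#' comparison with periodic grid neighbours, then each is refined by a
#' 3-point parabolic fit through the extremum and its two neighbours.
#' A flat triple (three equal energies) is reported at the grid point
#' with `flat = TRUE`.
#'
#' @param p a principal-window [torsion_profile()].
#' @return A data.frame with columns `chi` (deg, refined), `energy`
#'   (kcal/mol, refined), `kind` (`"minimum"`/`"maximum"`) and `flat`.
#' @export
locate_stationary_points <- function(p) {
  stopifnot(inherits(p, "torsion_profile"))
  if (p$window != "principal")
    stop("locate_stationary_points needs a principal-window profile")
  chi <- p$angles; e <- p$energies
  n <- length(chi)
  if (n < 4L) stop("profile too short for stationary-point analysis")
  prev <- c(n, seq_len(n - 1L)); nxt <- c(seq_len(n - 1L) + 1L, 1L)
  out <- list()
  for (i in seq_len(n)) {
    em <- e[prev[i]]; e0 <- e[i]; ep <- e[nxt[i]]
    kind <- if (e0 < em && e0 < ep) "minimum"
            else if (e0 > em && e0 > ep) "maximum"
            else if (em == e0 && e0 == ep) "flat"
            else NA_character_
    if (is.na(kind)) next
    # unwrap neighbour angles around chi[i] for the local fit
    xm <- chi[prev[i]]; xp <- chi[nxt[i]]
    if (xm > chi[i]) xm <- xm - 360
    if (xp < chi[i]) xp <- xp + 360
    if (kind == "flat") {
      out[[length(out) + 1L]] <-
        data.frame(chi = chi[i], energy = e0, kind = "flat", flat = TRUE)
      next
    }
    v <- .parabola_vertex(c(xm, chi[i], xp), c(em, e0, ep))
    out[[length(out) + 1L]] <-
      data.frame(chi = fold_angle(v$x), energy = v$y, kind = kind,
                 flat = v$flat)
  }
  res <- do.call(rbind, out)
  res[order(res$chi), , drop = FALSE]
}

#' Enantiomerization barrier from a torsional profile
#'
#' The global minimum at chi_g and its mirror image at -chi_g are the two
#' enantiomers. Two rotation paths connect them: through the planar syn
#' orientation (0 degrees) and through the anti orientation (+/-180).
#' The barrier is the lower of the two path maxima, measured from the
#' refined ground-state energy.
#'
#' @param p a principal-window [torsion_profile()] whose global minimum is
#'   away from 0 and 180 (an axially chiral rotor).
#' @param tol angular tolerance (deg) for declaring the minimum achiral.
#' @return A list of class `barrier_result`: `barrier` (kcal/mol), `path`
#'   (`"syn"`/`"anti"`), `chi_gs` and `chi_ts` (deg, refined).
#' @export
enantiomerization_barrier <- function(p, tol = 1e-3) {
  stopifnot(inherits(p, "torsion_profile"))
  sp <- locate_stationary_points(p)
  mins <- sp[sp$kind == "minimum", , drop = FALSE]
  if (nrow(mins) == 0L) stop("no minima located on the profile")
  gs <- mins[which.min(mins$energy), ]
  ag <- abs(gs$chi)
  if (ag <= tol || abs(ag - 180) <= tol)
    stop("no chiral axis: the global minimum lies at a planar/anti ",
         "orientation (chi = ", round(gs$chi, 3), " deg)")
  path_max <- function(on_arc) {
    idx <- which(on_arc(p$angles))
    if (length(idx) == 0L) return(NULL)
    i <- idx[which.max(p$energies[idx])]
    n <- length(p$angles)
    im <- if (i == 1L) n else i - 1L
    ip <- if (i == n) 1L else i + 1L
    xm <- p$angles[im]; x0 <- p$angles[i]; xp <- p$angles[ip]
    if (xm > x0) xm <- xm - 360
    if (xp < x0) xp <- xp + 360
    v <- .parabola_vertex(c(xm, x0, xp),
                          p$energies[c(im, i, ip)])
    if (v$curv < 0) list(chi = fold_angle(v$x), e = v$y)
    else list(chi = x0, e = p$energies[i])
  }
  syn <- path_max(function(x) abs(x) < ag - tol)
  anti <- path_max(function(x) abs(x) > ag + tol)
  if (is.null(syn) || is.null(anti))
    stop("cannot resolve both rotation paths on this grid")
  if (syn$e <= anti$e) {
    res <- list(barrier = syn$e - gs$energy, path = "syn",
                chi_gs = gs$chi, chi_ts = syn$chi)
  } else {
    res <- list(barrier = anti$e - gs$energy, path = "anti",
                chi_gs = gs$chi, chi_ts = anti$chi)
  }
  structure(res, class = "barrier_result")
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf(
    "<barrier_result> dG = %.2f kcal/mol via %s path (GS chi %.1f deg, TS chi %.1f deg)\n",
    x$barrier, x$path, x$chi_gs, x$chi_ts))
  invisible(x)
}

#' Stationary-point record from a frequency calculation
#'
#' @param chi dihedral in degrees.
#' @param e_el electronic energy, kcal/mol.
#' @param g_corr thermal free-energy correction, kcal/mol.
#' @param n_imag number of imaginary vibrational frequencies.
#' @param kind `"minimum"` (ground state) or `"maximum"` (transition state).
#' @return An object of class `stationary_point`.
#' @export
stationary_point <- function(chi, e_el, g_corr, n_imag,
                             kind = c("minimum", "maximum")) {
  kind <- match.arg(kind)
  if (n_imag < 0 || n_imag != round(n_imag))
    stop("n_imag must be a non-negative integer")
  structure(list(chi = chi, e_el = e_el, g_corr = g_corr,
                 n_imag = as.integer(n_imag), kind = kind),
            class = "stationary_point")
}

#' Free-energy barrier from validated stationary points
#'
#' Each candidate transition state must carry exactly one imaginary
#' frequency and the ground state none; the barrier is the lowest
#' `(E_el + G_corr)` difference over the transition-state candidates.
#'
#' @param gs ground-state [stationary_point()] (kind `"minimum"`, 0
#'   imaginary frequencies).
#' @param ts a [stationary_point()] or list of them (each kind
#'   `"maximum"`, 1 imaginary frequency).
#' @return Barrier in kcal/mol.
#' @export
free_energy_barrier <- function(gs, ts) {
  stopifnot(inherits(gs, "stationary_point"))
  if (inherits(ts, "stationary_point")) ts <- list(ts)
  if (gs$kind != "minimum" || gs$n_imag != 0L)
    stop("ground state invalid: expected a minimum with 0 imaginary ",
         "frequencies, got kind '", gs$kind, "' with ", gs$n_imag)
  g_gs <- gs$e_el + gs$g_corr
  dgs <- vapply(ts, function(t) {
    stopifnot(inherits(t, "stationary_point"))
    if (t$n_imag != 1L)
      stop("transition state at chi = ", t$chi, " invalid: expected exactly ",
           "1 imaginary frequency, got ", t$n_imag)
    (t$e_el + t$g_corr) - g_gs
  }, numeric(1))
  dg <- min(dgs)
  if (dg < 0)
    stop("ordering error: transition state lies below the ground state (",
         round(dg, 3), " kcal/mol)")
  dg
}

#' Classify atropisomer stability from the rotational barrier
#'
#' Axes with barriers below 22 kcal/mol interconvert freely at ambient
#' temperature (class 1); 22-30 kcal/mol axes are moderately stable
#' (class 2); barriers of 30 kcal/mol and above mark configurationally
#' stable, single-atropisomer-developable axes (class 3). Boundaries are
#' half-open: [0, 22) / [22, 30) / [30, Inf).
#'
#' @param dg rotational barrier, kcal/mol (non-negative, finite).
#' @param boundaries the two class boundaries, kcal/mol.
#' @return An object of class `atrop_class` with `label` (1/2/3) and
#'   `boundaries`.
#' @export
classify_axis <- function(dg, boundaries = c(22, 30)) {
  if (!is.finite(dg) || dg < 0)
    stop("barrier must be a finite non-negative energy in kcal/mol")
  stopifnot(length(boundaries) == 2L, diff(boundaries) > 0)
  label <- if (dg < boundaries[1L]) 1L else if (dg < boundaries[2L]) 2L else 3L
  structure(list(label = label, boundaries = boundaries),
            class = "atrop_class")
}

#' @export
print.atrop_class <- function(x, ...) {
  cat("<atrop_class> class", x$label,
      sprintf("(boundaries %g/%g kcal/mol)\n",
              x$boundaries[1], x$boundaries[2]))
  invisible(x)
}
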