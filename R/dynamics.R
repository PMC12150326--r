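#' Dihedral time series from a trajectory
#'
#' Pre-extracted `time, angle` observations of the chiral-axis dihedral
#' along a molecular-dynamics trajectory, tagged with the binding state.
#' Angles are folded into the principal window (-180, 180].
#'
#' @param times increasing time stamps (arbitrary units).
#' @param angles dihedral angles, degrees.
#' @param state `"bound"` or `"unbound"`.
#' @param compound compound label.
#' @return An object of class `dihedral_series`.
#' @export
dihedral_series <- function(times, angles, state = c("bound", "unbound"),
                            compound = "") {
  state <- match.arg(state)
  times <- as.numeric(times); angles <- as.numeric(angles)
  if (length(times) != length(angles))
    stop("times and angles must have the same length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be increasing")
  structure(list(times = times, angles = fold_angle(angles),
                 state = state, compound = as.character(compound)),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("<dihedral_series>", x$state,
      if (nzchar(x$compound)) paste0("(", x$compound, ")") else "",
      "-", length(x$angles), "frames\n")
  invisible(x)
}

#' Read a dihedral series table
#'
#' CSV with header `frame,chi_deg`; a `# state=bound|unbound` comment
#' sets the state unless overridden.
#'
#' @param path input path.
#' @param state overrides any `# state=` comment.
#' @param compound compound label.
#' @return A [dihedral_series()].
#' @export
read_dihedral_series <- function(path, state = NULL, compound = "") {
  lines <- readLines(path, warn = FALSE)
  if (is.null(state)) {
    m <- grep("^#\\s*state\\s*=", lines, value = TRUE)
    state <- if (length(m)) trimws(sub("^#\\s*state\\s*=", "", m[1L]))
             else "unbound"
  }
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  dihedral_series(d$frame, d$chi_deg, state = state, compound = compound)
}

#' Bin dihedral angles into fixed-width windows on the circle
#'
#' Left-closed bins `[k*width, (k+1)*width)` anchored at 0 degrees on the
#' full circle, reported at their midpoints folded into (-180, 180] — so
#' a 5-degree width yields midpoints such as 82.5. Counts are conserved,
#' including for data straddling the +/-180 seam.
#'
#' @param s a [dihedral_series()] or numeric vector of angles (degrees).
#' @param width bin width in degrees; must divide 360 evenly.
#' @return A data.frame of class `dihedral_histogram` with columns
#'   `midpoint` (deg) and `count`, plus attribute `width`.
#' @export
bin_dihedrals <- function(s, width = 5) {
  angles <- if (inherits(s, "dihedral_series")) s$angles else as.numeric(s)
  if (!isTRUE(all.equal(360 %% width, 0)))
    stop("bin width must divide 360 evenly")
  nb <- as.integer(round(360 / width))
  # work on [0, 360) so the anchored bins are contiguous
  x <- angles %% 360
  idx <- pmin(floor(x / width), nb - 1L)  # guard x == 360 - eps rounding
  counts <- tabulate(idx + 1L, nbins = nb)
  mid <- fold_angle((seq_len(nb) - 1L) * width + width / 2)
  o <- order(mid)
  out <- data.frame(midpoint = mid[o], count = counts[o])
  attr(out, "width") <- width
  class(out) <- c("dihedral_histogram", "data.frame")
  out
}

#' Circular summary of a dihedral series
#'
#' Circular mean = `atan2(mean(sin), mean(cos))` in degrees; circular
#' standard deviation = `sqrt(-2 ln Rbar)` (degrees); the range is the
#' smallest arc containing every observation (the naive min/max is
#' meaningless across the +/-180 seam).
#'
#' @param s a [dihedral_series()] or numeric vector of angles (degrees).
#' @return A list with `mean` (deg, NA with `undefined_mean = TRUE` when
#'   the resultant vanishes), `range` (arc endpoints, deg), `range_width`
#'   (deg), `sd` (deg), `n`.
#' @export
circular_summary <- function(s) {
  angles <- if (inherits(s, "dihedral_series")) s$angles else as.numeric(s)
  n <- length(angles)
  if (n == 0L) stop("empty series")
  rad <- angles * pi / 180
  ms <- mean(sin(rad)); mc <- mean(cos(rad))
  rbar <- sqrt(ms^2 + mc^2)
  undefined <- rbar < 1e-12
  mu <- if (undefined) NA_real_ else fold_angle(atan2(ms, mc) * 180 / pi)
  sd <- if (undefined) NA_real_ else sqrt(max(-2 * log(rbar), 0)) * 180 / pi
  # smallest covering arc: complement of the largest gap between
  # consecutive sorted angles on the circle
  a <- sort(angles %% 360)
  gaps <- diff(c(a, a[1L] + 360))
  if (n == 1L) {
    rng <- c(angles, angles); width <- 0
  } else {
    big <- which.max(gaps)
    width <- 360 - gaps[big]
    start <- a[if (big == n) 1L else big + 1L]
    rng <- fold_angle(c(start, start + width))
  }
  list(mean = mu, range = rng, range_width = width, sd = sd, n = n,
       undefined_mean = undefined)
}

#' Compare bound and unbound dihedral occupancy
#'
#' Per-state circular summaries, the circular shift between the modal
#' histogram bins, and the overlap coefficient
#' `sum(min(p_bound, p_unbound))` of the normalized histograms.
#'
#' @param bound,unbound [dihedral_series()]s.
#' @param width histogram bin width, degrees.
#' @return A list of class `occupancy_comparison`: `bound`, `unbound`
#'   (circular summaries), `mode_shift` (deg), `overlap` in [0, 1], and
#'   the two histograms.
#' @export
compare_states <- function(bound, unbound, width = 5) {
  hb <- bin_dihedrals(bound, width)
  hu <- bin_dihedrals(unbound, width)
  pb <- hb$count / sum(hb$count)
  pu <- hu$count / sum(hu$count)
  mode_b <- hb$midpoint[which.max(hb$count)]
  mode_u <- hu$midpoint[which.max(hu$count)]
  shift <- fold_angle(mode_b - mode_u)
  structure(list(bound = circular_summary(bound),
                 unbound = circular_summary(unbound),
                 mode_shift = shift,
                 overlap = sum(pmin(pb, pu)),
                 hist_bound = hb, hist_unbound = hu),
            class = "occupancy_comparison")
}

#' @export
print.occupancy_comparison <- function(x, ...) {
  cat(sprintf(
    "<occupancy_comparison> bound mean %.1f deg (arc %.1f deg), unbound mean %.1f deg (arc %.1f deg)\n",
    x$bound$mean, x$bound$range_width, x$unbound$mean, x$unbound$range_width))
  cat(sprintf("  mode shift %.1f deg, histogram overlap %.3f\n",
              x$mode_shift, x$overlap))
  invisible(x)
}
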