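#' Five-dose growth-inhibition record for one cell line
#'
#' The NCI-60 screening design: time-zero cell density Tz, untreated
#' control density C after the growth period, and treated densities Ti at
#' each of five ten-fold dilutions (100, 10, 1, 0.1, 0.01 uM by default).
#'
#' @param conc molar concentrations, strictly increasing.
#' @param tz time-zero density.
#' @param control untreated control density (> tz).
#' @param treated treated densities, one per concentration.
#' @param cell_line label.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(conc, tz, control, treated, cell_line = "") {
  conc <- as.numeric(conc); treated <- as.numeric(treated)
  if (any(diff(conc) <= 0)) stop("concentrations must be strictly increasing")
  if (length(conc) != length(treated))
    stop("one treated density per concentration required")
  if (tz < 0) stop("time-zero density cannot be negative")
  if (control <= tz)
    stop("degenerate control: C must exceed Tz (no growth measured)")
  structure(list(conc = conc, tz = tz, control = control, treated = treated,
                 cell_line = as.character(cell_line)),
            class = "dose_response")
}

#' Percent growth at each dose
#'
#' NCI-60 convention: `PG = 100 * (Ti - Tz) / (C - Tz)` when growth is
#' net-positive (`Ti >= Tz`), else `100 * (Ti - Tz) / Tz` (net kill,
#' bounded below by -100). PG = 100 is uninhibited growth, 0 is total
#' growth inhibition, -100 is complete kill.
#'
#' @param dr a [dose_response()].
#' @return Numeric PG values, one per dose.
#' @export
percent_growth <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  ifelse(dr$treated >= dr$tz,
         100 * (dr$treated - dr$tz) / (dr$control - dr$tz),
         100 * (dr$treated - dr$tz) / dr$tz)
}

#' GI50 / TGI / LC50 response levels from percent growth
#'
#' Each level is the concentration at which PG crosses +50 (GI50), 0
#' (TGI) or -50 (LC50), by linear interpolation in log10(concentration)
#' between the bracketing doses. With no crossing the level is censored
#' at the nearest tested bound and flagged. Non-monotone curves with
#' several crossings take the lowest-concentration one and flag the
#' multiplicity.
#'
#' @param pg percent-growth values (from [percent_growth()]).
#' @param conc molar concentrations matching `pg`.
#' @return A data.frame with one row per level (`gi50`, `tgi`, `lc50`):
#'   `conc_M`, `log10_conc`, `censored` (`""`, `">"` or `"<"`),
#'   `multiple_crossings`.
#' @export
response_levels <- function(pg, conc) {
  if (length(pg) != length(conc)) stop("pg and conc lengths differ")
  if (length(pg) < 2L) stop("at least 2 doses required")
  if (any(diff(conc) <= 0)) stop("concentrations must be strictly increasing")
  lx <- log10(conc)
  one <- function(target) {
    d <- pg - target
    if (all(d > 0))       # never reaches the level: censored above
      return(list(lc = lx[length(lx)], cens = ">", multi = FALSE))
    if (all(d < 0))       # already past the level at the lowest dose
      return(list(lc = lx[1L], cens = "<", multi = FALSE))
    cross <- which(d[-length(d)] * d[-1L] <= 0 &
                     !(d[-length(d)] == 0 & d[-1L] == 0))
    exact <- which(d == 0)
    cand <- sort(c(lx[exact], vapply(cross, function(i) {
      if (d[i] == 0) return(lx[i])
      lx[i] + (lx[i + 1L] - lx[i]) * d[i] / (d[i] - d[i + 1L])
    }, numeric(1))))
    cand <- unique(round(cand, 12))
    list(lc = cand[1L], cens = "", multi = length(cand) > 1L)
  }
  res <- lapply(c(gi50 = 50, tgi = 0, lc50 = -50), one)
  data.frame(level = names(res),
             conc_M = vapply(res, function(r) 10^r$lc, numeric(1)),
             log10_conc = vapply(res, `[[`, numeric(1), "lc"),
             censored = vapply(res, `[[`, character(1), "cens"),
             multiple_crossings = vapply(res, `[[`, logical(1), "multi"),
             row.names = NULL)
}

#' Per-cell-line screen fingerprint
#'
#' @param cell_line character labels.
#' @param log10_conc log10 molar endpoint (GI50 or TGI) per line;
#'   censored lines carry the tested bound, never a fabricated value.
#' @param censored `""`, `">"` or `"<"` per line.
#' @param endpoint `"GI50"` or `"TGI"`.
#' @return An object of class `screen_fingerprint` (a data.frame).
#' @export
screen_fingerprint <- function(cell_line, log10_conc, censored = "",
                               endpoint = "GI50") {
  cell_line <- as.character(cell_line)
  if (anyDuplicated(cell_line)) stop("cell lines must be unique")
  censored <- rep_len(as.character(censored), length(cell_line))
  if (!all(censored %in% c("", ">", "<")))
    stop("censoring flags must be '', '>' or '<'")
  out <- data.frame(cell_line = cell_line,
                    log10_conc = as.numeric(log10_conc),
                    censored = censored)
  attr(out, "endpoint") <- endpoint
  class(out) <- c("screen_fingerprint", "data.frame")
  out
}

#' Read a screen fingerprint table
#'
#' CSV with header `cell_line,log10_gi50,censored` (or `log10_tgi`).
#'
#' @param path input path.
#' @return A [screen_fingerprint()].
#' @export
read_fingerprint <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  val_col <- intersect(c("log10_gi50", "log10_tgi", "log10_conc"), names(d))
  if (length(val_col) == 0L)
    stop("fingerprint table needs a log10_gi50 / log10_tgi column")
  cens <- if ("censored" %in% names(d)) d$censored else ""
  cens[is.na(cens)] <- ""
  screen_fingerprint(d$cell_line, d[[val_col[1L]]], censored = cens,
                     endpoint = toupper(sub("log10_", "", val_col[1L])))
}

#' Mean-graph statistics of a screen fingerprint
#'
#' The mean endpoint is the geometric mean over cell lines, i.e.
#' `10^mean(log10 endpoint)`, with censored lines contributing their
#' bound (the screening convention). The selectivity range is
#' `max - min` of the log10 endpoints, in log units; per-line deltas
#' from the mean are what the mean-graph bars display.
#'
#' @param fp a [screen_fingerprint()].
#' @return A list of class `mean_graph_stats`: `mean_conc_M`,
#'   `mean_log10`, `selectivity_range` (log units), `deltas` (named, log
#'   units), `n`, `n_censored`, `all_censored`.
#' @export
mean_graph <- function(fp) {
  stopifnot(inherits(fp, "screen_fingerprint"))
  lg <- fp$log10_conc
  all_cens <- all(fp$censored != "")
  if (all_cens)
    warning("all lines censored: mean-graph statistics are bound-only")
  m <- mean(lg)
  structure(list(mean_conc_M = 10^m, mean_log10 = m,
                 selectivity_range = max(lg) - min(lg),
                 deltas = stats::setNames(lg - m, fp$cell_line),
                 n = nrow(fp), n_censored = sum(fp$censored != ""),
                 all_censored = all_cens),
            class = "mean_graph_stats")
}

#' @export
print.mean_graph_stats <- function(x, ...) {
  cat(sprintf(
    "<mean_graph_stats> mean %.3g M (%.2f uM), selectivity range %.2f log units, n = %d (%d censored)\n",
    x$mean_conc_M, x$mean_conc_M * 1e6, x$selectivity_range, x$n,
    x$n_censored))
  invisible(x)
}

#' COMPARE-style Pearson correlation of two fingerprints
#'
#' Pearson r over the mean-graph deltas of the cell lines common to both
#' fingerprints, after dropping censored lines. A coefficient above the
#' threshold (0.5 by convention) is considered significant.
#'
#' @param a,b [screen_fingerprint()]s.
#' @param threshold significance threshold on r.
#' @return A list of class `compare_result`: `r`, `n` (common uncensored
#'   lines), `significant`, `threshold`; `r` is NA with
#'   `undefined = TRUE` when either vector has zero variance.
#' @export
compare_correlation <- function(a, b, threshold = 0.5) {
  stopifnot(inherits(a, "screen_fingerprint"),
            inherits(b, "screen_fingerprint"))
  au <- a[a$censored == "", , drop = FALSE]
  bu <- b[b$censored == "", , drop = FALSE]
  common <- intersect(au$cell_line, bu$cell_line)
  if (length(common) < 3L)
    stop("insufficient overlap: fewer than 3 common uncensored cell lines")
  va <- au$log10_conc[match(common, au$cell_line)]
  vb <- bu$log10_conc[match(common, bu$cell_line)]
  # Pearson r is invariant to the per-fingerprint mean shift, so deltas
  # and raw log values give the same r; deltas are what COMPARE displays
  da <- va - mean(va); db <- vb - mean(vb)
  undefined <- stats::sd(da) == 0 || stats::sd(db) == 0
  r <- if (undefined) NA_real_ else stats::cor(da, db)
  structure(list(r = r, n = length(common),
                 significant = isTRUE(r > threshold),
                 threshold = threshold, undefined = undefined),
            class = "compare_result")
}

#' @export
print.compare_result <- function(x, ...) {
  cat(sprintf("<compare_result> r = %.3f over %d lines (%ssignificant at %.2f)\n",
              x$r, x$n, if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}
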