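#' Eyring rate constant from an activation free energy
#'
#' `k = kappa * (kB/h) * T * exp(-dG / (R * T))`, the one-way microscopic
#' enantiomerization rate (R -> S). Note that the observed enantiomeric
#' excess decays with rate `2k`, not `k` (see [ee_decay()]); the factor of
#' two is a classic pitfall when converting racemization half-lives to
#' barriers.
#'
#' @param dg activation free energy, kcal/mol.
#' @param temperature absolute temperature, K.
#' @return An object of class `rate_constant`: `k` (s^-1), `se` (s^-1,
#'   NA here), `temperature` (K).
#' @export
eyring_rate <- function(dg, temperature) {
  if (!is.finite(dg)) stop("dg must be finite")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (K)")
  cst <- eyring_constants
  k <- cst$kappa * cst$kB_h * temperature *
    exp(-dg / (cst$R * temperature))
  rate_constant(k, temperature)
}

#' Rate-constant container
#'
#' @param k one-way enantiomerization rate, s^-1 (> 0).
#' @param temperature K.
#' @param se standard error of `k`, s^-1.
#' @return An object of class `rate_constant`.
#' @export
rate_constant <- function(k, temperature, se = NA_real_) {
  if (!is.finite(k) || k <= 0) stop("rate constant must be positive")
  if (temperature <= 0) stop("temperature must be positive (K)")
  structure(list(k = k, se = se, temperature = temperature),
            class = "rate_constant")
}

#' @export
print.rate_constant <- function(x, ...) {
  cat(sprintf("<rate_constant> k = %.4g s^-1%s at %.2f K (ee half-life %s)\n",
              x$k,
              if (is.finite(x$se)) sprintf(" (se %.2g)", x$se) else "",
              x$temperature, .fmt_time(log(2) / (2 * x$k))))
  invisible(x)
}

.fmt_time <- function(s) {
  if (s < 1e-3) sprintf("%.3g s", s)
  else if (s < 120) sprintf("%.3g s", s)
  else if (s < 7200) sprintf("%.3g min", s / 60)
  else if (s < 172800) sprintf("%.3g h", s / 3600)
  else sprintf("%.3g d", s / 86400)
}

#' Activation free energy from a rate constant
#'
#' Exact inverse of [eyring_rate()]:
#' `dG = R * T * ln(kappa * (kB/h) * T / k)`.
#'
#' @param k a [rate_constant()], or a positive numeric rate (s^-1) with
#'   `temperature` supplied.
#' @param temperature K (only when `k` is numeric).
#' @return Activation free energy, kcal/mol.
#' @export
barrier_from_rate <- function(k, temperature = NULL) {
  if (inherits(k, "rate_constant")) {
    temperature <- k$temperature
    k <- k$k
  }
  if (is.null(temperature)) stop("temperature required for a bare rate")
  if (!is.finite(k) || k <= 0) stop("rate constant must be positive")
  cst <- eyring_constants
  cst$R * temperature * log(cst$kappa * cst$kB_h * temperature / k)
}

#' First-order decay of enantiomeric excess
#'
#' Racemic interconversion R <-> S with one-way rate k gives
#' `d(ee)/dt = -2 k ee`, hence `ee(t) = ee0 * exp(-2 k t)` and an ee
#' half-life of `ln(2) / (2 k)`.
#'
#' @param ee0 initial enantiomeric excess in [-1, 1].
#' @param k a [rate_constant()] or numeric one-way rate (s^-1).
#' @param t time(s), s, non-negative.
#' @return A list with `ee` (same length as `t`) and `half_life` (s).
#' @export
ee_decay <- function(ee0, k, t) {
  if (inherits(k, "rate_constant")) k <- k$k
  if (abs(ee0) > 1) stop("|ee0| must be <= 1")
  if (any(t < 0)) stop("times must be non-negative")
  list(ee = ee0 * exp(-2 * k * t), half_life = log(2) / (2 * k))
}

#' Racemization time course
#'
#' Observations of enantiomeric excess versus time at one temperature.
#' Peak areas from chiral chromatography may be given instead of ee, in
#' which case `ee = (A_major - A_minor) / (A_major + A_minor)`.
#'
#' @param times s, non-negative, increasing.
#' @param ee enantiomeric excess in [-1, 1] (omit if areas given).
#' @param area_major,area_minor chiral-HPLC peak areas (optional).
#' @param temperature K.
#' @return An object of class `racemization_timecourse`.
#' @export
racemization_timecourse <- function(times, ee = NULL, area_major = NULL,
                                    area_minor = NULL, temperature) {
  if (is.null(ee)) {
    if (is.null(area_major) || is.null(area_minor))
      stop("supply either ee or both peak areas")
    ee <- (area_major - area_minor) / (area_major + area_minor)
  }
  times <- as.numeric(times); ee <- as.numeric(ee)
  if (length(times) != length(ee)) stop("times and ee lengths differ")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and increasing")
  if (any(abs(ee) > 1 + 1e-9)) stop("|ee| cannot exceed 1")
  if (temperature <= 0) stop("temperature must be positive (K)")
  structure(list(times = times, ee = ee, temperature = temperature),
            class = "racemization_timecourse")
}

#' Read a racemization time course
#'
#' CSV with header `t_s,ee` or `t_s,area_major,area_minor`; the
#' temperature comes from a `# T_K=<value>` comment line or the
#' `temperature` argument.
#'
#' @param path input path.
#' @param temperature K; overrides any `# T_K=` comment.
#' @return A [racemization_timecourse()].
#' @export
read_timecourse <- function(path, temperature = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(temperature)) {
    m <- grep("^#\\s*T_K\\s*=", lines, value = TRUE)
    if (length(m))
      temperature <- as.numeric(sub("^#\\s*T_K\\s*=\\s*", "", m[1L]))
  }
  if (is.null(temperature) || !is.finite(temperature))
    stop("temperature not given and no '# T_K=' comment found")
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  if (all(c("area_major", "area_minor") %in% names(d)))
    racemization_timecourse(d$t_s, area_major = d$area_major,
                            area_minor = d$area_minor,
                            temperature = temperature)
  else
    racemization_timecourse(d$t_s, ee = d$ee, temperature = temperature)
}

#' Fit the enantiomerization rate from one time course
#'
#' Linear regression of `ln|ee|` on time; the slope is `-2k`. Points with
#' `|ee|` at or below `floor` (noise that crossed zero) are dropped with a
#' warning. The default fit is unweighted;
#' `weights = "inverse-variance"` applies weights proportional to `ee^2`,
#' the inverse variance of `ln|ee|` when the measurement noise is
#' additive on ee with constant sd — appropriate for detector-limited
#' chromatographic data where late, small-ee points are noisiest on the
#' log scale.
#'
#' @param tc a [racemization_timecourse()].
#' @param weights NULL (unweighted), a numeric vector, or
#'   `"inverse-variance"`.
#' @param floor drop threshold on |ee|.
#' @return A [rate_constant()] with regression standard error.
#' @export
fit_rate_from_timecourse <- function(tc, weights = NULL, floor = 1e-6) {
  stopifnot(inherits(tc, "racemization_timecourse"))
  keep <- abs(tc$ee) > floor
  if (!all(keep))
    warning(sum(!keep), " point(s) at or below the |ee| floor of ", floor,
            " dropped")
  t <- tc$times[keep]; ee <- tc$ee[keep]
  if (length(t) < 3L)
    stop("insufficient data: fewer than 3 usable time points")
  if (length(unique(sign(ee))) != 1L)
    stop("ee must keep one sign for log-linear fitting")
  if (identical(weights, "inverse-variance")) {
    # model-based weights: var(ln|ee|) ~ (sd/ee)^2, with ee taken from a
    # preliminary unweighted fit so weight noise does not leak into the fit
    pre <- stats::lm(log(abs(ee)) ~ t)
    weights <- exp(2 * stats::fitted(pre))
  } else if (!is.null(weights)) {
    weights <- weights[keep]
  }
  fit <- stats::lm(log(abs(ee)) ~ t, weights = weights)
  slope <- stats::coef(fit)[["t"]]
  # suppressWarnings: summary.lm warns on exactly log-linear (noise-free)
  # data, where the zero residual variance is the correct answer
  se <- sqrt(suppressWarnings(stats::vcov(fit)["t", "t"]))
  if (slope >= 0)
    stop("non-decaying ee: fitted slope is non-negative")
  rate_constant(-slope / 2, tc$temperature, se = se / 2)
}

#' Eyring regression over one or more rate constants
#'
#' Multi-temperature mode (>= 2 distinct temperatures): ordinary least
#' squares of `ln(k/T)` on `1/T`; the slope is `-dH/R` and the intercept
#' `ln(kB/h) + dS/R`. `dG(Tref) = dH - Tref * dS`. When every rate
#' carries a finite standard error (as rates fitted by
#' [fit_rate_from_timecourse()] do), the parameter covariance is
#' propagated from those per-rate uncertainties through the regression
#' (a fixed-variance sandwich), which keeps the dG interval calibrated
#' even with as few as three temperatures, where a residual-based
#' variance estimate would rest on a single degree of freedom.
#' Otherwise the usual residual-based `lm` covariance is used.
#' Single-temperature mode: `dG = barrier_from_rate(k)` and dH/dS are
#' undefined (NA).
#'
#' @param rates a [rate_constant()] or list of them.
#' @param t_ref reference temperature for dG, K.
#' @param weights optional regression weights.
#' @return An object of class `eyring_fit` with `dH`, `dS`, `dG`, `dG_se`,
#'   `t_ref`, `cov` and `mode`.
#' @export
eyring_regression <- function(rates, t_ref = 298.15, weights = NULL) {
  if (inherits(rates, "rate_constant")) rates <- list(rates)
  stopifnot(length(rates) >= 1L,
            all(vapply(rates, inherits, logical(1), "rate_constant")))
  k <- vapply(rates, `[[`, numeric(1), "k")
  temp <- vapply(rates, `[[`, numeric(1), "temperature")
  cst <- eyring_constants
  if (length(unique(temp)) == 1L) {
    if (length(k) > 1L && length(unique(temp)) == 1L && length(temp) > 1L)
      stop("rank error: multiple rates at a single temperature cannot ",
           "separate dH and dS; supply distinct temperatures")
    dg <- barrier_from_rate(k[1L], temp[1L])
    kse <- rates[[1L]]$se
    dg_se <- if (is.finite(kse)) cst$R * temp[1L] * kse / k[1L] else NA_real_
    return(structure(list(dH = NA_real_, dS = NA_real_,
                          dG = dg, dG_se = dg_se, t_ref = temp[1L],
                          cov = NULL, mode = "single-temperature"),
                     class = "eyring_fit"))
  }
  y <- log(k / temp); x <- 1 / temp
  fit <- stats::lm(y ~ x, weights = weights)
  b <- stats::coef(fit)
  dH <- -b[["x"]] * cst$R
  dS <- (b[["(Intercept)"]] - log(cst$kappa * cst$kB_h)) * cst$R
  dG <- dH - t_ref * dS
  # dG is linear in (intercept, slope): dG = -R*Tref*b0 - R*b1 + const
  se_k <- vapply(rates, `[[`, numeric(1), "se")
  if (all(is.finite(se_k)) && is.null(weights)) {
    # var(ln(k/T)) = (se_k / k)^2; fixed-variance sandwich covariance
    X <- cbind(1, x)
    XtXi <- solve(crossprod(X))
    V <- XtXi %*% t(X) %*% diag((se_k / k)^2, length(k)) %*% X %*% XtXi
    dimnames(V) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))
  } else {
    V <- suppressWarnings(stats::vcov(fit))
  }
  grad <- c(-cst$R * t_ref, -cst$R)
  dG_se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(dH = dH, dS = dS, dG = dG, dG_se = dG_se, t_ref = t_ref,
                 cov = V, mode = "multi-temperature"),
            class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat("<eyring_fit>", x$mode, "\n")
  if (x$mode == "multi-temperature")
    cat(sprintf("  dH = %.3f kcal/mol, dS = %.5f kcal/mol/K\n", x$dH, x$dS))
  cat(sprintf("  dG(%.2f K) = %.3f %s kcal/mol\n", x$t_ref, x$dG,
              if (is.finite(x$dG_se)) sprintf("+/- %.3f", x$dG_se) else ""))
  invisible(x)
}

#' Barrier lower bound from a non-racemization observation
#'
#' If heating for `duration` at `temperature` produced no detectable loss
#' of ee, the one-way rate cannot exceed
#' `k_max = -ln(1 - detection) / (2 * duration)` and the barrier must be
#' at least `R * T * ln((kB/h) * T / k_max)`. The value is a lower bound
#' ("at least"), even where informal usage reports it as "the" barrier.
#'
#' @param temperature K.
#' @param duration s, > 0.
#' @param detection smallest detectable fractional ee loss, in (0, 1);
#'   default 0.02 (2 percent).
#' @return Minimum barrier consistent with the observation, kcal/mol.
#' @export
min_barrier_from_no_racemization <- function(temperature, duration,
                                             detection = 0.02) {
  if (temperature <= 0) stop("temperature must be positive (K)")
  if (duration <= 0) stop("duration must be positive (s)")
  if (detection <= 0 || detection >= 1)
    stop("detection threshold must lie strictly in (0, 1)")
  k_max <- -log(1 - detection) / (2 * duration)
  barrier_from_rate(k_max, temperature)
}

#' Celsius to Kelvin
#' @param x temperature in degrees Celsius.
#' @return temperature in K.
#' @export
celsius_to_kelvin <- function(x) x + 273.15
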