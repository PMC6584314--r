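#' Standard-deviation-weighted linear fit
#'
#' Weighted least squares of `y` on `t` with weights \eqn{1/sd^2}
#' (inverse-variance). The slope standard error is the residual-scaled
#' weighted-normal-equations value (identical to `lm(..., weights =)`),
#' so only the *relative* sizes of the SDs matter; the 95% CI uses the
#' normal 1.96 multiplier.
#'
#' @param t predictor (time, s).
#' @param y response (normalized intensity).
#' @param sd per-point standard deviations; zeros are replaced by the
#'   smallest positive value present.
#' @return An object of class `wls_fit`: `slope`, `intercept`, `slope_se`,
#'   `ci95` (slope interval), `r_squared`, `n`, plus the filtered inputs.
#' @examples
#' f <- weighted_linear_fit(0:2, c(0, 1, 4), c(1, 1, 2))
#' f$slope   # 5/3
#' @export
weighted_linear_fit <- function(t, y, sd = rep(1, length(t))) {
  keep <- is.finite(t) & is.finite(y) & is.finite(sd)
  t <- t[keep]; y <- y[keep]; sd <- sd[keep]
  if (length(t) < 3) stop("need at least 3 points for a weighted linear fit")
  if (diff(range(t)) == 0) stop("all t identical")
  if (any(sd < 0)) stop("sd must be non-negative")
  if (any(sd == 0)) {
    pos <- sd[sd > 0]
    if (length(pos) == 0) sd <- rep(1, length(sd))
    else sd[sd == 0] <- min(pos)
  }
  w <- 1 / sd^2
  fit <- stats::lm(y ~ t, weights = w)
  co <- stats::coef(fit)
  # residual-scaled SE and weighted R^2 computed directly from the normal
  # equations (summary.lm / vcov.lm warn on numerically exact fits)
  res <- y - co[1] - co[2] * t
  sw <- sum(w); swx <- sum(w * t)
  den <- sw * sum(w * t^2) - swx^2
  sigma2 <- sum(w * res^2) / (length(t) - 2)
  se <- sqrt(sigma2 * sw / den)
  tss <- sum(w * (y - sum(w * y) / sw)^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - sum(w * res^2) / tss)) else 1
  out <- list(slope = unname(co[2]), intercept = unname(co[1]),
              slope_se = unname(se),
              ci95 = unname(co[2] + c(-1, 1) * 1.96 * se),
              r_squared = r2, n = length(t), t = t, y = y, sd = sd,
              lm = fit)
  class(out) <- "wls_fit"
  out
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("Weighted linear fit (n = %d): slope %.4g +/- %.2g (1/s), intercept %.4g, R^2 %.3f\n",
              x$n, x$slope, x$slope_se, x$intercept, x$r_squared))
  invisible(x)
}

# weighted polynomial fit returning raw coefficients c0, c1, ...
wpoly <- function(t, y, sd, degree) {
  if (any(sd == 0)) {
    pos <- sd[sd > 0]
    sd[sd == 0] <- if (length(pos)) min(pos) else 1
  }
  fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE), weights = 1 / sd^2)
  unname(stats::coef(fit))
}

#' Stationary point (plateau time) from a weighted quadratic fit
#'
#' Fits \eqn{a t^2 + b t + c} by inverse-variance WLS and returns the
#' vertex \eqn{-b / 2a} when it falls inside the observed time window;
#' otherwise (or when the quadratic coefficient is degenerate) `NA`.
#'
#' @param t,y,sd time, normalized intensity and weights as in
#'   [weighted_linear_fit()].
#' @return Vertex time in the units of `t`, or `NA`.
#' @export
find_stationary <- function(t, y, sd = rep(1, length(t))) {
  if (length(t) < 4) stop("need at least 4 points for a quadratic fit")
  co <- wpoly(t, y, sd, 2)
  a <- co[3]; b <- co[2]
  scale <- max(stats::sd(y), .Machine$double.eps) / max(diff(range(t)), 1)^2
  if (!is.finite(a) || abs(a) < 1e-12 * scale) return(NA_real_)
  v <- -b / (2 * a)
  if (v >= min(t) && v <= max(t)) v else NA_real_
}

#' Inflection point from a weighted cubic fit
#'
#' Fits \eqn{a t^3 + b t^2 + c t + d} by inverse-variance WLS and returns
#' the root of its second derivative, \eqn{-b / 3a}, when it falls inside
#' the observed window; otherwise `NA`. An inflection is a sign change of
#' curvature, so profiles that only ever decelerate yield no (interior)
#' inflection and `NA` is the correct answer.
#'
#' @inheritParams find_stationary
#' @return Inflection time in the units of `t`, or `NA`.
#' @export
find_inflection <- function(t, y, sd = rep(1, length(t))) {
  if (length(t) < 5) stop("need at least 5 points for a cubic fit")
  co <- wpoly(t, y, sd, 3)
  a <- co[4]; b <- co[3]
  scale <- max(stats::sd(y), .Machine$double.eps) / max(diff(range(t)), 1)^3
  if (!is.finite(a) || abs(a) < 1e-12 * scale) return(NA_real_)
  v <- -b / (3 * a)
  if (v >= min(t) && v <= max(t)) v else NA_real_
}

#' Select the slope-fitting frame window
#'
#' The permeability slope is fitted on post-equilibrium frames acquired
#' before the profile departs from its initial linear rise: the window is
#' `[equilibrium_frame, frame(t_inflection))` when an inflection exists,
#' else `[equilibrium_frame, frame(t_plateau))`, else all post-equilibrium
#' frames. Degenerate windows are widened to a minimum of 3 frames with a
#' warning.
#'
#' @param times frame times, s.
#' @param equilibrium_frame 1-based index of the first usable frame.
#' @param t_inflection,t_plateau times from [find_inflection()] /
#'   [find_stationary()] (`NA` when absent).
#' @return An integer vector of frame indices.
#' @export
select_fit_window <- function(times, equilibrium_frame,
                              t_inflection = NA, t_plateau = NA) {
  n <- length(times)
  if (equilibrium_frame > n) stop("equilibrium_frame beyond the acquisition")
  t_end <- if (!is.na(t_inflection)) t_inflection
           else if (!is.na(t_plateau)) t_plateau
           else Inf
  idx <- which(seq_len(n) >= equilibrium_frame & times < t_end)
  if (length(idx) < 3) {
    idx <- equilibrium_frame:min(n, equilibrium_frame + 2)
    if (length(idx) < 3) idx <- (n - 2):n
    warning("fit window smaller than 3 frames; widened to the minimum")
  }
  idx
}

#' Convert a fitted intensity slope into a permeability
#'
#' \eqn{P = (V/S) \, dI/dt}: the early-time slope of the receiver's
#' normalized intensity times the receiver volume-to-surface ratio. The
#' 95% CI endpoints are scaled identically. A negative slope produces a
#' non-positive permeability with a warning (a barrier indistinguishable
#' from zero flux).
#'
#' @param fit a [weighted_linear_fit()] result (slope in 1/s).
#' @param vs_ratio receiver V/S, cm.
#' @return A list: `p_total` (cm/s), `ci95` (cm/s), `slope_fit`.
#' @export
permeability_from_slope <- function(fit, vs_ratio) {
  stopifnot(inherits(fit, "wls_fit"))
  if (vs_ratio <= 0) stop("vs_ratio must be positive")
  p <- vs_ratio * fit$slope
  if (p < 0)
    warning("negative fitted slope: permeability indistinguishable from zero flux")
  list(p_total = p, ci95 = vs_ratio * fit$ci95, slope_fit = fit)
}

#' Permeabilities over separate temporal regions
#'
#' Fits independent weighted slopes on the sub-windows delimited by
#' `breakpoints` (applied to the post-equilibrium frames) and converts
#' each via \eqn{P = (V/S) dI/dt}. Apparent permeabilities across regions
#' of a single run can differ severalfold when transport is not
#' steady; this quantifies that temporal heterogeneity.
#'
#' @param profile an [normalize_profile()] `intensity_profile`.
#' @param breakpoints strictly increasing interior region boundaries, s.
#' @param vs_ratio receiver V/S, cm.
#' @return A data.frame: `t_start`, `t_end`, `n`, `p` (cm/s), `ci_lo`,
#'   `ci_hi`, `r_squared`; regions with fewer than 3 frames are skipped
#'   with a warning.
#' @export
piecewise_permeability <- function(profile, breakpoints, vs_ratio) {
  stopifnot(inherits(profile, "intensity_profile"))
  eq <- attr(profile, "equilibrium_frame")
  idx <- which(!profile$excluded)
  t <- profile$time_s[idx]; y <- profile$norm_I[idx]; s <- profile$norm_sd[idx]
  if (length(breakpoints) == 0) {
    edges <- c(min(t), max(t) + 1)
  } else {
    if (is.unsorted(breakpoints, strictly = TRUE))
      stop("breakpoints must be strictly increasing")
    if (min(breakpoints) <= min(t) || max(breakpoints) > max(t))
      stop("breakpoints must lie inside the post-equilibrium time range")
    edges <- c(min(t), breakpoints, max(t) + 1)
  }
  out <- NULL
  for (i in seq_len(length(edges) - 1)) {
    inw <- t >= edges[i] & t < edges[i + 1]
    if (sum(inw) < 3) {
      warning(sprintf("region [%g, %g) has fewer than 3 frames; skipped",
                      edges[i], edges[i + 1]))
      next
    }
    f <- weighted_linear_fit(t[inw], y[inw], s[inw])
    out <- rbind(out, data.frame(
      t_start = edges[i], t_end = min(edges[i + 1], max(t)),
      n = sum(inw), p = vs_ratio * f$slope,
      ci_lo = vs_ratio * f$ci95[1], ci_hi = vs_ratio * f$ci95[2],
      r_squared = f$r_squared))
  }
  out
}

#' Local permeability per azimuthal sector
#'
#' Fits each sector's normalized intensity series over the *global* fit
#' window (same equilibrium frame and normalization constants as the
#' whole-chamber analysis) and converts each slope with the same V/S
#' ratio — a documented approximation, since a wedge's own volume-to-arc
#' ratio equals the disk's.
#'
#' @param profile an `intensity_profile` with `sector_*` columns (see
#'   `sectors = TRUE` in [extract_timeseries()]).
#' @param window frame indices of the global fit window.
#' @param vs_ratio receiver V/S, cm.
#' @return A data.frame: `sector`, `p`, `ci_lo`, `ci_hi`, `r_squared`.
#' @export
sector_permeability <- function(profile, window, vs_ratio) {
  stopifnot(inherits(profile, "intensity_profile"))
  sec_cols <- grep("^sector_", names(profile), value = TRUE)
  if (length(sec_cols) == 0)
    stop("profile has no sector columns; extract with sectors = TRUE")
  t <- profile$time_s[window]
  s <- profile$norm_sd[window]
  out <- NULL
  for (i in seq_along(sec_cols)) {
    y <- profile[[sec_cols[i]]][window]
    if (all(!is.finite(y))) {
      warning(sprintf("sector %d has no data; skipped", i))
      next
    }
    f <- weighted_linear_fit(t, y, s)
    out <- rbind(out, data.frame(sector = i, p = vs_ratio * f$slope,
                                 ci_lo = vs_ratio * f$ci95[1],
                                 ci_hi = vs_ratio * f$ci95[2],
                                 r_squared = f$r_squared))
  }
  out
}

#' Fit barrier permeability from a normalized intensity profile
#'
#' The central estimator of the package. Given the receiver's normalized
#' intensity profile \eqn{I(t)}, it (1) locates the plateau and inflection
#' of the post-equilibrium profile by weighted quadratic and cubic fits,
#' (2) selects the slope-fitting window ([select_fit_window()]),
#' (3) estimates \eqn{dI/dt} by inverse-variance weighted linear fit and
#' converts it to an overall permeability \eqn{P_{total} = (V/S) dI/dt}
#' with a 95% CI, and (4) when an acellular scaffold permeability is
#' supplied, removes the scaffold's series resistance to report the
#' endothelial permeability \eqn{P_e} ([subtract_scaffold()]).
#'
#' Two slope estimators are available. `method = "slope"` is the
#' assay-standard early-time estimator, exact only while the receiver is
#' far from equilibrium (\eqn{k t \ll 1}); it underestimates fast
#' transport once the window extends toward saturation.
#' `method = "log-slope"` fits the same weighted straight line to
#' \eqn{-\log(1 - I)}, whose slope equals \eqn{k = P/(V/S)} exactly under
#' the two-compartment model at any degree of saturation (weights are
#' propagated as \eqn{sd/(1-I)}; frames with \eqn{I \ge 1} are dropped).
#'
#' @param profile an `intensity_profile` from [normalize_profile()].
#' @param vs_ratio receiver volume-to-surface ratio, cm.
#' @param p_scaffold acellular scaffold permeability, cm/s, or `NULL` for
#'   no correction (e.g. an acellular run itself).
#' @param method `"slope"` (raw \eqn{dI/dt}) or `"log-slope"` (saturation
#'   -corrected; see Details).
#' @param breakpoints optional interior boundaries (s) for
#'   [piecewise_permeability()].
#' @param sectors compute per-sector permeabilities (requires sector
#'   columns in the profile)?
#' @return An object of class `perm_fit`; see [print.perm_fit()],
#'   [summary.perm_fit()], [plot.perm_fit()], [coef.perm_fit()],
#'   [predict.perm_fit()], [residuals.perm_fit()], [confint.perm_fit()].
#' @examples
#' prof <- two_slope_profile(seed = 7)
#' fit <- fit_permeability(as_intensity_profile(prof$time, prof$I, prof$sd),
#'                         vs_ratio = 0.045)
#' fit$t_inflection / 60   # near the 60 min generator breakpoint
#' @export
fit_permeability <- function(profile, vs_ratio, p_scaffold = NULL,
                             method = c("slope", "log-slope"),
                             breakpoints = NULL, sectors = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "intensity_profile"))
  if (vs_ratio <= 0) stop("vs_ratio must be positive")
  eq <- attr(profile, "equilibrium_frame")
  post <- which(!profile$excluded)
  t_all <- profile$time_s[post]
  y_all <- profile$norm_I[post]
  s_all <- profile$norm_sd[post]
  t_plateau <- if (length(post) >= 4)
    find_stationary(t_all, y_all, s_all) else NA_real_
  t_inflection <- if (length(post) >= 5)
    find_inflection(t_all, y_all, s_all) else NA_real_
  window <- select_fit_window(profile$time_s, eq, t_inflection, t_plateau)
  tw <- profile$time_s[window]
  yw <- profile$norm_I[window]
  sw <- profile$norm_sd[window]
  if (method == "log-slope") {
    ok <- yw < 1 - 1e-9
    if (sum(ok) < 3)
      stop("log-slope estimator needs at least 3 frames with I < 1")
    fit <- weighted_linear_fit(tw[ok], -log(1 - yw[ok]), sw[ok] / (1 - yw[ok]))
  } else {
    fit <- weighted_linear_fit(tw, yw, sw)
  }
  pt <- permeability_from_slope(fit, vs_ratio)
  pe <- NULL; ci_pe <- NULL
  if (!is.null(p_scaffold)) {
    if (pt$p_total > 0 && pt$p_total < p_scaffold) {
      pe <- subtract_scaffold(pt$p_total, p_scaffold)
      ci_pe <- vapply(pt$ci95, function(x)
        if (x > 0 && x < p_scaffold) subtract_scaffold(x, p_scaffold)
        else NA_real_, numeric(1))
    } else {
      warning("overall permeability not below the scaffold's; P_e unresolved")
      pe <- NA_real_
    }
  }
  regions <- if (!is.null(breakpoints))
    piecewise_permeability(profile, breakpoints, vs_ratio) else NULL
  secs <- if (sectors) sector_permeability(profile, window, vs_ratio) else NULL
  out <- list(profile = profile, vs_ratio = vs_ratio, method = method,
              equilibrium_frame = eq, window = window,
              t_inflection = t_inflection, t_plateau = t_plateau,
              fit = fit, p_total = pt$p_total, ci95_p = pt$ci95,
              p_scaffold = p_scaffold, p_endothelium = pe, ci95_pe = ci_pe,
              regions = regions, sectors = secs)
  class(out) <- "perm_fit"
  out
}
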