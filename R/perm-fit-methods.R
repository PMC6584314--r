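#' @rdname fit_permeability
#' @param time,norm_I,norm_sd time (s), normalized intensity and its SD of
#'   an already-normalized profile.
#' @param equilibrium_frame 1-based first usable frame of the bare profile.
#' @export
as_intensity_profile <- function(time, norm_I, norm_sd = rep(1e-2, length(time)),
                                 equilibrium_frame = 1L) {
  df <- data.frame(time_s = time, norm_I = norm_I, norm_sd = norm_sd,
                   excluded = seq_along(time) < equilibrium_frame)
  attr(df, "equilibrium_frame") <- as.integer(equilibrium_frame)
  class(df) <- c("intensity_profile", "data.frame")
  df
}

#' Print a permeability fit
#'
#' @param x a `perm_fit`.
#' @param ... unused.
#' @export
print.perm_fit <- function(x, ...) {
  cat("Barrier permeability fit\n")
  cat(sprintf("  estimator     : %s\n", x$method))
  cat(sprintf("  fit window    : frames %d-%d (t = %.1f-%.1f min, %d frames)\n",
              min(x$window), max(x$window),
              x$profile$time_s[min(x$window)] / 60,
              x$profile$time_s[max(x$window)] / 60, length(x$window)))
  if (!is.na(x$t_inflection))
    cat(sprintf("  inflection    : t = %.1f min\n", x$t_inflection / 60))
  if (!is.na(x$t_plateau))
    cat(sprintf("  plateau       : t = %.1f min\n", x$t_plateau / 60))
  cat(sprintf("  P_total       : %.4g cm/s  [95%% CI %.4g, %.4g]\n",
              x$p_total, x$ci95_p[1], x$ci95_p[2]))
  if (!is.null(x$p_endothelium)) {
    if (is.na(x$p_endothelium))
      cat("  P_e           : unresolved (P_total not below P_scaffold)\n")
    else
      cat(sprintf("  P_e           : %.4g cm/s  (P_scaffold %.4g)\n",
                  x$p_endothelium, x$p_scaffold))
  }
  invisible(x)
}

#' Summarize a permeability fit
#'
#' @param object a `perm_fit`.
#' @param ... unused.
#' @return An object of class `summary.perm_fit`.
#' @export
summary.perm_fit <- function(object, ...) {
  out <- object[c("method", "vs_ratio", "equilibrium_frame", "window",
                  "t_inflection", "t_plateau", "p_total", "ci95_p",
                  "p_scaffold", "p_endothelium", "ci95_pe",
                  "regions", "sectors")]
  out$slope <- object$fit$slope
  out$slope_se <- object$fit$slope_se
  out$r_squared <- object$fit$r_squared
  out$n_frames <- length(object$window)
  class(out) <- "summary.perm_fit"
  out
}

#' @export
print.summary.perm_fit <- function(x, ...) {
  cat("Permeability fit summary\n")
  cat(sprintf("  slope dI/dt : %.4g +/- %.2g 1/s (R^2 %.3f, %d frames)\n",
              x$slope, x$slope_se, x$r_squared, x$n_frames))
  cat(sprintf("  V/S         : %.4g cm\n", x$vs_ratio))
  cat(sprintf("  P_total     : %.4g cm/s [%.4g, %.4g]\n",
              x$p_total, x$ci95_p[1], x$ci95_p[2]))
  if (!is.null(x$p_endothelium) && !is.na(x$p_endothelium))
    cat(sprintf("  P_e         : %.4g cm/s\n", x$p_endothelium))
  if (!is.null(x$regions)) {
    cat("  temporal regions:\n")
    print(x$regions, row.names = FALSE)
  }
  if (!is.null(x$sectors)) {
    cat("  azimuthal sectors:\n")
    print(x$sectors, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.perm_fit <- function(object, ...) {
  c(intercept = object$fit$intercept, slope = object$fit$slope)
}

#' Confidence interval of the fitted permeability
#'
#' @param object a `perm_fit`.
#' @param parm `"p_total"` or `"p_endothelium"`.
#' @param level only 0.95 is provided (normal-approximation interval).
#' @param ... unused.
#' @export
confint.perm_fit <- function(object, parm = c("p_total", "p_endothelium"),
                             level = 0.95, ...) {
  parm <- match.arg(parm)
  if (level != 0.95) warning("only the 95% interval is computed")
  if (parm == "p_total") object$ci95_p else object$ci95_pe
}

#' Predicted normalized intensity of the fitted line
#'
#' Evaluates the fitted straight line (on the estimator's working scale,
#' mapped back to intensity for `method = "log-slope"`).
#'
#' @param object a `perm_fit`.
#' @param newdata optional data.frame with a `time_s` column; defaults to
#'   the fit-window frames.
#' @param ... unused.
#' @export
predict.perm_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$profile$time_s[object$window]
       else newdata$time_s
  eta <- object$fit$intercept + object$fit$slope * t
  if (object$method == "log-slope") 1 - exp(-eta) else eta
}

#' @export
residuals.perm_fit <- function(object, ...) {
  object$profile$norm_I[object$window] -
    predict.perm_fit(object,
                     newdata = data.frame(
                       time_s = object$profile$time_s[object$window]))
}

#' Plot a permeability fit
#'
#' Normalized intensity versus time with the excluded pre-equilibrium
#' frames greyed out, the fit window shaded, the fitted line drawn
#' through it, and the detected inflection/plateau marked.
#'
#' @param x a `perm_fit`.
#' @param ... passed to [plot.default()].
#' @export
plot.perm_fit <- function(x, ...) {
  p <- x$profile
  tmin <- p$time_s / 60
  graphics::plot(tmin, p$norm_I, type = "n",
                 xlab = "time (min)", ylab = "normalized intensity I(t)", ...)
  wr <- range(p$time_s[x$window]) / 60
  graphics::rect(wr[1], graphics::par("usr")[3], wr[2],
                 graphics::par("usr")[4],
                 col = grDevices::adjustcolor("steelblue", 0.12), border = NA)
  graphics::points(tmin[p$excluded], p$norm_I[p$excluded],
                   col = "grey70", pch = 1)
  graphics::points(tmin[!p$excluded], p$norm_I[!p$excluded], pch = 16,
                   cex = 0.6)
  tw <- p$time_s[x$window]
  graphics::lines(tw / 60,
                  predict.perm_fit(x, newdata = data.frame(time_s = tw)),
                  col = "firebrick", lwd = 2)
  if (!is.na(x$t_inflection))
    graphics::abline(v = x$t_inflection / 60, lty = 2, col = "darkorange")
  if (!is.na(x$t_plateau))
    graphics::abline(v = x$t_plateau / 60, lty = 3, col = "darkgreen")
  graphics::mtext(sprintf("P_total = %.3g cm/s", x$p_total), side = 3,
                  line = 0.2, cex = 0.9)
  invisible(x)
}

#' Export a permeability report
#'
#' Writes the fit as JSON (units cm/s; times s) and, optionally, a flat
#' one-row CSV for batch collation.
#'
#' @param fit a `perm_fit`.
#' @param path output JSON path.
#' @param csv optional CSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(fit, path, csv = NULL) {
  stopifnot(inherits(fit, "perm_fit"))
  rep <- list(method = fit$method, vs_ratio_cm = fit$vs_ratio,
              p_total = fit$p_total, ci95_p = fit$ci95_p,
              p_scaffold_used = fit$p_scaffold,
              p_endothelium = fit$p_endothelium, ci95_pe = fit$ci95_pe,
              t_inflection_s = fit$t_inflection,
              t_plateau_s = fit$t_plateau,
              window_frames = range(fit$window),
              slope_per_s = fit$fit$slope, slope_se = fit$fit$slope_se,
              r_squared = fit$fit$r_squared,
              regions = fit$regions, sectors = fit$sectors)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows")
  if (!is.null(csv)) {
    row <- data.frame(p_total = fit$p_total,
                      ci_lo = fit$ci95_p[1], ci_hi = fit$ci95_p[2],
                      p_endothelium = ifelse(is.null(fit$p_endothelium), NA,
                                             fit$p_endothelium),
                      t_inflection_s = fit$t_inflection,
                      t_plateau_s = fit$t_plateau,
                      r_squared = fit$fit$r_squared)
    utils::write.csv(row, csv, row.names = FALSE)
  }
  invisible(path)
}
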