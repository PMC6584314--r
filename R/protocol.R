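#' Wall shear stress in a rectangular perfusion channel
#'
#' Plane-Poiseuille (infinite parallel-plate) closure evaluated on the
#' wide wall: \eqn{\tau = 6 \mu Q / (w h^2)}, linear in both the flow rate
#' and the viscosity. No finite-aspect-ratio correction is applied; the
#' default viscosity is that of aqueous culture medium at room-ish
#' conditions and is an explicit input, not a measured property.
#'
#' @param flow_ul_min volumetric flow rate, uL/min.
#' @param width_um,height_um channel cross-section, um (width >= height:
#'   shear is evaluated on the wide wall).
#' @param viscosity_mPa_s dynamic viscosity, mPa s (= cP).
#' @return Wall shear stress, dyn/cm^2.
#' @examples
#' wall_shear_stress(5)          # 2.5 dyn/cm^2 in a 200 x 100 um channel
#' @export
wall_shear_stress <- function(flow_ul_min, width_um = 200, height_um = 100,
                              viscosity_mPa_s = 1.0) {
  if (any(c(width_um, height_um, viscosity_mPa_s) <= 0) || any(flow_ul_min < 0))
    stop("dimensions and viscosity must be positive; flow non-negative")
  if (width_um < height_um)
    stop("width must be at least height (shear evaluated on the wide wall)")
  q_cm3_s <- flow_ul_min * 1e-3 / 60            # uL/min -> cm^3/s
  mu_poise <- viscosity_mPa_s * 0.01            # mPa s (cP) -> poise
  w <- um_to_cm(width_um); h <- um_to_cm(height_um)
  6 * mu_poise * q_cm3_s / (w * h^2)            # dyn/cm^2
}

#' Flow rate producing a target wall shear stress
#'
#' Exact inverse of [wall_shear_stress()].
#'
#' @param shear_dyn_cm2 target wall shear stress, dyn/cm^2.
#' @inheritParams wall_shear_stress
#' @return Flow rate, uL/min.
#' @export
flow_for_shear <- function(shear_dyn_cm2, width_um = 200, height_um = 100,
                           viscosity_mPa_s = 1.0) {
  if (any(shear_dyn_cm2 < 0)) stop("shear must be non-negative")
  mu_poise <- viscosity_mPa_s * 0.01
  w <- um_to_cm(width_um); h <- um_to_cm(height_um)
  q_cm3_s <- shear_dyn_cm2 * w * h^2 / (6 * mu_poise)
  q_cm3_s * 60 * 1e3                            # cm^3/s -> uL/min
}

#' Linear shear-conditioning ramp schedule
#'
#' Endothelial monolayers detach when abruptly exposed to physiological
#' shear; they are conditioned instead by a linear ramp from a low
#' starting shear to the physiological target, followed by a constant
#' hold. The schedule is generated in shear space,
#' \eqn{\tau(t) = \tau_0 + (\tau_1 - \tau_0) t / T_{ramp}} for
#' \eqn{t \le T_{ramp}} then constant, and the pump flow rates are
#' obtained by exact inversion of the plane-Poiseuille relation, so the
#' flow column is strictly proportional to the shear column.
#'
#' @param start_shear,end_shear ramp endpoints, dyn/cm^2 (defaults: the
#'   0.05 to 2.73 dyn/cm^2 overnight conditioning protocol).
#' @param ramp_duration,hold_duration ramp and hold lengths, s.
#' @param step schedule resolution, s.
#' @inheritParams wall_shear_stress
#' @return A data.frame of class `ramp_schedule` with columns `time_s`,
#'   `shear_dyn_cm2`, `flow_ul_min`.
#' @examples
#' sched <- ramp_schedule()
#' sched[sched$time_s == 6 * 3600, "shear_dyn_cm2"]   # midpoint: 1.39
#' @export
ramp_schedule <- function(start_shear = 0.05, end_shear = 2.73,
                          ramp_duration = 12 * 3600,
                          hold_duration = 6 * 3600, step = 60,
                          width_um = 200, height_um = 100,
                          viscosity_mPa_s = 1.0) {
  if (end_shear < start_shear || start_shear < 0)
    stop("need end_shear >= start_shear >= 0")
  if (ramp_duration <= 0 || hold_duration <= 0 || step <= 0)
    stop("durations and step must be positive")
  t <- seq(0, ramp_duration + hold_duration, by = step)
  shear <- ifelse(t <= ramp_duration,
                  start_shear + (end_shear - start_shear) * t / ramp_duration,
                  end_shear)
  flow <- flow_for_shear(shear, width_um, height_um, viscosity_mPa_s)
  out <- data.frame(time_s = t, shear_dyn_cm2 = shear, flow_ul_min = flow)
  attr(out, "ramp_duration") <- ramp_duration
  attr(out, "hold_duration") <- hold_duration
  class(out) <- c("ramp_schedule", "data.frame")
  out
}

#' @export
print.ramp_schedule <- function(x, ...) {
  rd <- attr(x, "ramp_duration"); hd <- attr(x, "hold_duration")
  cat(sprintf("Shear conditioning ramp: %.3g -> %.3g dyn/cm^2 over %.3g h, hold %.3g h (%d entries)\n",
              x$shear_dyn_cm2[1], max(x$shear_dyn_cm2), rd / 3600, hd / 3600,
              nrow(x)))
  cat(sprintf("  pump flow: %.3g -> %.3g uL/min\n",
              x$flow_ul_min[1], max(x$flow_ul_min)))
  invisible(x)
}

#' Write a ramp schedule as a pump-programmable CSV
#'
#' @param schedule a [ramp_schedule()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ramp_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "ramp_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}
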