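#' Fluorescent tracer description
#'
#' @param name tracer label.
#' @param molecular_weight_kda nominal molecular weight, kDa.
#' @param stokes_radius_A hydrodynamic (Stokes) radius, Angstrom.
#' @param inlet_concentration_nM concentration perfused through the apical
#'   channel, nM. The assay-standard probe concentration is 312.5 nM.
#' @param brightness_gain detector counts per nM of tracer at the imaging
#'   settings; the default puts the apical equilibrium near 30,000 counts
#'   on a 16-bit camera at 312.5 nM.
#' @return An object of class `tracer_spec`.
#' @seealso [fitc_dextran()] for the standard 10/70 kDa probes.
#' @export
tracer_spec <- function(name, molecular_weight_kda, stokes_radius_A,
                        inlet_concentration_nM = 312.5,
                        brightness_gain = 96) {
  if (stokes_radius_A <= 0) stop("stokes_radius_A must be positive")
  if (inlet_concentration_nM <= 0) stop("inlet_concentration_nM must be positive")
  structure(list(name = name,
                 molecular_weight_kda = molecular_weight_kda,
                 stokes_radius_A = stokes_radius_A,
                 inlet_concentration_nM = inlet_concentration_nM,
                 brightness_gain = brightness_gain),
            class = "tracer_spec")
}

#' Standard FITC-dextran probes
#'
#' Size-selectivity probes used for paracellular permeability: 10 kDa
#' (Stokes radius 23 Angstrom) and 70 kDa (60 Angstrom) FITC-dextran.
#'
#' @param size `"10kDa"` or `"70kDa"`.
#' @param ... passed on to [tracer_spec()].
#' @return A `tracer_spec`.
#' @export
fitc_dextran <- function(size = c("10kDa", "70kDa"), ...) {
  size <- match.arg(size)
  if (size == "10kDa")
    tracer_spec("FITC-dextran 10 kDa", 10, 23, ...)
  else
    tracer_spec("FITC-dextran 70 kDa", 70, 60, ...)
}

#' Stokes-Einstein free diffusivity
#'
#' \eqn{D = k_B T / (6 \pi \mu r)} for a sphere of hydrodynamic radius
#' \eqn{r} in a fluid of viscosity \eqn{\mu}.
#'
#' @param stokes_radius_A Stokes radius, Angstrom.
#' @param temperature_K absolute temperature (default 310 K, culture
#'   conditions).
#' @param viscosity_Pa_s dynamic viscosity (default 6.9e-4 Pa s, water at
#'   37 C).
#' @return Diffusivity in cm^2/s.
#' @examples
#' stokes_einstein_diffusivity(23)   # ~1.4e-6 cm^2/s
#' @export
stokes_einstein_diffusivity <- function(stokes_radius_A, temperature_K = 310,
                                        viscosity_Pa_s = 6.9e-4) {
  if (any(c(stokes_radius_A, temperature_K, viscosity_Pa_s) <= 0))
    stop("all arguments must be positive")
  kb <- 1.380649e-23                       # J/K
  r_m <- stokes_radius_A * 1e-10
  d_m2s <- kb * temperature_K / (6 * pi * viscosity_Pa_s * r_m)
  d_m2s * 1e4                              # m^2/s -> cm^2/s
}

#' Series combination of barrier permeabilities
#'
#' Two barriers in series (endothelial monolayer on its supporting pore
#' scaffold) add as resistances: \eqn{1/P_{total} = 1/P_e + 1/P_{scaffold}}.
#'
#' @param p_endothelium,p_scaffold permeabilities, cm/s. Either may be
#'   `NULL`/`Inf`, meaning that barrier is absent.
#' @return The combined permeability, cm/s.
#' @examples
#' series_combine(1.5e-5, 5.0e-5)   # 1.154e-5
#' @export
series_combine <- function(p_endothelium, p_scaffold) {
  pe <- if (is.null(p_endothelium)) Inf else p_endothelium
  ps <- if (is.null(p_scaffold)) Inf else p_scaffold
  if (pe < 0 || ps < 0) stop("permeabilities must be non-negative")
  if (pe == 0 && ps == 0) stop("both permeabilities are zero")
  if (is.infinite(pe)) return(ps)
  if (is.infinite(ps)) return(pe)
  1 / (1 / pe + 1 / ps)
}

#' Recover the endothelial permeability by scaffold subtraction
#'
#' Inverts the series combination: \eqn{1/P_e = 1/P_{total} -
#' 1/P_{scaffold}}. Requires the overall barrier to be slower than the
#' bare scaffold, otherwise no endothelial resistance is resolvable.
#'
#' @param p_total overall measured permeability, cm/s.
#' @param p_scaffold acellular scaffold permeability, cm/s (`Inf` allowed:
#'   no scaffold correction).
#' @return Endothelial permeability \eqn{P_e}, cm/s.
#' @examples
#' subtract_scaffold(1.1538462e-05, 5.0e-5)   # 1.5e-5
#' @export
subtract_scaffold <- function(p_total, p_scaffold) {
  if (p_total <= 0) stop("p_total must be positive")
  if (is.infinite(p_scaffold)) return(p_total)
  if (p_scaffold <= 0) stop("p_scaffold must be positive")
  if (p_total >= p_scaffold)
    stop("barrier faster than scaffold - no endothelial resistance resolvable")
  1 / (1 / p_total - 1 / p_scaffold)
}

#' Transport parameters of a chip run
#'
#' Bundles the true (simulation) or assumed (analysis) permeabilities with
#' the compartment exchange constants. The overall permeability is always
#' the series combination of the endothelial and scaffold values; for an
#' acellular run leave `p_endothelium = NULL` and `p_total = p_scaffold`.
#'
#' @param p_scaffold acellular scaffold permeability, cm/s.
#' @param p_endothelium endothelial monolayer permeability, cm/s, or `NULL`
#'   for an acellular run.
#' @param vs_ratio receiver volume-to-exchange-surface ratio, cm (see
#'   [chip_geometry()]).
#' @param apical_fill_tau time constant of the exponential rise of the
#'   apical concentration to its inlet value, s (dead volume / tubing);
#'   `0` means the apical side is clamped from t = 0.
#' @return An object of class `transport_params` with derived `p_total` and
#'   the exchange rate `k_exchange = p_total / vs_ratio` (1/s).
#' @export
transport_params <- function(p_scaffold, p_endothelium = NULL,
                             vs_ratio = chip_geometry()$vs_ratio_cm,
                             apical_fill_tau = 300) {
  if (!is.null(p_endothelium) && p_endothelium < 0)
    stop("p_endothelium must be non-negative")
  if (p_scaffold < 0) stop("p_scaffold must be non-negative")
  if (vs_ratio <= 0) stop("vs_ratio must be positive")
  if (apical_fill_tau < 0) stop("apical_fill_tau must be non-negative")
  p_total <- series_combine(p_endothelium, p_scaffold)
  structure(list(p_endothelium = p_endothelium, p_scaffold = p_scaffold,
                 p_total = p_total, vs_ratio = vs_ratio,
                 apical_fill_tau = apical_fill_tau,
                 k_exchange = p_total / vs_ratio),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Two-compartment transport parameters\n")
  if (is.null(x$p_endothelium)) cat("  acellular run (no endothelial barrier)\n")
  else cat(sprintf("  P_endothelium : %.4g cm/s\n", x$p_endothelium))
  cat(sprintf("  P_scaffold    : %.4g cm/s\n", x$p_scaffold))
  cat(sprintf("  P_total       : %.4g cm/s\n", x$p_total))
  cat(sprintf("  V/S           : %.4g cm   (exchange rate %.4g 1/s)\n",
              x$vs_ratio, x$k_exchange))
  cat(sprintf("  apical fill   : tau = %g s\n", x$apical_fill_tau))
  invisible(x)
}
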