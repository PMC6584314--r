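#' Acquisition (camera) configuration for the simulator
#'
#' Emulates a widefield time-lapse acquisition: one 16-bit grayscale frame
#' per `frame_interval`. Noise follows the standard gain-scaled camera
#' model: counts = `photon_gain` * Poisson(signal / `photon_gain`) +
#' `background_level` + N(0, `read_noise_sd`), clipped to the bit depth, so
#' that the variance of a uniform region is
#' `photon_gain * (mean - background) + read_noise_sd^2`.
#'
#' @param frame_interval seconds between frames (default 60: one frame per
#'   minute).
#' @param n_frames number of frames (default 120, a 2 h acquisition).
#' @param bit_depth camera bit depth.
#' @param background_level constant detector offset, counts.
#' @param photon_gain counts per photon-equivalent; `0` disables shot noise.
#' @param read_noise_sd Gaussian read noise, counts; `0` disables it.
#' @param bleach_rate first-order photobleaching rate, 1/s.
#' @param seed integer seed driving every stochastic draw of a simulated
#'   acquisition (per-frame substreams are derived from it).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_interval = 60, n_frames = 120,
                               bit_depth = 16, background_level = 400,
                               photon_gain = 0.5, read_noise_sd = 10,
                               bleach_rate = 0, seed = 1L) {
  if (n_frames < 3) stop("n_frames must be at least 3")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (any(c(background_level, photon_gain, read_noise_sd, bleach_rate) < 0))
    stop("noise parameters must be non-negative")
  structure(list(frame_interval = frame_interval, n_frames = n_frames,
                 bit_depth = as.integer(bit_depth),
                 background_level = background_level,
                 photon_gain = photon_gain, read_noise_sd = read_noise_sd,
                 bleach_rate = bleach_rate, seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Two-compartment tracer concentrations over time
#'
#' Forward model of passive tracer transport in the radial chip. The apical
#' channel fills exponentially to the inlet concentration,
#' \eqn{C_a(t) = C_0 (1 - e^{-t/\tau})}, and the receiver follows
#' \eqn{dC_b/dt = k (C_a - C_b)} with \eqn{k = P_{total} / (V/S)} and
#' \eqn{C_b(0) = 0}. The exact two-exponential solution is evaluated
#' (confluent limit handled when \eqn{k \to 1/\tau}); with the apical side
#' clamped (\eqn{\tau = 0}) it reduces to \eqn{C_b = C_0(1 - e^{-kt})}.
#'
#' @param params a [transport_params()] object.
#' @param tracer a [tracer_spec()] object (supplies \eqn{C_0}).
#' @param times sampling times, s; non-decreasing, starting at 0.
#' @return A data.frame with columns `time`, `apical`, `basolateral` (nM).
#' @examples
#' p <- transport_params(p_scaffold = 5e-5, p_endothelium = 1.5e-5,
#'                       apical_fill_tau = 0)
#' ct <- compartment_transport(p, fitc_dextran("10kDa"), c(0, 3600))
#' ct$basolateral[2] / 312.5   # 1 - exp(-3600 * k)
#' @export
compartment_transport <- function(params, tracer, times) {
  stopifnot(inherits(params, "transport_params"),
            inherits(tracer, "tracer_spec"))
  if (length(times) < 1 || times[1] < 0 ||
      (length(times) > 1 && any(diff(times) <= 0)))
    stop("times must be non-negative and strictly increasing")
  c0 <- tracer$inlet_concentration_nM
  k <- params$k_exchange
  tau <- params$apical_fill_tau
  if (tau <= 0) {
    ca <- rep(c0, length(times))
    cb <- c0 * (1 - exp(-k * times))
  } else {
    a <- 1 / tau
    ca <- c0 * (1 - exp(-a * times))
    if (k == 0) {
      cb <- rep(0, length(times))
    } else if (abs(k - a) < 1e-12 * max(k, a)) {
      cb <- c0 * (1 - exp(-k * times) * (1 + k * times))
    } else {
      cb <- c0 * (1 - exp(-k * times) -
                    k * (exp(-a * times) - exp(-k * times)) / (k - a))
    }
  }
  data.frame(time = times, apical = ca, basolateral = cb)
}

#' Azimuthally resolved receiver concentrations (2D diffusion mode)
#'
#' Explicit finite-difference solution of diffusion on the basolateral
#' disk in polar coordinates, with a flux boundary at the wall whose local
#' permeability varies azimuthally:
#' \eqn{D \partial C/\partial r |_{r=R} = p(\theta) (C_a(t) - C_{wall})}.
#' Used to create azimuthal heterogeneity for sector-level analyses; the
#' well-mixed model of [compartment_transport()] is the default elsewhere.
#'
#' @param params a [transport_params()] object; `params$p_total` is the
#'   azimuthal mean wall permeability.
#' @param tracer a [tracer_spec()] object; its Stokes radius sets the free
#'   diffusivity via [stokes_einstein_diffusivity()].
#' @param times sampling times, s.
#' @param sector_factors numeric vector of relative local permeability
#'   factors per equal-angle arc (recycled around the wall); `c(1,1,...)`
#'   is homogeneous.
#' @param n_r,n_theta polar grid resolution (rings x wedges).
#' @param chamber_radius_cm disk radius, cm.
#' @return A list: `times`, `apical` (nM), `cells` (matrix
#'   `length(times)` x `n_r * n_theta`, nM), `r_edges_cm`, `theta_id`
#'   (wedge index of each cell), `sector_mean` (matrix
#'   `length(times)` x `n_theta` of ring-averaged wedge concentrations).
#' @export
compartment_transport_2d <- function(params, tracer, times,
                                     sector_factors = rep(1, 12),
                                     n_r = 24, n_theta = 36,
                                     chamber_radius_cm = 0.09) {
  stopifnot(inherits(params, "transport_params"),
            inherits(tracer, "tracer_spec"))
  c0 <- tracer$inlet_concentration_nM
  D <- stokes_einstein_diffusivity(tracer$stokes_radius_A)
  R <- chamber_radius_cm
  dr <- R / n_r
  dth <- 2 * pi / n_theta
  r_c <- (seq_len(n_r) - 0.5) * dr        # ring centres
  r_f <- seq_len(n_r) * dr                # outer face radius per ring
  # local wall permeability per wedge: factor j applies to the j-th
  # equal-angle arc (factor 1 = the nominal p_total)
  n_arc <- length(sector_factors)
  arc_of_wedge <- pmin(floor((seq_len(n_theta) - 0.5) / n_theta * n_arc) + 1L,
                       n_arc)
  p_loc <- params$p_total * sector_factors[arc_of_wedge]
  # azimuthal diffusion is evaluated only outside the inner quarter radius:
  # wedge cells near the axis are tiny and effectively uniform, and skipping
  # them lifts the crippling stability limit of the innermost ring
  az_rings <- which(r_c > R / 4)
  dt <- 0.4 / (D * (1 / dr^2 + 1 / (r_c[min(az_rings)] * dth)^2))
  tau <- params$apical_fill_tau
  Cgrid <- matrix(0, n_r, n_theta)
  out <- matrix(NA_real_, length(times), n_r * n_theta)
  t_now <- 0
  ti <- 1
  t_end <- max(times)
  while (ti <= length(times)) {
    while (t_now < times[ti] - 1e-9) {
      h <- min(dt, times[ti] - t_now)
      ca <- if (tau <= 0) c0 else c0 * (1 - exp(-t_now / tau))
      # radial fluxes at faces (conservative form)
      flux_out <- matrix(0, n_r, n_theta)   # D * r_f * dC/dr at outer face
      if (n_r > 1)
        flux_out[-n_r, ] <- D * r_f[-n_r] * (Cgrid[-1, ] - Cgrid[-n_r, ]) / dr
      # wall boundary: permeation flux into the outermost ring
      flux_out[n_r, ] <- r_f[n_r] * p_loc * (ca - Cgrid[n_r, ])
      flux_in <- rbind(0, flux_out[-n_r, , drop = FALSE])
      dC_rad <- (flux_out - flux_in) / (r_c * dr)
      # azimuthal diffusion (outer rings only, see above)
      left <- Cgrid[, c(n_theta, seq_len(n_theta - 1)), drop = FALSE]
      right <- Cgrid[, c(2:n_theta, 1), drop = FALSE]
      dC_th <- matrix(0, n_r, n_theta)
      dC_th[az_rings, ] <- D *
        (left[az_rings, ] + right[az_rings, ] - 2 * Cgrid[az_rings, ]) /
        (r_c[az_rings]^2 * dth^2)
      Cgrid <- Cgrid + h * (dC_rad + dC_th)
      t_now <- t_now + h
    }
    out[ti, ] <- as.vector(Cgrid)
    ti <- ti + 1
  }
  theta_id <- rep(seq_len(n_theta), each = n_r)
  sector_mean <- t(apply(out, 1, function(row) {
    m <- matrix(row, n_r, n_theta)
    # area-weighted ring average per wedge
    colSums(m * r_c) / sum(r_c)
  }))
  ca_all <- if (tau <= 0) rep(c0, length(times)) else c0 * (1 - exp(-times / tau))
  list(times = times, apical = ca_all, cells = out,
       r_edges_cm = c(0, r_f), theta_id = theta_id,
       n_r = n_r, n_theta = n_theta, sector_mean = sector_mean)
}

# deterministic per-frame substream seed
frame_seed <- function(seed, frame) {
  as.integer((as.numeric(seed) * 48271 + frame * 16807) %% 2147483647)
}

#' Render compartment concentrations into a noisy image stack
#'
#' Each frame assigns every masked pixel the expected fluorescence signal
#' `brightness_gain * C * exp(-bleach_rate * t)` of its compartment, draws
#' gain-scaled Poisson shot noise, adds the constant detector background
#' and Gaussian read noise, and clips to the camera bit depth. Pixels in no
#' ROI (the pillar barrier annulus) carry zero signal. Identical
#' configuration and seed give a bit-identical stack.
#'
#' @param conc data.frame from [compartment_transport()].
#' @param masks a [rasterize_chip()] mask set.
#' @param tracer a [tracer_spec()].
#' @param acq an [acquisition_config()].
#' @param basolateral_field optional per-pixel basolateral concentration:
#'   a matrix `n_frames` x `sum(masks$basolateral)` (nM), overriding the
#'   well-mixed `conc$basolateral` (used by the 2D diffusion mode).
#' @return A list of `n_frames` integer matrices (counts).
#' @export
render_frames <- function(conc, masks, tracer, acq, basolateral_field = NULL) {
  stopifnot(inherits(masks, "roi_masks"), inherits(tracer, "tracer_spec"),
            inherits(acq, "acquisition_config"))
  n <- nrow(conc)
  if (n != acq$n_frames)
    stop("one concentration pair per frame time is required")
  if (!is.null(basolateral_field) &&
      (nrow(basolateral_field) != n ||
       ncol(basolateral_field) != sum(masks$basolateral)))
    stop("basolateral_field must be n_frames x n_basolateral_pixels")
  shape <- masks$frame_shape
  maxc <- 2^acq$bit_depth - 1
  gain <- acq$photon_gain
  b <- tracer$brightness_gain
  ap <- which(masks$apical); ba <- which(masks$basolateral)
  stack <- vector("list", n)
  n_sat <- 0
  for (i in seq_len(n)) {
    set.seed(frame_seed(acq$seed, i))
    t_i <- conc$time[i]
    fade <- exp(-acq$bleach_rate * t_i)
    sig <- matrix(0, shape[1], shape[2])
    sig[ap] <- b * conc$apical[i] * fade
    sig[ba] <- if (is.null(basolateral_field)) b * conc$basolateral[i] * fade
               else b * basolateral_field[i, ] * fade
    if (gain > 0) {
      counts <- matrix(0, shape[1], shape[2])
      nz <- which(sig > 0)
      counts[nz] <- gain * stats::rpois(length(nz), sig[nz] / gain)
    } else counts <- sig
    px <- counts + acq$background_level
    if (acq$read_noise_sd > 0)
      px <- px + stats::rnorm(length(px), 0, acq$read_noise_sd)
    px <- round(pmin(pmax(px, 0), maxc))
    n_sat <- n_sat + sum(px >= maxc)
    stack[[i]] <- matrix(as.integer(px), shape[1], shape[2])
  }
  if (n_sat > 0.01 * n * prod(shape))
    warning(sprintf("saturation: %.2f%% of pixels at full scale",
                    100 * n_sat / (n * prod(shape))))
  stack
}

#' Simulate a full time-lapse acquisition
#'
#' Runs the forward transport model on the chip geometry, renders the noisy
#' image stack, and (optionally) writes a multi-page 16-bit TIFF together
#' with a JSON frame-time sidecar and a JSON ground-truth manifest, so that
#' downstream analysis can be validated by parameter recovery.
#'
#' @param geometry a [chip_geometry()].
#' @param tracer a [tracer_spec()].
#' @param transport a [transport_params()] (acellular runs: build it with
#'   `p_endothelium = NULL`).
#' @param acq an [acquisition_config()].
#' @param masks optional pre-rasterized [rasterize_chip()] masks; by
#'   default the geometry is rasterized at `pixel_size`.
#' @param pixel_size raster resolution, um/px, when `masks` is `NULL`.
#' @param sector_factors optional relative local wall permeability factors;
#'   switches the forward model to the 2D diffusion mode
#'   ([compartment_transport_2d()]).
#' @param path optional output stem: writes `<path>.tif`,
#'   `<path>_times.json` and `<path>_truth.json`.
#' @return A list of class `chip_acquisition`: `stack` (list of integer
#'   matrices), `times` (s), `masks`, `conc` (forward-model
#'   concentrations) and `manifest` (ground truth echo).
#' @export
generate_acquisition <- function(geometry, tracer, transport, acq,
                                 masks = NULL, pixel_size = 10,
                                 sector_factors = NULL, path = NULL) {
  stopifnot(inherits(geometry, "chip_geometry"))
  if (is.null(masks))
    masks <- rasterize_chip(geometry, pixel_size)
  times <- (seq_len(acq$n_frames) - 1) * acq$frame_interval
  baso_field <- NULL
  if (is.null(sector_factors)) {
    conc <- compartment_transport(transport, tracer, times)
  } else {
    sol <- compartment_transport_2d(transport, tracer, times,
                                    sector_factors = sector_factors,
                                    chamber_radius_cm =
                                      um_to_cm(geometry$chamber_diameter) / 2)
    conc <- data.frame(time = times, apical = sol$apical,
                       basolateral = rowMeans(sol$sector_mean))
    baso_field <- map_polar_field(sol, masks, geometry)
  }
  stack <- render_frames(conc, masks, tracer, acq,
                         basolateral_field = baso_field)
  manifest <- list(
    transport = list(p_endothelium = transport$p_endothelium,
                     p_scaffold = transport$p_scaffold,
                     p_total = transport$p_total,
                     vs_ratio = transport$vs_ratio,
                     apical_fill_tau = transport$apical_fill_tau),
    tracer = unclass(tracer),
    acquisition = unclass(acq),
    geometry_hash = geometry_hash(geometry),
    sector_factors = sector_factors,
    seed = acq$seed)
  out <- list(stack = stack, times = times, masks = masks, conc = conc,
              manifest = manifest)
  class(out) <- "chip_acquisition"
  if (!is.null(path)) write_acquisition(out, path)
  out
}

# project the polar-grid solution onto the basolateral pixels of the raster
map_polar_field <- function(sol, masks, geometry) {
  shape <- masks$frame_shape
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  idx <- which(masks$basolateral)
  row <- (idx - 1) %% shape[1] + 1
  col <- (idx - 1) %/% shape[1] + 1
  x <- (col - cx) * masks$pixel_size
  y <- (cy - row) * masks$pixel_size
  R_um <- geometry$chamber_diameter / 2
  r <- pmin(sqrt(x^2 + y^2) / R_um, 1 - 1e-9)        # fraction of radius
  th <- atan2(y, x); th[th < 0] <- th[th < 0] + 2 * pi
  ri <- pmin(floor(r * sol$n_r) + 1L, sol$n_r)
  tj <- pmin(floor(th / (2 * pi / sol$n_theta)) + 1L, sol$n_theta)
  cell <- ri + (tj - 1L) * sol$n_r
  sol$cells[, cell, drop = FALSE]
}

geometry_hash <- function(geometry) {
  nums <- unlist(unclass(geometry)[sapply(geometry, is.numeric)])
  paste0("g", format(sum(nums * seq_along(nums)), digits = 12))
}

#' Write a simulated acquisition to disk
#'
#' Multi-page 16-bit grayscale TIFF plus JSON sidecars (`_times.json` with
#' the frame times, `_truth.json` with the ground-truth manifest).
#'
#' @param acquisition a `chip_acquisition` from [generate_acquisition()].
#' @param path output stem (no extension).
#' @return Invisibly, the TIFF path.
#' @export
write_acquisition <- function(acquisition, path) {
  stopifnot(inherits(acquisition, "chip_acquisition"))
  maxc <- 2^acquisition$manifest$acquisition$bit_depth - 1
  tif <- paste0(path, ".tif")
  ok <- try(tiff::writeTIFF(lapply(acquisition$stack, function(m) m / maxc),
                            tif, bits.per.sample = 16L,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write TIFF '%s': %s", tif, as.character(ok)))
  jsonlite::write_json(list(frame_interval =
                              acquisition$manifest$acquisition$frame_interval,
                            times = acquisition$times),
                       paste0(path, "_times.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(acquisition$manifest, paste0(path, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tif)
}

#' Synthetic two-slope normalized-intensity profile
#'
#' Generates the changepoint fixture used to exercise the inflection
#' detector: a piecewise-linear normalized intensity that rises with a
#' gentle slope (fill-limited early transport), steepens by
#' `slope_ratio` at `break_time` (the breakpoint is therefore a true
#' inflection, where curvature changes sign), and plateaus after
#' `plateau_time`, plus i.i.d. Gaussian noise. A profile whose slope only
#' ever decreases has no inflection, so a curvature-based detector is
#' correctly blind to it; the accelerating shape is also the realistic one
#' for a receiver fed through a slowly filling donor channel.
#'
#' @param n_frames number of samples.
#' @param frame_interval seconds between samples.
#' @param break_time slope-change (inflection) time, s.
#' @param plateau_time start of the flat plateau, s.
#' @param slope_ratio ratio of the post-break to pre-break slope.
#' @param plateau_level normalized intensity of the plateau.
#' @param noise_sd Gaussian noise SD on the normalized intensity.
#' @param seed integer seed.
#' @return A data.frame `time` (s), `I`, `sd` (the noise SD, for use as
#'   fit weights), plus attribute `truth` echoing the generator values.
#' @export
two_slope_profile <- function(n_frames = 120, frame_interval = 60,
                              break_time = 3600, plateau_time = 5400,
                              slope_ratio = 3, plateau_level = 0.6,
                              noise_sd = 0.01, seed = 1L) {
  stopifnot(break_time < plateau_time, slope_ratio > 0)
  t <- (seq_len(n_frames) - 1) * frame_interval
  # pre-break slope s1, post-break s1 * slope_ratio, flat after plateau
  s1 <- plateau_level / (break_time + slope_ratio * (plateau_time - break_time))
  s2 <- s1 * slope_ratio
  I0 <- ifelse(t < break_time, s1 * t,
               ifelse(t < plateau_time,
                      s1 * break_time + s2 * (t - break_time),
                      s1 * break_time + s2 * (plateau_time - break_time)))
  set.seed(as.integer(seed))
  out <- data.frame(time = t, I = I0 + stats::rnorm(n_frames, 0, noise_sd),
                    sd = rep(noise_sd, n_frames))
  attr(out, "truth") <- list(break_time = break_time,
                             plateau_time = plateau_time,
                             slope_pre = s1, slope_post = s2,
                             plateau_level = plateau_level,
                             noise_sd = noise_sd, seed = seed)
  out
}
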