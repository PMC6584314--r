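# shared builders for the test suite; everything is generated in code

# hand-built 4x4 mask set for arithmetic-level checks
tiny_masks <- function() {
  ap <- ba <- bg <- matrix(FALSE, 4, 4)
  ap[1, ] <- TRUE                 # top row: apical
  ba[2:3, 2:3] <- TRUE            # centre 2x2: basolateral
  bg[4, ] <- TRUE                 # bottom row: background
  structure(list(apical = ap, basolateral = ba, background = bg,
                 sectors = list(ba), pixel_size = 1,
                 frame_shape = c(4L, 4L)),
            class = "roi_masks")
}

# constant-valued stack on the tiny masks
tiny_stack <- function(n_frames, apical, baso, bg) {
  lapply(seq_len(n_frames), function(i) {
    f <- matrix(0, 4, 4)
    f[1, ] <- apical; f[2:3, 2:3] <- baso; f[4, ] <- bg
    f
  })
}

# small full-chain simulation (coarse raster for speed)
quick_run <- function(p_scaffold, p_endothelium = NULL, seed = 1,
                      n_frames = 60, pixel = 20, sectors = FALSE,
                      sector_factors = NULL, tracer = fitc_dextran("10kDa"),
                      geometry = chip_geometry(), ...) {
  tp <- transport_params(p_scaffold = p_scaffold,
                         p_endothelium = p_endothelium,
                         vs_ratio = geometry$vs_ratio_cm)
  masks <- rasterize_chip(geometry, pixel)
  acq <- acquisition_config(seed = seed, n_frames = n_frames, ...)
  sim <- generate_acquisition(geometry, tracer, tp, acq, masks = masks,
                              sector_factors = sector_factors)
  ts <- extract_timeseries(sim, masks, sectors = sectors)
  prof <- normalize_profile(ts)
  list(sim = sim, masks = masks, ts = ts, prof = prof,
       geometry = geometry, transport = tp, acq = acq, tracer = tracer)
}

# independent brute-force weighted least squares via explicit sums
wls_oracle <- function(t, y, sd) {
  w <- 1 / sd^2
  sw <- sum(w); swx <- sum(w * t); swy <- sum(w * y)
  swxx <- sum(w * t^2); swxy <- sum(w * t * y)
  den <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / den
  intercept <- (swy - slope * swx) / sw
  resid <- y - intercept - slope * t
  sigma2 <- sum(w * resid^2) / (length(t) - 2)
  slope_se <- sqrt(sigma2 * sw / den)
  list(slope = slope, intercept = intercept, slope_se = slope_se)
}
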