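test_that("receiver concentration follows the clamped-donor closed form", {
  tr <- fitc_dextran("10kDa")
  tp <- transport_params(p_scaffold = 1.154e-5, vs_ratio = 0.045,
                         apical_fill_tau = 0)
  times <- seq(0, 7200, by = 60)
  ct <- compartment_transport(tp, tr, times)
  closed <- 312.5 * (1 - exp(-tp$k_exchange * times))
  expect_true(all(abs(ct$basolateral[-1] / closed[-1] - 1) < 1e-12))
  # the 60-min value quoted for these kinetics
  expect_equal(ct$basolateral[times == 3600] / 312.5, 0.603, tolerance = 1e-2)
  expect_true(all(ct$apical == 312.5))
})

test_that("zero permeability carries no flux; equilibrium reaches the inlet", {
  tr <- fitc_dextran("10kDa")
  z <- transport_params(p_scaffold = 0, p_endothelium = 1e-5)
  expect_identical(z$p_total, 0)
  ct <- compartment_transport(z, tr, seq(0, 3600, 600))
  expect_true(all(ct$basolateral == 0))
  fast <- transport_params(p_scaffold = 5e-5, apical_fill_tau = 300)
  eq <- compartment_transport(fast, tr, c(0, 1e6))
  expect_equal(eq$basolateral[2] / 312.5, 1, tolerance = 1e-6)
})

test_that("receiver series is monotone and never exceeds the donor", {
  tr <- fitc_dextran("70kDa")
  set.seed(21)
  for (i in 1:10) {
    tp <- transport_params(p_scaffold = 10^runif(1, -6, -4),
                           p_endothelium = 10^runif(1, -6, -4),
                           apical_fill_tau = runif(1, 0, 600))
    ct <- compartment_transport(tp, tr, seq(0, 7200, 60))
    expect_true(all(diff(ct$basolateral) >= -1e-9))
    expect_true(all(ct$basolateral <= ct$apical * (1 + 1e-6) + 1e-9))
  }
  expect_error(compartment_transport(tp, tr, c(0, 60, 60)), "increasing")
})

test_that("closed-form solution agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  tr <- fitc_dextran("10kDa")
  tp <- transport_params(p_scaffold = 5e-5, p_endothelium = 1.5e-5,
                         apical_fill_tau = 300)
  times <- seq(0, 7200, by = 120)
  ct <- compartment_transport(tp, tr, times)
  rhs <- function(t, y, parms) {
    ca <- 312.5 * (1 - exp(-t / 300))
    list(parms$k * (ca - y[1]))
  }
  num <- deSolve::ode(c(cb = 0), times, rhs, list(k = tp$k_exchange),
                      rtol = 1e-10, atol = 1e-12)
  expect_true(all(abs(ct$basolateral[-1] - num[-1, "cb"]) <
                    1e-6 * pmax(num[-1, "cb"], 1e-9)))
})

test_that("rendering is deterministic and respects the camera noise model", {
  r <- quick_run(5e-5, 1.5e-5, seed = 9, n_frames = 30, pixel = 10)
  r2 <- quick_run(5e-5, 1.5e-5, seed = 9, n_frames = 30, pixel = 10)
  expect_identical(r$sim$stack, r2$sim$stack)
  r3 <- quick_run(5e-5, 1.5e-5, seed = 10, n_frames = 30, pixel = 10)
  expect_false(identical(r$sim$stack, r3$sim$stack))
  # tracer-free region: mean equals the detector background within read noise
  bg_px <- r$sim$stack[[1]][r$masks$background]
  expect_equal(mean(bg_px), 400, tolerance = 1e-3)
  expect_equal(stats::sd(bg_px), 10, tolerance = 0.05)
  # uniform signal region: var ~ gain*(mean - bg) + read^2 (>= 1e4 pixels)
  f <- r$sim$stack[[30]]
  ap <- f[r$masks$apical]
  expect_gt(length(ap), 1e4)
  pred_var <- 0.5 * (mean(ap) - 400) + 10^2
  expect_lt(abs(stats::var(ap) / pred_var - 1), 0.10)
})

test_that("signal is linear in inlet concentration", {
  g <- chip_geometry(); m <- rasterize_chip(g, 10)
  tp <- transport_params(p_scaffold = 5e-5, p_endothelium = 1.5e-5)
  mk <- function(conc, seed) {
    tr <- tracer_spec("x", 10, 23, inlet_concentration_nM = conc,
                      brightness_gain = 48)
    generate_acquisition(g, tr, tp, acquisition_config(seed = seed,
                                                       n_frames = 40),
                         masks = m)
  }
  a1 <- mk(312.5, 3); a2 <- mk(625, 3)
  m1 <- mean(a1$stack[[40]][m$apical]) - 400
  m2 <- mean(a2$stack[[40]][m$apical]) - 400
  expect_equal(m2 / m1, 2, tolerance = 0.01)
})

test_that("acquisitions round-trip through TIFF with an exact manifest", {
  g <- chip_geometry(); m <- rasterize_chip(g, 20)
  tr <- fitc_dextran("70kDa")
  tp <- transport_params(p_scaffold = 3.1e-5, apical_fill_tau = 300)
  acq <- acquisition_config(seed = 77, n_frames = 3)
  d <- withr::local_tempdir()
  stem <- file.path(d, "acq")
  sim <- generate_acquisition(g, tr, tp, acq, masks = m, path = stem)
  expect_true(file.exists(paste0(stem, ".tif")))
  back <- read_stack(stem)
  expect_length(back$stack, 3)
  expect_identical(back$times, sim$times)
  expect_identical(lapply(back$stack, function(x) matrix(as.integer(x),
                                                         nrow(x), ncol(x))),
                   sim$stack)
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 77)
  expect_equal(truth$transport$p_total, tp$p_total, tolerance = 1e-12)
  expect_equal(truth$tracer$inlet_concentration_nM, 312.5)
  expect_null(truth$transport$p_endothelium)
})

test_that("invalid acquisition settings are rejected", {
  expect_error(acquisition_config(n_frames = 2), "at least 3")
  expect_error(acquisition_config(frame_interval = 0), "positive")
  expect_error(acquisition_config(read_noise_sd = -1), "non-negative")
})

test_that("two-slope profile encodes its generator truth", {
  prof <- two_slope_profile(seed = 3)
  truth <- attr(prof, "truth")
  expect_equal(truth$break_time, 3600)
  expect_equal(truth$slope_post / truth$slope_pre, 3)
  expect_equal(nrow(prof), 120)
  # noise-free level at the plateau equals the configured plateau level
  noisefree <- two_slope_profile(noise_sd = 0, seed = 1)
  expect_equal(max(noisefree$I), 0.6, tolerance = 1e-12)
  expect_equal(noisefree$I[120], noisefree$I[91], tolerance = 1e-12)
})

test_that("2D diffusion mode conserves ordering against the wall profile", {
  tp <- transport_params(p_scaffold = 5e-5, p_endothelium = 1.5e-5)
  tr <- fitc_dextran("10kDa")
  sol <- compartment_transport_2d(tp, tr, times = c(0, 1800),
                                  sector_factors = c(0.2, rep(1, 11)))
  w <- sol$sector_mean[2, ]
  # wedges behind the low-permeability arc (first 3 of 36) are the lowest
  expect_true(all(rank(w)[1:3] <= 5))
  expect_true(all(w >= 0) && all(w <= 312.5))
})
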