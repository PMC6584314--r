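test_that("ROI means and sample SDs are the textbook values", {
  m <- tiny_masks()
  f <- matrix(0, 4, 4)
  f[2:3, 2:3] <- c(10, 20, 30, 40)
  ts <- extract_timeseries(list(f), m, times = 0)
  expect_equal(ts$baso_mean, 25)
  expect_equal(ts$baso_sd, sd(c(10, 20, 30, 40)), tolerance = 1e-12)
  expect_equal(ts$baso_sd, 12.91, tolerance = 1e-3)
  # constant frames give SD zero in every ROI
  ts2 <- extract_timeseries(tiny_stack(3, 7, 7, 7), m, times = c(0, 60, 120))
  expect_true(all(ts2$apical_mean == 7) && all(ts2$apical_sd == 0))
  expect_true(all(ts2$bg_sd == 0))
})

test_that("mismatched shapes and empty masks are rejected", {
  m <- tiny_masks()
  expect_error(extract_timeseries(list(matrix(0, 5, 5)), m), "5 x 5")
  m$apical[] <- FALSE
  expect_error(extract_timeseries(list(matrix(0, 4, 4)), m), "empty")
})

test_that("extracted apical series matches the forward model within 3 SE", {
  r <- quick_run(5e-5, 1.5e-5, seed = 3, n_frames = 40, pixel = 10)
  expect_gt(sum(r$masks$apical), 1e4)
  expected <- r$tracer$brightness_gain * r$sim$conc$apical + 400
  se <- r$ts$apical_sd / sqrt(sum(r$masks$apical))
  expect_true(all(abs(r$ts$apical_mean - expected) < 3 * se))
})

test_that("apical equilibrium detection follows the band criterion", {
  # constant series: first frame
  expect_identical(detect_apical_equilibrium(rep(5, 20)), 1L)
  # exponential approach, tau = 300 s sampled each minute: detected in [2,5]*tau
  t <- 0:119 * 60
  f <- detect_apical_equilibrium(1000 * (1 - exp(-t / 300)))
  expect_true(t[f] >= 600 && t[f] <= 1500)
  # a ramp that keeps climbing relative to its tail never plateaus
  expect_error(detect_apical_equilibrium(1.05^(1:120)), "never reached")
  expect_error(detect_apical_equilibrium(1:3, window = 5), "window")
})

test_that("normalization applies the background-subtracted ratio", {
  m <- tiny_masks()
  # apical 1000, basolateral 250, background 0
  ts <- extract_timeseries(tiny_stack(6, 1000, 250, 0), m)
  prof <- normalize_profile(ts)
  expect_true(all(prof$norm_I == 0.25))
  expect_identical(attr(prof, "equilibrium_frame"), 1L)
  # receiver at donor equilibrium: I = 1
  prof1 <- normalize_profile(extract_timeseries(tiny_stack(6, 1000, 1000, 0), m))
  expect_true(all(prof1$norm_I == 1))
  # with background: (700 - 400) / (1400 - 400) = 0.30
  prof2 <- normalize_profile(extract_timeseries(tiny_stack(6, 1400, 700, 400), m))
  expect_true(all(abs(prof2$norm_I - 0.30) < 1e-12))
  # no signal above background
  expect_error(normalize_profile(extract_timeseries(tiny_stack(6, 400, 400, 400), m)),
               "no signal")
})

test_that("normalization is invariant to affine detector rescaling", {
  r <- quick_run(5e-5, 1.5e-5, seed = 5, n_frames = 30)
  a <- 1.7; b <- 120
  scaled <- lapply(r$sim$stack, function(f) a * f + b)
  ts2 <- extract_timeseries(scaled, r$masks, times = r$sim$times)
  prof2 <- normalize_profile(ts2)
  expect_equal(prof2$norm_I, r$prof$norm_I, tolerance = 1e-10)
  expect_equal(prof2$norm_sd, r$prof$norm_sd, tolerance = 1e-10)
})

test_that("pre-equilibrium frames are flagged excluded", {
  r <- quick_run(5e-5, 1.5e-5, seed = 2, n_frames = 60)
  eq <- attr(r$prof, "equilibrium_frame")
  expect_gt(eq, 1)
  expect_true(all(r$prof$excluded[seq_len(eq - 1)]))
  expect_false(any(r$prof$excluded[eq:nrow(r$prof)]))
  # the detected time is consistent with the 300 s fill constant
  expect_true(r$prof$time_s[eq] >= 600 && r$prof$time_s[eq] <= 1500)
})

test_that("profiles round-trip through CSV", {
  r <- quick_run(5e-5, 1.5e-5, seed = 8, n_frames = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(r$prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$norm_I, r$prof$norm_I, tolerance = 1e-12)
  expect_identical(attr(back, "equilibrium_frame"),
                   attr(r$prof, "equilibrium_frame"))
  f1 <- fit_permeability(r$prof, 0.045)
  f2 <- fit_permeability(back, 0.045)
  expect_equal(f2$p_total, f1$p_total, tolerance = 1e-9)
})
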