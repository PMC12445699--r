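test_that("magnet map is monotone with the expected limits", {
  m <- magnet_map()
  expect_equal(force_at_position(0, m), 30.5)
  d <- seq(0, 10, by = 0.1)
  expect_true(all(diff(force_at_position(d, m)) < 0))
  expect_equal(force_at_position(1e6, m), m$offset)
  expect_equal(force_at_position(position_at_force(8.6, m), m), 8.6,
               tolerance = 1e-9)
  expect_error(position_at_force(100, m), "outside achievable range")
})

test_that("ramp profile hits its endpoints with linear magnet motion", {
  ramp <- test_ramp()
  expect_equal(ramp$force_fn(0), 0.1, tolerance = 1e-6)
  expect_equal(ramp$force_fn(ramp$duration), 30, tolerance = 1e-6)
  # derived from the default map: ~6.43 mm of travel at 10 um/s
  expect_equal(ramp$duration, 643.155, tolerance = 1e-4)
  tt <- seq(0, ramp$duration, length.out = 200)
  expect_true(all(diff(ramp$force_fn(tt)) > 0))
  d <- ramp$position_fn(tt)
  expect_equal(max(abs(diff(d) + ramp$speed * diff(tt)[1])), 0,
               tolerance = 1e-12)
  expect_error(ramp_profile(f_start = 5, f_end = 1), "f_start")
})

test_that("transverse fluctuations satisfy equipartition statistics", {
  pp <- polymer_params()
  y <- simulate_transverse_fluctuations(5, 3200, seed = 4)
  expect_equal(stats::sd(y), sqrt(pp$thermal_energy * 3200 / 5),
               tolerance = 0.03)
  # corner frequency closed form: k/(2 pi gamma)
  bead <- bead_params()
  expect_equal(bead$drag, 2.6389e-5, tolerance = 1e-4)
  expect_equal((5 / 3200) / (2 * pi * bead$drag), 9.4235,
               tolerance = 1e-4)
  # stiff limit: variance shrinks
  y2 <- simulate_transverse_fluctuations(50, 100, seed = 4)
  expect_lt(stats::var(y2), stats::var(y) / 100)
})

test_that("equipartition estimator is exact on constructed variance", {
  pp <- polymer_params()
  set.seed(2)
  y <- stats::rnorm(5000)
  target_var <- pp$thermal_energy * 3200 / 5
  y <- y / stats::sd(y) * sqrt(target_var)
  expect_equal(equipartition_force_estimate(y, 3200, pp), 5,
               tolerance = 1e-9)
  expect_equal(equipartition_force_estimate(y, 6400, pp), 10,
               tolerance = 1e-9)
  expect_error(equipartition_force_estimate(rep(1, 10), 3200, pp),
               "zero variance")
})

test_that("PSD and equipartition force estimates agree with the truth", {
  pp <- polymer_params()
  ext5 <- ewlc_extension(5, 3380, pp)
  y <- simulate_transverse_fluctuations(5, ext5, seed = 6)
  psd <- psd_force_estimate(y, ext5)
  equi <- equipartition_force_estimate(y, ext5)
  expect_equal(psd$force, 5, tolerance = 0.10)
  expect_equal(equi, 5, tolerance = 0.10)
  expect_lt(abs(psd$force - equi) / 5, 0.10)
  expect_true(psd$ci[1] < 5 && psd$ci[2] > 5)
  # slow corner at low force still within 15%
  ext05 <- ewlc_extension(0.5, 3380, pp)
  y <- simulate_transverse_fluctuations(0.5, ext05, seed = 6)
  expect_equal(psd_force_estimate(y, ext05)$force, 0.5, tolerance = 0.15)
  expect_error(psd_force_estimate(stats::rnorm(100), 3380),
               "4096 samples")
})

test_that("magnet map fit recovers exact data and rejects sparse input", {
  truth <- magnet_map(amp1 = 24, amp2 = 3.1, decay1 = 0.42, decay2 = 1.7)
  d <- position_at_force(c(0.5, 1, 2, 4, 8, 14, 20, 26), truth)
  fit <- fit_magnet_map(d, force_at_position(d, truth))
  expect_lt(fit$rms, 1e-6)
  expect_equal(fit$fitted_map$amp1, 24, tolerance = 1e-4)
  expect_equal(fit$fitted_map$decay1, 0.42, tolerance = 1e-4)
  expect_error(fit_magnet_map(d[1:3], force_at_position(d[1:3], truth)),
               "at least 6")
})

test_that("end-to-end simulated calibration recovers the map within 5%", {
  cal <- simulate_force_calibration(n_molecules = 4, seed = 5)
  fr <- seq(0.5, 25, length.out = 15)
  d <- position_at_force(fr, magnet_map())
  rel <- force_at_position(d, cal$fitted_map) / fr - 1
  expect_lt(max(abs(rel)), 0.05)
})

test_that("drift correction removes shared drift and is idempotent", {
  set.seed(3)
  n <- 2000
  tt <- seq(0, 100, length.out = n)
  drift <- 0.5 * tt
  z <- 50 + drift + stats::rnorm(n, sd = 2)
  ref <- drift + stats::rnorm(n, sd = 2)
  zc <- apply_drift_correction(z, ref)
  slope <- stats::coef(stats::lm(zc ~ tt))[2]
  expect_lt(abs(slope), 0.01)
  # constant reference leaves input unchanged, so correction is idempotent
  expect_identical(apply_drift_correction(z, rep(7, n)), z)
  expect_error(apply_drift_correction(z, ref[-1]), "equal length")
})
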