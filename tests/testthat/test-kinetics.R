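test_that("Bell rate has the right limits and force sensitivity", {
  pp <- polymer_params()
  s <- transition_spec("outer", k0 = 0.01, dx = 1, released_bp = 62)
  expect_equal(bell_rate(0, s, pp), 0.01)
  s0 <- transition_spec("outer", k0 = 0.01, dx = 0, released_bp = 62)
  expect_equal(bell_rate(c(0, 10, 30), s0, pp), rep(0.01, 3))
  # with dx = 1 nm the rate doubles every kBT ln(2) = 2.835 pN
  df <- pp$thermal_energy * log(2)
  expect_equal(bell_rate(10 + df, s, pp) / bell_rate(10, s, pp), 2,
               tolerance = 1e-9)
  # overflow guard
  expect_true(is.finite(bell_rate(1e6, s, pp)))
})

test_that("survival rupture distribution matches closed forms", {
  ramp <- test_ramp()
  # immediate-rupture limit
  s_fast <- transition_spec("outer", k0 = 1e6, dx = 0, released_bp = 62)
  d <- survival_rupture_distribution(s_fast, ramp)
  expect_equal(d$mean, 0.1, tolerance = 0.01)
  # dx = 0: constant rate, rupture time ~ Exp(k); oracle by direct
  # quadrature of E[F(T) | T < duration]
  k <- 0.02
  s_const <- transition_spec("outer", k0 = k, dx = 0, released_bp = 62)
  d <- survival_rupture_distribution(s_const, ramp)
  tg <- seq(0, ramp$duration, by = 0.01)
  w <- k * exp(-k * tg)
  oracle <- sum(w * ramp$force_fn(tg)) / sum(w)
  expect_equal(d$mean, oracle, tolerance = 1e-3)
  # everything ruptures below the floor: no observable mass left
  expect_error(survival_rupture_distribution(
    transition_spec("outer", k0 = 1e6, dx = 0, released_bp = 1), ramp,
    min_force = 2), "never fires")
})

test_that("thinning draws match the survival integral and fine-grid Euler", {
  ramp <- test_ramp()
  pp <- polymer_params()
  s <- transition_spec("inner", k0 = 2e-6, dx = 2, released_bp = 85)
  d <- survival_rupture_distribution(s, ramp)
  set.seed(10)
  tdraw <- replicate(2000, nucpull:::rupture_time_thinning(s, ramp, pp))
  fdraw <- ramp$force_fn(tdraw[is.finite(tdraw)])
  mc_se <- stats::sd(fdraw) / sqrt(length(fdraw))
  expect_lt(abs(mean(fdraw) - d$mean), 3 * mc_se)
  ks1 <- stats::ks.test(fdraw, d$cdf)
  expect_gt(ks1$p.value, 0.01)
  # brute-force fine-grid Euler oracle on a fast ramp (same map, 100 um/s)
  fast <- ramp_profile(acquisition_config(ramp_speed = 100))
  tg <- seq(0, fast$duration, by = 1e-4)
  kg <- bell_rate(fast$force_fn(tg), s2 <- transition_spec(
    "inner", k0 = 2e-4, dx = 2, released_bp = 85), pp)
  lam <- cumsum(kg * 1e-4)
  set.seed(11)
  e <- stats::rexp(2000)
  t_euler <- tg[pmin(length(tg), findInterval(e, lam) + 1L)]
  f_euler <- fast$force_fn(t_euler[e < max(lam)])
  set.seed(12)
  t_thin <- replicate(2000, nucpull:::rupture_time_thinning(s2, fast, pp))
  f_thin <- fast$force_fn(t_thin[is.finite(t_thin)])
  # grid-valued Euler draws produce ties; the approximate p is fine here
  ks2 <- suppressWarnings(stats::ks.test(f_thin, f_euler))
  expect_gt(ks2$p.value, 0.01)
})

test_that("rate calibration reproduces target means and spreads", {
  ramp <- test_ramp()
  s <- calibrate_rates(22.9, ramp = ramp, released_bp = 85,
                       name = "inner")
  d <- survival_rupture_distribution(s, ramp)
  expect_equal(d$mean, 22.9, tolerance = 0.05 / 22.9)
  s2 <- calibrate_rates(11.3, 2.6, ramp = ramp, released_bp = 62)
  d2 <- survival_rupture_distribution(s2, ramp)
  expect_lt(abs(d2$mean - 11.3), 0.05)
  expect_lt(abs(d2$sd - 2.6), 0.05)
  s3 <- calibrate_rates(13.9, 3.1, ramp = ramp, released_bp = 147,
                        name = "cooperative")
  d3 <- survival_rupture_distribution(s3, ramp)
  expect_lt(abs(d3$sd - 3.1), 0.05)
  expect_error(calibrate_rates(22.9, 25, ramp = ramp),
               "feasible sd range")
  expect_error(calibrate_rates(80, ramp = ramp), "outside ramp")
})

test_that("conditional calibration matches the observable distribution", {
  ramp <- test_ramp()
  s <- calibrate_rates(6.6, ramp = ramp, released_bp = 62,
                       dx_default = 6, min_force = 2)
  d <- survival_rupture_distribution(s, ramp, min_force = 2)
  expect_equal(d$mean, 6.6, tolerance = 0.05 / 6.6)
  # unconditional mean sits slightly below the conditional target
  d0 <- survival_rupture_distribution(s, ramp)
  expect_lt(d0$mean, 6.6)
  expect_gt(d0$mean, 6.2)
})

test_that("calibrated presets report their provenance targets", {
  reg <- preset_registry()
  expect_setequal(
    names(reg),
    c("h3_nuc", "h33_nuc", "h33s31a_nuc", "h33s31e_nuc", "h33s31ph_nuc",
      "h3_fact", "h33_fact", "h33s31ph_fact", "h33s31ae_fact",
      "h3_tetra", "h33_tetra", "h3_depo", "h33_depo"))
  expect_error(get_preset("nope"), "unknown preset")
  p <- calibrate_preset("h33_tetra", test_ramp())
  expect_true(p$calibrated)
  d <- survival_rupture_distribution(p$transitions[[1]]$spec, test_ramp(),
                                     min_force = 2)
  expect_equal(d$mean, 22.5, tolerance = 0.01)
  # total released bp never exceeds a full nucleosome
  for (pr in reg) {
    expect_lte(sum(vapply(pr$transitions, function(tr) tr$released_bp, 0)),
               147)
  }
})
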