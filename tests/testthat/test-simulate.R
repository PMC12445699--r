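test_that("a silent preset produces the bare-tether eWLC curve", {
  ramp <- test_ramp()
  pp <- polymer_params()
  p <- manual_preset(k0 = 1e-28, dx = 0)
  set.seed(1)
  res <- simulate_cycle("wrapped", p, ramp, trace_rate = 5)
  expect_identical(nrow(res$events), 0L)
  expect_identical(res$end_state, "wrapped")
  tg <- res$trace$data$time_s
  handle <- (409 - 62) * pp$bp_rise
  clean <- vapply(ramp$force_fn(tg), function(f)
    ewlc_extension(f, handle, pp), 0)
  resid <- res$trace$data$ext_nm - clean
  expect_lt(abs(mean(resid)), 1)
  # lost molecules produce the naked-DNA curve instead
  set.seed(1)
  res2 <- simulate_cycle("lost", p, ramp, trace_rate = 5)
  clean2 <- vapply(ramp$force_fn(tg), function(f)
    ewlc_extension(f, 409 * pp$bp_rise, pp), 0)
  expect_lt(abs(mean(res2$trace$data$ext_nm - clean2)), 1)
  expect_gt(mean(res2$trace$data$ext_nm - res$trace$data$ext_nm), 5)
})

test_that("trace noise follows the force-dependent equipartition scale", {
  pp <- polymer_params()
  # constant-force hold with no event: sd(ext) = sqrt(kBT z / F)
  dp <- simulate_dephos(k_dephos = 0, seed = 9)
  expect_identical(nrow(dp$truth), 0L)
  z <- (409 - 147) * pp$bp_rise * ewlc_extension(8.6, 1, pp)
  expect_equal(stats::sd(dp$trace$data$ext_nm),
               sqrt(pp$thermal_energy * z / 8.6), tolerance = 0.05)
})

test_that("molecule state machine: maintenance and loss bookkeeping", {
  ramp <- test_ramp()
  p1 <- manual_preset(k0 = 1e-5, dx = 6, p_maintain = 1)
  mol <- simulate_molecule(p1, protocol_config(n_cycles = 3), ramp,
                           trace_rate = 2, seed = 21)
  expect_setequal(unique(mol$truth$cycle), 1:3)
  expect_identical(mol$states, rep("wrapped", 3))
  p0 <- manual_preset(k0 = 1e-5, dx = 6, p_maintain = 0)
  mol0 <- simulate_molecule(p0, protocol_config(n_cycles = 3), ramp,
                            trace_rate = 2, seed = 21)
  expect_identical(unique(mol0$truth$cycle), 1L)
  expect_identical(mol0$states[2:3], c("lost", "lost"))
})

test_that("reassembly probability is recovered at the binomial scale", {
  ramp <- test_ramp()
  p <- manual_preset(k0 = 1e-5, dx = 6, p_maintain = 0.9)
  ts <- simulate_experiment(p, 400, protocol_config(n_cycles = 2), ramp,
                            trace_rate = 2, seed = 31)
  frac2 <- length(unique(ts$truth$molecule_id[ts$truth$cycle == 2])) / 400
  expect_lt(abs(frac2 - 0.9), 3 * sqrt(0.9 * 0.1 / 400))
  # events per molecule are non-increasing across cycles
  tab <- table(factor(ts$truth$cycle, levels = 1:2))
  expect_gte(tab[[1]], tab[[2]])
})

test_that("trace sets are bit-reproducible under a master seed", {
  ramp <- test_ramp()
  p <- manual_preset(k0 = 1e-5, dx = 6)
  a <- simulate_experiment(p, 3, protocol_config(n_cycles = 2), ramp,
                           trace_rate = 2, seed = 77)
  b <- simulate_experiment(p, 3, protocol_config(n_cycles = 2), ramp,
                           trace_rate = 2, seed = 77)
  expect_identical(a$truth, b$truth)
  for (i in seq_along(a$traces))
    expect_identical(a$traces[[i]]$data, b$traces[[i]]$data)
  expect_error(simulate_experiment(p, 0, ramp = ramp), "at least 1")
})

test_that("full disruption releases exactly the wrapped bp total", {
  ramp <- test_ramp()
  p <- calibrate_preset("h33_nuc", ramp)
  set.seed(41)
  res <- simulate_cycle("wrapped", p, ramp, trace_rate = 2)
  if (nrow(res$events) == 2)
    expect_equal(sum(res$events$released_bp), 147)
  expect_true(all(diff(res$events$time) > 0))
})

test_that("dephosphorylation events follow the exponential clock", {
  pp <- polymer_params()
  # waiting times are Exp(k_dephos); rupture follows quickly at 8.6 pN
  td <- vapply(1:150, function(s) {
    dp <- simulate_dephos(k_dephos = 1 / 30, hold_time = 1e4,
                          sample_rate = 1, seed = s)
    dp$truth$t_dephos
  }, numeric(1))
  ks <- stats::ks.test(td, stats::pexp, rate = 1 / 30)
  expect_gt(ks$p.value, 0.01)
  # the jump released is the calibrated outer wrap: ~20 nm at 8.6 pN
  expect_equal(extension_jump(62, 8.6, pp), 20.03, tolerance = 1e-3)
})

test_that("deposition mixes nucleosome and tetrasome populations", {
  ramp <- test_ramp()
  proto <- protocol_config(n_cycles = 1)
  ts1 <- simulate_deposition("h33_depo", "h33_tetra", 1, 20, proto, ramp,
                             trace_rate = 2, seed = 5)
  expect_true(all(ts1$meta$assembled))
  counts <- table(ts1$truth$molecule_id)
  expect_true(all(counts == 2))  # every molecule two-step
  ts2 <- simulate_deposition("h33_depo", "h33_tetra", 0.608, 400, proto,
                             ramp, trace_rate = 2, seed = 6)
  n_ass <- sum(ts2$meta$assembled)
  expect_lt(abs(n_ass - 0.608 * 400), 3 * sqrt(0.608 * 0.392 * 400))
})
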