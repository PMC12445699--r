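test_that("an injected step is located and sized accurately", {
  cfg <- analysis_config()
  set.seed(8)
  tr <- step_trace(n = 4000, rate = 100, sigma = 3,
                   steps = data.frame(time = 20, size = 20))
  d <- detect_jumps(tr, cfg)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$time - 20), 0.1)
  expect_lt(abs(d$jump - 20), 1.5)
  expect_error(detect_jumps(step_trace(n = 50), cfg), "shorter than")
})

test_that("steps closer than the separation limit merge into one event", {
  cfg <- analysis_config()  # min_event_separation 0.5 s
  set.seed(9)
  tr <- step_trace(n = 4000, rate = 100, sigma = 3,
                   steps = data.frame(time = c(20, 20.2), size = c(20, 20)))
  d <- detect_jumps(tr, cfg)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$jump - 40), 4)
})

test_that("bare-tether traces yield no events (false-positive control)", {
  ramp <- test_ramp()
  p <- calibrate_preset("h33_nuc", ramp)
  cfg <- ramp_analysis_config(10)
  set.seed(55)
  n_fp <- 0
  for (i in 1:25) {
    res <- simulate_cycle("lost", p, ramp, trace_rate = 10)
    ev <- to_rupture_events(detect_jumps(res$trace, cfg), res$trace)
    n_fp <- n_fp + nrow(ev)
  }
  expect_lte(n_fp, 1)
})

test_that("detections convert to rupture events through the eWLC", {
  pp <- polymer_params()
  tr <- step_trace(n = 1000, rate = 100, sigma = 1, force = 8.6)
  det <- data.frame(time = c(5, 6, 7), jump = c(20, 28.4, 6),
                    local_sd = 1, zscore = 20)
  ev <- to_rupture_events(det, tr, params = pp)
  expect_identical(nrow(ev), 2L)  # the 6 nm jump is filtered out
  expect_equal(ev$released_bp[1], 62, tolerance = 0.01)
  tr23 <- step_trace(n = 1000, rate = 100, sigma = 1, force = 23)
  ev2 <- to_rupture_events(data.frame(time = 5, jump = 28.4,
                                      local_sd = 1, zscore = 20),
                           tr23, params = pp)
  expect_equal(ev2$released_bp, 85, tolerance = 0.01)
  # events below the force floor are dropped
  tr1 <- step_trace(n = 1000, rate = 100, sigma = 1, force = 1)
  ev3 <- to_rupture_events(data.frame(time = 5, jump = 20,
                                      local_sd = 1, zscore = 20), tr1)
  expect_identical(nrow(ev3), 0L)
})

test_that("cycle patterns classify outer/inner/full transitions", {
  cfg <- analysis_config()
  ev2 <- data.frame(molecule_id = "m", cycle = 1L, time = c(100, 500),
                    force = c(6.5, 23), jump = c(20, 28.4),
                    released_bp = c(62, 85), label = "unclassified")
  cl <- classify_events(ev2, cfg)
  expect_identical(cl$pattern, "two_step")
  expect_identical(cl$events$label, c("outer", "inner"))
  ev1 <- ev2[2, ]; ev1$released_bp <- 140
  expect_identical(classify_events(ev1, cfg)$pattern, "one_step_full")
  ev85 <- ev2[2, ]
  cl85 <- classify_events(ev85, cfg)
  expect_identical(cl85$pattern, "one_step")
  expect_identical(cl85$events$label, "inner")
  expect_identical(classify_events(ev2[0, ], cfg)$pattern, "none")
  # an outer-sized single event stays unclassified
  ev62 <- ev2[1, ]
  expect_identical(classify_events(ev62, cfg)$pattern, "none")
})

test_that("pipeline recovers events, labels and integrity on a known arm", {
  an <- simulate_and_analyze("h33_nuc", 25, seed = 1)
  truth_obs <- an$truth[an$truth$force >= 2, ]
  # recovery: nearly every observable ground-truth event is detected
  rec <- 0
  for (i in seq_len(nrow(truth_obs))) {
    sel <- an$events$molecule_id == truth_obs$molecule_id[i] &
      an$events$cycle == truth_obs$cycle[i]
    if (any(sel) && min(abs(an$events$time[sel] - truth_obs$time[i])) < 3)
      rec <- rec + 1
  }
  expect_gte(rec / nrow(truth_obs), 0.95)
  # labels agree with the transition windows
  ft <- rupture_force_table(an)
  expect_true(all(c("outer", "inner") %in% names(ft)))
  expect_lt(abs(mean(ft$outer) - 6.6), 0.35)
  expect_lt(abs(mean(ft$inner) - 22.9), 1.0)
  # pooling modes differ only through repeated cycles
  f1 <- rupture_force_table(an, "first_cycle")
  expect_lte(length(f1$outer), length(ft$outer))
})

test_that("maintenance proportions follow the preset reassembly rates", {
  an <- simulate_and_analyze("h33s31ph_fact", 25, seed = 2)
  mp <- maintenance_proportion(an, n_boot = 500, seed = 3)
  expect_equal(mp$proportion[1], 1)
  expect_lte(mp$proportion[2], 0.05)  # lost after the first pull
  an2 <- simulate_and_analyze("h33_tetra", 30, seed = 3)
  mp2 <- maintenance_proportion(an2, n_boot = 500, seed = 3)
  expect_lt(abs(mp2$proportion[2] - 0.9), 3 * sqrt(0.09 / 30) + 0.03)
  expect_true(all(mp2$ci_lo <= mp2$proportion &
                    mp2$proportion <= mp2$ci_hi))
})

test_that("deposition efficiency tracks the assembled fraction", {
  ramp <- test_ramp()
  proto <- protocol_config(n_cycles = 1)
  ts <- simulate_deposition("h33_depo", "h33_tetra", 0.6, 120, proto,
                            ramp, seed = 4)
  an <- analyze_traceset(ts)
  de <- deposition_efficiency(an, n_boot = 500, seed = 5)
  truth_frac <- mean(ts$meta$assembled)
  expect_lt(abs(de$efficiency - truth_frac), 0.05)
  expect_true(de$ci[1] < de$efficiency && de$efficiency < de$ci[2])
})

test_that("constant-force change-point detector finds the dephos jump", {
  cfg <- analysis_config()
  # no event
  set.seed(12)
  tr0 <- step_trace(n = 2000, rate = 100, sigma = 6,
                    steps = data.frame(time = numeric(), size = numeric()),
                    force = 8.6, constant_force = 8.6)
  expect_null(detect_constant_force_event(tr0, cfg))
  expect_error(detect_constant_force_event(step_trace(n = 500), cfg),
               "constant-force")
  # power at the force-dependent noise scale of the 8.6 pN hold
  set.seed(13)
  hits <- 0; jumps <- numeric()
  for (i in 1:100) {
    tr <- step_trace(n = 1000, rate = 100, sigma = 12.5,
                     steps = data.frame(time = 5, size = 20),
                     force = 8.6, constant_force = 8.6)
    ev <- detect_constant_force_event(tr, cfg)
    if (!is.null(ev)) { hits <- hits + 1; jumps <- c(jumps, ev$jump) }
  }
  expect_gte(hits / 100, 0.95)
  expect_lt(abs(stats::median(jumps) - 20), 1.5)
  # end-to-end on simulated dephosphorylation traces
  med <- stats::median(vapply(1:25, function(s) {
    dp <- simulate_dephos(seed = s, hold_time = 120)
    ev <- detect_constant_force_event(dp$trace, cfg)
    if (is.null(ev)) NA_real_ else ev$jump
  }, numeric(1)), na.rm = TRUE)
  expect_lt(abs(med - 20), 1.5)
})
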