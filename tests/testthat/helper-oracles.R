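# Independent oracles and small fixture builders used across test files.

# eWLC relative extension by plain bisection on the interpolation formula
# (independent of the package's vectorized Newton solver).
oracle_rel_ext <- function(force, params = polymer_params()) {
  if (force == 0) return(0)
  kBT <- params$thermal_energy
  Lp <- params$persistence_length
  S <- params$stretch_modulus
  g <- function(u) (kBT / Lp) * (1 / (4 * (1 - u)^2) - 0.25 + u) - force
  lo <- 0; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 + force / S
}

# Shared default ramp; presets are cached inside the package so repeated
# calibrate_preset() calls are cheap.
test_ramp <- local({
  r <- NULL
  function() {
    if (is.null(r)) r <<- ramp_profile()
    r
  }
})

# A preset with explicitly chosen Bell parameters, bypassing calibration.
manual_preset <- function(k0, dx, released_bp = 62, name = "outer",
                          p_maintain = 1, label = "manual") {
  tr <- list(name = name, released_bp = released_bp, target_mean = NA,
             target_sd = NULL, dx = dx,
             spec = transition_spec(name, k0 = k0, dx = dx,
                                    released_bp = released_bp))
  p <- condition_preset(label, list(tr), p_maintain = p_maintain)
  p$calibrated <- TRUE
  p
}

# Flat-baseline constant-force trace with optional injected steps.
step_trace <- function(n = 2000, rate = 100, sigma = 3, baseline = 100,
                       steps = data.frame(time = 10, size = 20),
                       force = 10, constant_force = NULL) {
  tt <- seq(0, by = 1 / rate, length.out = n)
  z <- rep(baseline, n)
  for (i in seq_len(nrow(steps)))
    z <- z + ifelse(tt >= steps$time[i], steps$size[i], 0)
  z <- z + stats::rnorm(n, sd = sigma)
  meta <- list(molecule_id = "t1", cycle = 1L, preset = "synthetic",
               trace_rate = rate, schema_version = "1.0")
  if (!is.null(constant_force)) meta$constant_force <- constant_force
  structure(list(data = data.frame(time_s = tt, magnet_mm = NA_real_,
                                   force_pN = rep(force, n), ext_nm = z),
                 meta = meta),
            class = "mt_trace")
}
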