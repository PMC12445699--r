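#' Magnet position to force map
#'
#' Double-exponential mapping between magnet distance `d` (mm above the
#' sample) and applied force:
#' `F(d) = amp1 exp(-d/decay1) + amp2 exp(-d/decay2) + offset`.
#' The default constants span 0.1-30 pN over a few mm of magnet travel.
#'
#' @param amp1,amp2 Amplitudes in pN (non-negative).
#' @param decay1,decay2 Decay lengths in mm (positive).
#' @param offset Additive offset in pN.
#' @return An object of class `magnet_map`.
#' @export
magnet_map <- function(amp1 = 28, amp2 = 2.5, decay1 = 0.35, decay2 = 2.0,
                       offset = 0) {
  stopifnot(amp1 >= 0, amp2 >= 0, decay1 > 0, decay2 > 0)
  if (amp1 + amp2 <= 0) stop("at least one amplitude must be positive")
  structure(
    list(amp1 = amp1, amp2 = amp2, decay1 = decay1, decay2 = decay2,
         offset = offset),
    class = "magnet_map"
  )
}

#' Force at a magnet position
#'
#' Evaluates the double-exponential magnet map; strictly decreasing in `d`
#' for positive amplitudes, clamped below at zero.
#'
#' @param d Magnet distance in mm (vectorized).
#' @param map A [magnet_map()] object.
#' @return Force in pN.
#' @export
force_at_position <- function(d, map = magnet_map()) {
  pmax(0, map$amp1 * exp(-d / map$decay1) +
         map$amp2 * exp(-d / map$decay2) + map$offset)
}

#' Magnet position producing a given force
#'
#' Inverse of [force_at_position()] by root bracketing on `[0, d_max]`.
#'
#' @param force Target force in pN (vectorized).
#' @param map A [magnet_map()] object.
#' @param d_max Largest magnet distance considered, in mm.
#' @return Magnet distance in mm.
#' @export
position_at_force <- function(force, map = magnet_map(), d_max = 100) {
  f0 <- force_at_position(0, map)
  finf <- force_at_position(d_max, map)
  vapply(force, function(f) {
    if (f > f0 || f < finf)
      stop(sprintf("force %g pN outside achievable range [%g, %g] pN",
                   f, finf, f0))
    stats::uniroot(function(d) force_at_position(d, map) - f,
                   lower = 0, upper = d_max, tol = 1e-12)$root
  }, numeric(1))
}

#' Bead parameters
#'
#' Superparamagnetic bead properties used for Brownian-fluctuation
#' simulation and force calibration. The default 1.4 um radius corresponds
#' to a 2.8 um M-280 bead. The Stokes drag
#' `gamma = 6 pi eta r` is derived on construction (pN s / nm), never
#' stored stale.
#'
#' @param radius Bead radius in um.
#' @param medium_viscosity Medium viscosity in Pa s.
#' @return An object of class `bead_params` with derived `drag`.
#' @export
bead_params <- function(radius = 1.4, medium_viscosity = 1e-3) {
  stopifnot(radius > 0, medium_viscosity > 0)
  # 6 pi eta r with eta in Pa s and r in um is in units of 1e-3 pN s / nm
  drag <- 6 * pi * medium_viscosity * radius * 1e-3
  structure(
    list(radius = radius, medium_viscosity = medium_viscosity, drag = drag),
    class = "bead_params"
  )
}

#' Acquisition settings
#'
#' @param sampling_rate Sampling frequency in Hz (500 for calibration
#'   recordings).
#' @param duration Recording duration in s (300 s, i.e. 5 min, for
#'   calibration).
#' @param ramp_speed Magnet translation speed in um/s during force ramps.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 500, duration = 300,
                               ramp_speed = 10) {
  stopifnot(sampling_rate > 0, duration > 0, ramp_speed > 0)
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         ramp_speed = ramp_speed),
    class = "acquisition_config"
  )
}

#' Force-ramp profile from magnet motion
#'
#' The magnets approach the sample at constant speed, so the magnet
#' distance is exactly linear in time, `d(t) = d_start - speed * t`, and
#' the force follows the magnet map. Returns the force-versus-time
#' function and total ramp duration for a ramp from `f_start` to `f_end`.
#'
#' @param acq An [acquisition_config()]; `ramp_speed` is used (um/s).
#' @param map A [magnet_map()] object.
#' @param f_start,f_end Ramp endpoint forces in pN, `f_start < f_end`.
#' @return An object of class `ramp_profile` with elements `force_fn(t)`,
#'   `position_fn(t)`, `duration` (s), `d_start`, `d_end` (mm), and
#'   `speed` (mm/s).
#' @export
ramp_profile <- function(acq = acquisition_config(), map = magnet_map(),
                         f_start = 0.1, f_end = 30) {
  if (f_start >= f_end) stop("f_start must be below f_end")
  d_start <- position_at_force(f_start, map)
  d_end <- position_at_force(f_end, map)
  speed <- acq$ramp_speed / 1000  # um/s -> mm/s
  duration <- (d_start - d_end) / speed
  force_fn <- function(t) force_at_position(d_start - speed * t, map)
  position_fn <- function(t) d_start - speed * t
  structure(
    list(force_fn = force_fn, position_fn = position_fn, duration = duration,
         d_start = d_start, d_end = d_end, speed = speed,
         f_start = f_start, f_end = f_end, map = map),
    class = "ramp_profile"
  )
}

#' Simulate transverse bead fluctuations
#'
#' Exact discrete-time Ornstein-Uhlenbeck simulation of the transverse
#' (pendulum) coordinate of a tethered bead: stiffness `k = F / extension`,
#' drag from the bead, stationary variance `kBT / k`, relaxation time
#' `gamma / k`. The update `y[i+1] = a y[i] + s eps` with
#' `a = exp(-dt k / gamma)` and `s^2 = (kBT/k)(1 - a^2)` is exact at any
#' time step, so no discretization error enters the calibration loop.
#'
#' @param force Applied force in pN (> 0).
#' @param tether_extension Tether extension in nm (> 0).
#' @param bead A [bead_params()] object.
#' @param acq An [acquisition_config()]; `sampling_rate` and `duration` set
#'   the series length.
#' @param params A [polymer_params()] (thermal energy).
#' @param seed Optional integer seed.
#' @return Numeric vector of transverse positions in nm.
#' @export
simulate_transverse_fluctuations <- function(force, tether_extension,
                                             bead = bead_params(),
                                             acq = acquisition_config(),
                                             params = polymer_params(),
                                             seed = NULL) {
  stopifnot(force > 0, tether_extension > 0)
  if (!is.null(seed)) set.seed(seed)
  k <- force / tether_extension           # pN / nm
  n <- round(acq$sampling_rate * acq$duration)
  dt <- 1 / acq$sampling_rate
  a <- exp(-dt * k / bead$drag)
  s2 <- (params$thermal_energy / k) * (1 - a^2)
  innov <- stats::rnorm(n, sd = sqrt(s2))
  innov[1] <- stats::rnorm(1, sd = sqrt(params$thermal_energy / k))
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# Welch power spectral density: Hann window, n_segments segments with 50%
# overlap, one-sided, density normalized so that sum(S) * df = var(y).
welch_psd <- function(y, fs, n_segments = 8, overlap = 0.5) {
  n <- length(y)
  seg <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  step <- floor(seg * (1 - overlap))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))  # Hann
  u <- sum(w^2)
  starts <- seq(1, n - seg + 1, by = step)
  acc <- 0
  for (s in starts) {
    x <- y[s:(s + seg - 1)]
    x <- (x - mean(x)) * w
    p <- abs(stats::fft(x))^2
    acc <- acc + p
  }
  acc <- acc / length(starts)
  nf <- floor(seg / 2)
  f <- (1:nf) * fs / seg
  # one-sided density, per Hz
  S <- 2 * acc[2:(nf + 1)] / (fs * u)
  list(freq = f, psd = S)
}

#' Power-spectral-density force estimate
#'
#' Estimates the applied force from the transverse fluctuation spectrum of
#' the bead. The spectrum of the overdamped tethered bead is Lorentzian,
#' `S(f) = kBT / (pi^2 gamma (fc^2 + f^2))` with corner frequency
#' `fc = k / (2 pi gamma)`, so the force follows from
#' `F = 2 pi gamma fc * extension`. Sampling folds the Lorentzian tail
#' back into the recorded band, so the fit uses the exact aliased form of
#' the sampled process (the AR(1) spectrum
#' `S(f) = A / (1 - 2 a cos(2 pi f dt) + a^2)` with
#' `a = exp(-2 pi fc dt)`); fitting the continuous Lorentzian instead
#' overestimates the corner by ~20% at a 500 Hz sampling rate. The Welch
#' spectrum (8 segments, 50% overlap, Hann window) is fitted in log space
#' over `[4/duration, 0.8 * Nyquist]`; the confidence interval derives
#' from the covariance of the fitted log corner frequency. If the fitted
#' corner falls outside the fitted band a warning is raised and the
#' [equipartition_force_estimate()] is returned instead.
#'
#' @param y Transverse position series in nm (>= 4096 samples).
#' @param tether_extension Tether extension in nm.
#' @param bead A [bead_params()] object.
#' @param acq An [acquisition_config()] (sampling rate, duration).
#' @param params A [polymer_params()].
#' @return A list with `force` (pN), `ci` (95% interval), `corner_freq`
#'   (Hz), `stiffness` (pN/nm), and `method` ("psd" or "equipartition").
#' @export
psd_force_estimate <- function(y, tether_extension, bead = bead_params(),
                               acq = acquisition_config(),
                               params = polymer_params()) {
  if (length(y) < 4096) stop("series must contain at least 4096 samples")
  fs <- acq$sampling_rate
  duration <- length(y) / fs
  sp <- welch_psd(y, fs)
  f_min <- 4 / duration
  f_max <- 0.8 * fs / 2
  sel <- sp$freq >= f_min & sp$freq <= f_max
  f <- sp$freq[sel]
  S <- sp$psd[sel]
  dt <- 1 / fs
  df <- data.frame(lS = log(S), f = f)
  # crude corner guess from where the spectrum falls to half its
  # low-frequency plateau
  plateau <- stats::median(S[seq_len(max(3, floor(sum(sel) / 50)))])
  fc0 <- f[which.min(abs(S - plateau / 2))]
  fit <- try(minpack.lm::nlsLM(
    lS ~ lA - log(1 - 2 * exp(-2 * pi * exp(lfc) * dt) *
                    cos(2 * pi * f * dt) + exp(-4 * pi * exp(lfc) * dt)),
    data = df,
    start = list(lA = log(plateau * (1 - exp(-2 * pi * fc0 * dt))^2),
                 lfc = log(fc0)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  equi <- equipartition_force_estimate(y, tether_extension, params)
  if (inherits(fit, "try-error")) {
    warning("Lorentzian fit failed; falling back to equipartition estimate")
    return(list(force = equi, ci = c(NA_real_, NA_real_),
                corner_freq = NA_real_, stiffness = equi / tether_extension,
                method = "equipartition"))
  }
  co <- stats::coef(fit)
  fc <- exp(co[["lfc"]])
  if (fc < f_min || fc > f_max) {
    warning(sprintf(
      "fitted corner frequency %.3g Hz outside band [%.3g, %.3g]; %s",
      fc, f_min, f_max, "falling back to equipartition estimate"))
    return(list(force = equi, ci = c(NA_real_, NA_real_), corner_freq = fc,
                stiffness = equi / tether_extension,
                method = "equipartition"))
  }
  Fhat <- 2 * pi * bead$drag * fc * tether_extension
  se_lfc <- sqrt(stats::vcov(fit)[["lfc", "lfc"]])
  ci <- Fhat * exp(c(-1, 1) * 1.96 * se_lfc)
  list(force = Fhat, ci = ci, corner_freq = fc,
       stiffness = 2 * pi * bead$drag * fc, method = "psd")
}

#' Equipartition force estimate
#'
#' `F = kBT * extension / var(y)`: the transverse stiffness of a tethered
#' bead is `F / extension`, and equipartition fixes the stationary
#' variance at `kBT / k`. Serves as an independent cross-check of the
#' spectral estimate.
#'
#' @param y Transverse position series in nm.
#' @param tether_extension Tether extension in nm.
#' @param params A [polymer_params()].
#' @return Force estimate in pN.
#' @export
equipartition_force_estimate <- function(y, tether_extension,
                                         params = polymer_params()) {
  v <- stats::var(y)
  if (v == 0) stop("series has zero variance")
  params$thermal_energy * tether_extension / v
}

#' Fit the magnet map to per-position force estimates
#'
#' Nonlinear least squares of the double-exponential magnet map to
#' calibrated (position, force) pairs, e.g. PSD estimates averaged over
#' independent molecules at each magnet position.
#'
#' @param positions Magnet positions in mm (>= 6 distinct values).
#' @param force_estimates Estimated forces in pN, same length.
#' @param start Optional [magnet_map()] used as starting values.
#' @return An object of class `calibration_result`: `fitted_map`,
#'   `residuals`, `rms` (pN), and the input table `estimates`.
#' @export
fit_magnet_map <- function(positions, force_estimates, start = magnet_map()) {
  if (length(positions) != length(force_estimates))
    stop("positions and force_estimates must have equal length")
  if (length(unique(positions)) < 6)
    stop("need at least 6 distinct magnet positions spanning the force range")
  df <- data.frame(d = positions, f = force_estimates)
  fit <- minpack.lm::nlsLM(
    f ~ exp(la1) * exp(-d / exp(ld1)) + exp(la2) * exp(-d / exp(ld2)),
    data = df,
    start = list(la1 = log(start$amp1), ld1 = log(start$decay1),
                 la2 = log(start$amp2), ld2 = log(start$decay2)),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!fit$convInfo$isConv) stop("magnet map fit did not converge")
  co <- exp(stats::coef(fit))
  # order components so decay1 is the short decay
  if (co[["ld1"]] > co[["ld2"]])
    co <- co[c("la2", "ld2", "la1", "ld1")]
  fitted_map <- magnet_map(amp1 = unname(co[1]), decay1 = unname(co[2]),
                           amp2 = unname(co[3]), decay2 = unname(co[4]),
                           offset = 0)
  res <- df$f - force_at_position(df$d, fitted_map)
  structure(
    list(fitted_map = fitted_map, residuals = res,
         rms = sqrt(mean(res^2)), estimates = df),
    class = "calibration_result"
  )
}

#' Simulate a full force-calibration experiment
#'
#' Emulates the bench procedure: a long DNA tether (10 000 bp by default)
#' is held at a series of magnet positions; at each position, transverse
#' fluctuations of `n_molecules` independent beads are recorded (500 Hz,
#' 5 min by default) and converted to force estimates by PSD analysis;
#' the double-exponential magnet map is then fitted to the per-position
#' mean estimates. The tether extension entering the stiffness model is
#' computed from the eWLC at the true force, as in the mechanics module.
#'
#' @param true_map The [magnet_map()] generating the data.
#' @param target_forces Forces (pN) defining the sampled magnet positions.
#' @param n_molecules Independent molecules per position.
#' @param tether_bp Calibration tether length in bp.
#' @param bead,acq,params Instrument and polymer settings.
#' @param seed Integer seed.
#' @return A `calibration_result` (see [fit_magnet_map()]) with an extra
#'   `per_position` table of per-position mean estimates and their s.e.
#' @export
simulate_force_calibration <- function(true_map = magnet_map(),
                                       target_forces = c(0.5, 1, 2, 3.5, 5,
                                                         8, 12, 16, 20, 25),
                                       n_molecules = 10,
                                       tether_bp = 10000,
                                       bead = bead_params(),
                                       acq = acquisition_config(),
                                       params = polymer_params(),
                                       seed = 1) {
  set.seed(seed)
  contour <- tether_bp * params$bp_rise
  positions <- position_at_force(target_forces, true_map)
  est <- matrix(NA_real_, nrow = length(positions), ncol = n_molecules)
  for (i in seq_along(positions)) {
    f_true <- force_at_position(positions[i], true_map)
    ext <- ewlc_extension(f_true, contour, params)
    for (j in seq_len(n_molecules)) {
      y <- simulate_transverse_fluctuations(f_true, ext, bead, acq, params)
      est[i, j] <- psd_force_estimate(y, ext, bead, acq, params)$force
    }
  }
  per_position <- data.frame(
    position = positions,
    force_true = force_at_position(positions, true_map),
    force_est = rowMeans(est),
    se = apply(est, 1, stats::sd) / sqrt(n_molecules)
  )
  out <- fit_magnet_map(per_position$position, per_position$force_est)
  out$per_position <- per_position
  out
}

#' Reference-bead drift correction
#'
#' Subtracts the drift tracked on a surface-attached reference bead from
#' the measurement channel: `z_corr(t) = z(t) - (ref(t) - median(ref))`.
#' Centering on the reference median makes the correction zero-median, so
#' a constant reference leaves the input unchanged and the correction is
#' idempotent for constant references. A step artifact present only in
#' the reference channel propagates as an inverted step (flagged by
#' downstream QC, not silently removed).
#'
#' @param z Measurement z-position series in nm.
#' @param ref Reference bead z-position series in nm, same length and time
#'   base.
#' @return Corrected series in nm.
#' @export
apply_drift_correction <- function(z, ref) {
  if (length(z) != length(ref))
    stop("z and ref must have equal length (shared time base)")
  z - (ref - stats::median(ref))
}

#' @export
print.magnet_map <- function(x, ...) {
  cat(sprintf(
    "Magnet map: F(d) = %g exp(-d/%g) + %g exp(-d/%g) + %g pN (d in mm)\n",
    x$amp1, x$decay1, x$amp2, x$decay2, x$offset))
  invisible(x)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Force calibration fit\n")
  print(x$fitted_map)
  cat(sprintf("  residual RMS: %.4g pN over %d positions\n",
              x$rms, nrow(x$estimates)))
  invisible(x)
}
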