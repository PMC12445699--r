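#' Trace-analysis settings
#'
#' Tunable parameters of the jump-detection and classification pipeline.
#' Detection operates in the time domain against a locally smoothed
#' baseline: a median filter of half-width `smoothing_halfwidth` samples,
#' a paired-window mean contrast, and a robust local noise estimate. An
#' event is accepted when the contrast exceeds both `min_jump` and
#' `noise_z_threshold` standard errors of the paired-window contrast.
#' Basepair classification windows derive from the calibrated 62/85 bp
#' outer/inner split with noise-propagated slack; the \[65, 75\] overlap
#' is resolved by temporal order (first event in a two-event cycle is
#' outer).
#'
#' `min_event_separation` should be at least the paired-window span
#' (`2 * smoothing_halfwidth / sample rate`) so that one rupture is never
#' reported twice; see [ramp_analysis_config()].
#'
#' @param smoothing_halfwidth Paired-window half-width in samples.
#' @param min_jump Minimum accepted jump in nm.
#' @param noise_z_threshold Acceptance threshold in multiples of the
#'   contrast standard error.
#' @param min_event_separation Events closer than this (s) are merged,
#'   keeping the largest.
#' @param outer_bp_window,inner_bp_window Inclusive bp windows for
#'   outer/inner labels.
#' @param full_bp_threshold bp at or above which a single event is a full
#'   (cooperative) disruption.
#' @param min_force_for_event Events below this force (pN) are dropped.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(smoothing_halfwidth = 25, min_jump = 8,
                            noise_z_threshold = 4,
                            min_event_separation = 0.5,
                            outer_bp_window = c(40, 75),
                            inner_bp_window = c(65, 110),
                            full_bp_threshold = 120,
                            min_force_for_event = 2) {
  stopifnot(smoothing_halfwidth >= 2, min_jump > 0, noise_z_threshold > 0,
            min_event_separation >= 0,
            length(outer_bp_window) == 2, diff(outer_bp_window) > 0,
            length(inner_bp_window) == 2, diff(inner_bp_window) > 0)
  structure(
    list(smoothing_halfwidth = as.integer(smoothing_halfwidth),
         min_jump = min_jump, noise_z_threshold = noise_z_threshold,
         min_event_separation = min_event_separation,
         outer_bp_window = outer_bp_window,
         inner_bp_window = inner_bp_window,
         full_bp_threshold = full_bp_threshold,
         min_force_for_event = min_force_for_event),
    class = "analysis_config"
  )
}

#' Analysis settings matched to a ramp-trace sampling rate
#'
#' Convenience wrapper around [analysis_config()] that sets the merge
#' radius to the paired-window span so a single rupture cannot be
#' double-counted at any sampling rate.
#'
#' @param sample_rate Trace sampling rate in Hz.
#' @param smoothing_halfwidth Half-width in samples.
#' @param ... Further arguments to [analysis_config()].
#' @return An `analysis_config`.
#' @export
ramp_analysis_config <- function(sample_rate, smoothing_halfwidth = 25,
                                 ...) {
  analysis_config(
    smoothing_halfwidth = smoothing_halfwidth,
    min_event_separation = 2 * smoothing_halfwidth / sample_rate, ...)
}

# Robust, slope-insensitive local noise sd: running median of |first
# differences| scaled to the sd of the underlying white noise.
local_noise_sd <- function(x, halfwidth) {
  k <- 2 * (2 * halfwidth) + 1
  k <- min(k, if (length(x) %% 2 == 0) length(x) - 1 else length(x))
  if (k %% 2 == 0) k <- k - 1
  d <- abs(diff(x))
  s <- stats::runmed(d, k, endrule = "median") * 1.4826 / sqrt(2)
  c(s[1], s)  # align to x
}

#' Detect extension jumps on a ramp trace
#'
#' Change-point style step detection against a locally smoothed baseline:
#' the extension is passed through a short (5-sample) median filter to
#' suppress single-sample spikes, then the paired-window contrast
#' `delta(t) = mean(z[t+1, t+w]) - mean(z[t-w, t])` with
#' `w = smoothing_halfwidth` is computed at every sample (the matched
#' filter for a step in white noise; a wide median prefilter would smear
#' the step response and halve the contrast, so the spike filter is kept
#' deliberately short); samples where `delta` exceeds both `min_jump` and
#' `noise_z_threshold` standard errors of the contrast (from a robust
#' local noise estimate) are grouped into contiguous candidate runs; the
#' contrast maximum of each run is kept, and surviving candidates closer
#' than `min_event_separation` are merged keeping the largest. The jump
#' size is re-measured on the raw trace as the post-window mean minus the
#' pre-window mean.
#'
#' @param trace An `mt_trace` (drift-corrected, time-ordered samples).
#' @param config An [analysis_config()].
#' @return Data frame with columns `time`, `jump` (nm), `local_sd` (nm)
#'   and `zscore`; zero rows when nothing is detected.
#' @export
detect_jumps <- function(trace, config = analysis_config()) {
  z <- trace$data$ext_nm
  tt <- trace$data$time_s
  w <- config$smoothing_halfwidth
  n <- length(z)
  if (n < 4 * w) stop("trace shorter than 4 x smoothing_halfwidth")
  zm <- stats::runmed(z, 5, endrule = "median")
  cs <- cumsum(zm)
  idx <- (w + 1):(n - w)
  fwd <- (cs[idx + w] - cs[idx]) / w
  bwd <- (cs[idx] - cs[idx - w]) / w
  delta <- fwd - bwd
  sig <- local_noise_sd(z, w)[idx]
  se <- sig * sqrt(2 / w)
  zsc <- delta / se
  ok <- delta > config$min_jump & zsc > config$noise_z_threshold
  if (!any(ok)) {
    return(data.frame(time = numeric(), jump = numeric(),
                      local_sd = numeric(), zscore = numeric()))
  }
  # contiguous runs of accepted samples -> one candidate per run
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- integer(0)
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    cand <- c(cand, seg[which.max(delta[seg])])
  }
  # merge candidates closer than min_event_separation, keep largest
  cand <- cand[order(tt[idx][cand])]
  keep <- rep(TRUE, length(cand))
  if (length(cand) > 1) {
    i <- 1
    while (i < length(cand)) {
      j <- i + 1
      while (j <= length(cand) &&
             tt[idx][cand[j]] - tt[idx][cand[i]] <
               config$min_event_separation) {
        if (delta[cand[j]] > delta[cand[i]]) {
          keep[i] <- FALSE; i <- j
        } else keep[j] <- FALSE
        j <- j + 1
      }
      i <- j
    }
    cand <- cand[keep]
  }
  pos <- idx[cand]
  # re-measure size on the raw trace, excluding the sample at the edge.
  # Windows are extended up to 3w where the spacing to neighbouring
  # events permits: the longer average reduces the size (and hence
  # released-bp) estimation noise without affecting detection
  # resolution. The acceptance rule is applied to the re-measured jump
  # as well: the median-filtered contrast and the raw paired-window mean
  # are distinct statistics, and demanding both clear the threshold
  # suppresses marginal noise flukes without touching well-resolved
  # ruptures.
  jump <- vapply(seq_along(pos), function(i) {
    p <- pos[i]
    lo <- if (i == 1) 1 else pos[i - 1] + 2
    hi <- if (i == length(pos)) n else pos[i + 1] - 1
    mean(z[(p + 2):min(p + 1 + 3 * w, hi)]) -
      mean(z[max(p - 3 * w, lo):(p - 1)])
  }, numeric(1))
  ok2 <- jump > config$min_jump &
    jump / (sig[cand] * sqrt(2 / w)) > config$noise_z_threshold
  data.frame(time = tt[pos], jump = jump, local_sd = sig[cand],
             zscore = zsc[cand])[ok2, , drop = FALSE]
}

#' Convert detections to rupture events
#'
#' Attaches the force at each detection time from the trace's force
#' channel, converts jump sizes to released basepairs through the eWLC,
#' and drops events below the minimum analyzable force.
#'
#' @param detections Output of [detect_jumps()].
#' @param trace The `mt_trace` the detections came from.
#' @param geometry A [tether_geometry()].
#' @param params A [polymer_params()].
#' @param config An [analysis_config()].
#' @return Data frame of rupture events: `molecule_id`, `cycle`, `time`,
#'   `force` (pN), `jump` (nm), `released_bp`, `label` (filled by
#'   [classify_events()], initialized `"unclassified"`).
#' @export
to_rupture_events <- function(detections, trace,
                              geometry = tether_geometry(),
                              params = polymer_params(),
                              config = analysis_config()) {
  if (nrow(detections) == 0) return(empty_events())
  force <- stats::approx(trace$data$time_s, trace$data$force_pN,
                         xout = detections$time, rule = 2)$y
  keep <- force >= config$min_force_for_event &
    detections$jump >= config$min_jump
  detections <- detections[keep, , drop = FALSE]
  force <- force[keep]
  if (nrow(detections) == 0) return(empty_events())
  data.frame(
    molecule_id = trace$meta$molecule_id,
    cycle = as.integer(trace$meta$cycle),
    time = detections$time, force = force, jump = detections$jump,
    released_bp = released_bp_from_jump(detections$jump, force, params),
    label = "unclassified", stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(molecule_id = character(), cycle = integer(),
             time = numeric(), force = numeric(), jump = numeric(),
             released_bp = numeric(), label = character(),
             stringsAsFactors = FALSE)
}

in_window <- function(x, w) x >= w[1] & x <= w[2]

#' Classify the events of one stretching cycle
#'
#' Labels time-ordered events of a single cycle and assigns the cycle
#' pattern:
#' * exactly two events with released bp in the outer and inner windows
#'   respectively and increasing force: labels `(outer, inner)`, pattern
#'   `"two_step"`;
#' * a single event at or above the full-disruption threshold: label
#'   `"full"`, pattern `"one_step_full"`;
#' * a single event within the inner window: label `"inner"`, pattern
#'   `"one_step"` (tetrasome-style);
#' * otherwise events stay `"unclassified"`; the pattern is `"none"`
#'   unless at least one event was classified.
#'
#' @param events Event data frame for one molecule-cycle (time-ordered).
#' @param config An [analysis_config()].
#' @return List with `events` (labels filled) and `pattern`.
#' @export
classify_events <- function(events, config = analysis_config()) {
  n <- nrow(events)
  if (n == 0) return(list(events = events, pattern = "none"))
  if (is.unsorted(events$time)) events <- events[order(events$time), ]
  bp <- events$released_bp
  if (n == 2 && in_window(bp[1], config$outer_bp_window) &&
      in_window(bp[2], config$inner_bp_window) &&
      events$force[2] > events$force[1]) {
    events$label <- c("outer", "inner")
    return(list(events = events, pattern = "two_step"))
  }
  if (n == 1 && bp >= config$full_bp_threshold) {
    events$label <- "full"
    return(list(events = events, pattern = "one_step_full"))
  }
  if (n == 1 && in_window(bp, config$inner_bp_window)) {
    events$label <- "inner"
    return(list(events = events, pattern = "one_step"))
  }
  list(events = events, pattern = "none")
}

#' Analyze the stretching cycles of one molecule
#'
#' Runs detection, conversion and classification on each cycle trace of a
#' molecule.
#'
#' @param traces List of `mt_trace` objects for one molecule (one per
#'   cycle).
#' @param geometry,params,config Pipeline settings.
#' @return List with `events` (all labeled events) and `molecule` (one-row
#'   data frame: `molecule_id`, `pattern_cycle1..k`, `maintained_cycle1..k`).
#' @export
analyze_molecule_traces <- function(traces, geometry = tether_geometry(),
                                    params = polymer_params(),
                                    config = analysis_config()) {
  evs <- list()
  patterns <- character(length(traces))
  for (i in seq_along(traces)) {
    det <- detect_jumps(traces[[i]], config)
    ev <- to_rupture_events(det, traces[[i]], geometry, params, config)
    cl <- classify_events(ev, config)
    evs[[i]] <- cl$events
    patterns[i] <- cl$pattern
  }
  events <- do.call(rbind, evs)
  cycles <- vapply(traces, function(tr) tr$meta$cycle, 1L)
  mol <- data.frame(molecule_id = traces[[1]]$meta$molecule_id,
                    stringsAsFactors = FALSE)
  for (i in order(cycles)) {
    mol[[paste0("pattern_cycle", cycles[i])]] <- patterns[i]
    mol[[paste0("maintained_cycle", cycles[i])]] <- patterns[i] != "none"
  }
  list(events = events, molecule = mol)
}

#' Analyze a trace set
#'
#' Applies the detection-classification pipeline to every molecule of a
#' trace set.
#'
#' @param traceset An `mt_traceset` (see [simulate_experiment()] or
#'   [read_traceset()]).
#' @param geometry,params,config Pipeline settings.
#' @return An object of class `mt_analysis`: `events` (labeled event
#'   table), `molecules` (per-molecule cycle patterns), `n_cycles`, and
#'   `meta` echoed from the trace set.
#' @export
analyze_traceset <- function(traceset, geometry = tether_geometry(),
                             params = polymer_params(),
                             config = NULL) {
  if (is.null(config))
    config <- ramp_analysis_config(traceset$meta$trace_rate)
  ids <- vapply(traceset$traces, function(tr) tr$meta$molecule_id, "")
  out_ev <- list(); out_mol <- list()
  for (id in unique(ids)) {
    res <- analyze_molecule_traces(traceset$traces[ids == id], geometry,
                                   params, config)
    out_ev[[id]] <- res$events
    out_mol[[id]] <- res$molecule
  }
  structure(
    list(events = do.call(rbind, c(out_ev, list(empty_events()))),
         molecules = do.call(rbind, out_mol),
         n_cycles = traceset$meta$n_cycles,
         meta = traceset$meta, config = config),
    class = "mt_analysis"
  )
}

#' @export
print.mt_analysis <- function(x, ...) {
  cat(sprintf("Analysis of '%s': %d molecules, %d events\n",
              x$meta$preset, nrow(x$molecules), nrow(x$events)))
  invisible(x)
}

#' Rupture-force samples by label
#'
#' Extracts detected rupture forces keyed by event label, pooling either
#' all cycles or the first cycle only (whether published rupture
#' statistics pool repeated cycles is generally unstated, so both modes
#' are first-class).
#'
#' @param analysis An `mt_analysis`.
#' @param pooling `"all_cycles"` or `"first_cycle"`.
#' @param labels Labels to extract (default all present).
#' @return Named list of numeric force vectors; attribute `n` gives the
#'   per-label counts.
#' @export
rupture_force_table <- function(analysis,
                                pooling = c("all_cycles", "first_cycle"),
                                labels = NULL) {
  pooling <- match.arg(pooling)
  ev <- analysis$events
  if (pooling == "first_cycle") ev <- ev[ev$cycle == 1L, , drop = FALSE]
  if (is.null(labels)) labels <- setdiff(unique(ev$label), "unclassified")
  out <- lapply(labels, function(l) ev$force[ev$label == l])
  names(out) <- labels
  attr(out, "n") <- vapply(out, length, 0L)
  out
}

#' Proportion of molecules maintained across cycles
#'
#' The fraction of molecules whose unfolding pattern persists in each
#' cycle, among molecules that showed a cycle-1 pattern (the denominator
#' convention is explicit because published proportions rarely state
#' one). A seeded percentile bootstrap over molecules gives the 95%
#' confidence interval.
#'
#' @param analysis An `mt_analysis`.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return Data frame with `cycle`, `proportion`, `ci_lo`, `ci_hi`, `n`.
#' @export
maintenance_proportion <- function(analysis, n_boot = 2000, seed = 1) {
  mol <- analysis$molecules
  k <- analysis$n_cycles
  denom <- mol$maintained_cycle1
  if (!any(denom)) stop("no molecule shows a cycle-1 pattern")
  m <- mol[denom, , drop = FALSE]
  cols <- paste0("maintained_cycle", seq_len(k))
  props <- vapply(cols, function(cn) mean(m[[cn]]), 0)
  set.seed(seed)
  nb <- nrow(m)
  boot <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nb, nb, replace = TRUE)
    boot[b, ] <- vapply(cols, function(cn) mean(m[[cn]][idx]), 0)
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  data.frame(cycle = seq_len(k), proportion = unname(props),
             ci_lo = ci[1, ], ci_hi = ci[2, ], n = nb)
}

#' Deposition efficiency
#'
#' Fraction of molecules classified `two_step` in cycle 1 (assembled
#' nucleosomes) among all molecules with at least one cycle-1 event, with
#' a seeded percentile bootstrap CI.
#'
#' @param analysis An `mt_analysis` of a deposition assay.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `efficiency`, `ci` (95%), `n_assembled`, `n_total`.
#' @export
deposition_efficiency <- function(analysis, n_boot = 2000, seed = 1) {
  mol <- analysis$molecules
  has_event <- mol$maintained_cycle1
  two <- mol$pattern_cycle1 == "two_step" & has_event
  n_total <- sum(has_event)
  if (n_total == 0) return(list(efficiency = NA_real_,
                                ci = c(NA_real_, NA_real_),
                                n_assembled = 0L, n_total = 0L))
  x <- two[has_event]
  ci <- bootstrap_ci(mean, x, B = n_boot, seed = seed)
  list(efficiency = mean(x), ci = ci, n_assembled = sum(x),
       n_total = n_total)
}

#' Detect a single change point on a constant-force trace
#'
#' Scans every split point of the constant-force segment and maximizes
#' the two-sided mean-contrast statistic
#' `|mean(after) - mean(before)| / (sigma sqrt(1/n1 + 1/n2))`. The change
#' point is accepted if the contrast exceeds `min_jump` and the z-score
#' exceeds `noise_z_threshold`. If several well-separated split points
#' would be accepted, the largest is returned and the trace is flagged
#' for review.
#'
#' @param trace A constant-force `mt_trace` (meta field `constant_force`
#'   identifies the segment).
#' @param config An [analysis_config()].
#' @param min_margin Number of samples excluded at both ends.
#' @return `NULL` if nothing is accepted; otherwise a list with `time`,
#'   `jump` (nm), `zscore`, and `flagged` (logical).
#' @export
detect_constant_force_event <- function(trace, config = analysis_config(),
                                        min_margin = 10) {
  if (is.null(trace$meta$constant_force))
    stop("trace metadata does not identify a constant-force segment")
  z <- trace$data$ext_nm
  tt <- trace$data$time_s
  n <- length(z)
  ks <- min_margin:(n - min_margin)
  cs <- cumsum(z)
  tot <- cs[n]
  m1 <- cs[ks] / ks
  m2 <- (tot - cs[ks]) / (n - ks)
  contrast <- m2 - m1
  sig <- stats::median(abs(diff(z))) * 1.4826 / sqrt(2)
  se <- sig * sqrt(1 / ks + 1 / (n - ks))
  zsc <- abs(contrast) / se
  best <- which.max(abs(contrast) * (zsc > config$noise_z_threshold))
  if (abs(contrast[best]) < config$min_jump ||
      zsc[best] < config$noise_z_threshold) return(NULL)
  # flag if a second acceptable change point exists well away from best
  far <- abs(ks - ks[best]) > 4 * config$smoothing_halfwidth
  flagged <- any(far & abs(contrast) > config$min_jump &
                   zsc > config$noise_z_threshold)
  list(time = tt[ks[best]], jump = contrast[best], zscore = zsc[best],
       flagged = flagged)
}

#' Simulate and analyze a condition in one pass
#'
#' Streaming convenience for large experiments: molecules are simulated
#' and analyzed one at a time so full traces are never all held in
#' memory. Ground-truth events are retained alongside the detected
#' events.
#'
#' @param preset Preset or preset name.
#' @param n_molecules Number of molecules.
#' @param protocol,ramp,geometry,params,trace_rate,noise_cap Simulation
#'   settings (see [simulate_experiment()]).
#' @param config Analysis settings; defaults to
#'   [ramp_analysis_config()] at `trace_rate`.
#' @param seed Master seed.
#' @return An `mt_analysis` with an extra `truth` element.
#' @export
simulate_and_analyze <- function(preset, n_molecules,
                                 protocol = protocol_config(),
                                 ramp = ramp_profile(),
                                 geometry = tether_geometry(),
                                 params = polymer_params(),
                                 trace_rate = 20, noise_cap = 15,
                                 config = NULL, seed = 1) {
  if (is.character(preset)) preset <- get_preset(preset)
  if (is.null(preset$calibrated))
    preset <- calibrate_preset(preset, ramp, params)
  if (is.null(config)) config <- ramp_analysis_config(trace_rate)
  seeds <- derive_child_seeds(seed, n_molecules)
  out_ev <- vector("list", n_molecules)
  out_mol <- vector("list", n_molecules)
  out_truth <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    mol <- simulate_molecule(preset, protocol, ramp, geometry, params,
                             trace_rate, noise_cap,
                             molecule_id = sprintf("m%04d", i),
                             seed = seeds[i])
    res <- analyze_molecule_traces(mol$traces, geometry, params, config)
    out_ev[[i]] <- res$events
    out_mol[[i]] <- res$molecule
    out_truth[[i]] <- mol$truth
  }
  structure(
    list(events = do.call(rbind, c(out_ev, list(empty_events()))),
         molecules = do.call(rbind, out_mol),
         truth = do.call(rbind, out_truth),
         n_cycles = protocol$n_cycles,
         meta = list(preset = preset$name, n_molecules = n_molecules,
                     n_cycles = protocol$n_cycles, seed = seed,
                     trace_rate = trace_rate),
         config = config),
    class = "mt_analysis"
  )
}
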