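#' @title Synthetic trace generation
#' @description Stochastic generator of single-molecule stretching traces:
#'   a state machine for nucleosome/tetrasome unwrapping under a force
#'   ramp with Bell-Evans kinetics, condition presets for each
#'   experimental arm, relaxation-hold reassembly, constant-force
#'   dephosphorylation, and mixed deposition populations.
#' @name simulate
NULL

new_trace <- function(time, magnet, force, ext, meta) {
  structure(
    list(data = data.frame(time_s = time, magnet_mm = magnet,
                           force_pN = force, ext_nm = ext),
         meta = meta),
    class = "mt_trace"
  )
}

#' @export
print.mt_trace <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "Trace: molecule %s cycle %s (%s), %d samples over %.1f s\n",
    as.character(m$molecule_id), as.character(m$cycle),
    as.character(m$preset), nrow(x$data),
    max(x$data$time_s)))
  invisible(x)
}

empty_truth <- function() {
  data.frame(molecule_id = character(), cycle = integer(),
             time = numeric(), force = numeric(),
             transition = character(), released_bp = numeric(),
             stringsAsFactors = FALSE)
}

# Per-transition rupture times for one cycle. Sequential presets chain
# each clock off the previous rupture; non-sequential presets start all
# clocks at the cycle start and order the resulting times (the first
# rupture is attributed to the outer wrap).
draw_cycle_events <- function(preset, ramp, params) {
  trs <- preset$transitions
  times <- rep(Inf, length(trs))
  if (isTRUE(preset$sequential)) {
    t0 <- 0
    for (i in seq_along(trs)) {
      ti <- rupture_time_thinning(trs[[i]]$spec, ramp, params, t_start = t0)
      times[i] <- ti
      if (!is.finite(ti)) break
      t0 <- ti
    }
  } else {
    for (i in seq_along(trs))
      times[i] <- rupture_time_thinning(trs[[i]]$spec, ramp, params)
    ord <- order(times)
    times <- times[ord]           # labels keep preset order: first = outer
  }
  times
}

#' Simulate one stretching cycle
#'
#' Generates one force-ramp trace for a molecule in a given state.
#' Transition times are drawn by thinning against the time-varying
#' Bell-Evans rates (exact, no Euler discretization); the sampled
#' extension is the eWLC extension of the free handle DNA plus all
#' released wraps, with additive Gaussian noise of force-dependent
#' standard deviation `sigma(F) = sqrt(kBT z(F)/F)` capped at
#' `noise_cap`. Molecules in the `"lost"` state produce bare-DNA traces
#' (the full template contour follows the eWLC).
#'
#' @param state `"wrapped"` (intact particle) or `"lost"` (bare DNA).
#' @param preset A calibrated [condition_preset()] (see
#'   [calibrate_preset()]).
#' @param ramp A [ramp_profile()].
#' @param geometry A [tether_geometry()] (total template length).
#' @param params A [polymer_params()].
#' @param trace_rate Trace sampling rate in Hz.
#' @param noise_cap Maximum noise sd in nm.
#' @param molecule_id,cycle Metadata labels.
#' @return A list with `trace` (class `mt_trace`), `events` (ground-truth
#'   data frame) and `end_state` (`"wrapped"`, `"partial"`, `"unwrapped"`
#'   or `"lost"`).
#' @export
simulate_cycle <- function(state, preset, ramp, geometry = tether_geometry(),
                           params = polymer_params(), trace_rate = 20,
                           noise_cap = 15, molecule_id = "m1", cycle = 1L) {
  stopifnot(state %in% c("wrapped", "lost"))
  if (is.null(preset$calibrated))
    stop("preset must be calibrated first; see calibrate_preset()")
  tg <- seq(0, ramp$duration, by = 1 / trace_rate)
  Fg <- ramp$force_fn(tg)
  g <- ewlc_rel_ext(Fg, params)
  rise <- params$bp_rise
  wrapped_bp <- sum(vapply(preset$transitions,
                           function(tr) tr$released_bp, 0))
  handle_bp <- geometry$total_bp - wrapped_bp
  if (handle_bp < 0) stop("preset releases more bp than the template holds")

  events <- empty_truth()
  if (state == "lost") {
    free_bp <- rep(geometry$total_bp, length(tg))
    end_state <- "lost"
  } else {
    times <- draw_cycle_events(preset, ramp, params)
    fired <- which(is.finite(times))
    if (length(fired) > 0) {
      events <- data.frame(
        molecule_id = molecule_id, cycle = as.integer(cycle),
        time = times[fired],
        force = ramp$force_fn(times[fired]),
        transition = vapply(preset$transitions[fired],
                            function(tr) tr$name, ""),
        released_bp = vapply(preset$transitions[fired],
                             function(tr) tr$released_bp, 0),
        stringsAsFactors = FALSE)
    }
    released_cum <- c(0, cumsum(events$released_bp))
    idx <- findInterval(tg, events$time) + 1L
    free_bp <- handle_bp + released_cum[idx]
    end_state <- if (length(fired) == length(preset$transitions))
      "unwrapped" else if (length(fired) > 0) "partial" else "wrapped"
  }
  z_clean <- free_bp * rise * g
  sigma <- pmin(noise_cap,
                sqrt(params$thermal_energy * pmax(z_clean, 1e-9) /
                       pmax(Fg, 1e-6)))
  ext <- z_clean + stats::rnorm(length(tg), sd = sigma)
  meta <- list(molecule_id = molecule_id, cycle = as.integer(cycle),
               preset = preset$name, trace_rate = trace_rate,
               schema_version = "1.0")
  list(trace = new_trace(tg, ramp$position_fn(tg), Fg, ext, meta),
       events = events, end_state = end_state)
}

#' Simulate repeated stretching of one molecule
#'
#' Runs the full stretch-relax protocol on a single molecule. After a
#' cycle that ends fully unwrapped, the particle reassembles during the
#' 0.1 pN hold with probability `p_maintain`, otherwise it is lost (bare
#' DNA thereafter; loss is absorbing). A partially opened particle at the
#' cycle end rewraps deterministically at the hold force.
#'
#' @param preset A calibrated [condition_preset()].
#' @param protocol A [protocol_config()].
#' @param ramp A [ramp_profile()] matching the protocol's endpoints.
#' @param geometry,params,trace_rate,noise_cap See [simulate_cycle()].
#' @param molecule_id Molecule label.
#' @param seed Optional integer seed.
#' @return A list with `traces` (list of `mt_trace`, one per cycle),
#'   `truth` (ground-truth event data frame) and `states` (state at the
#'   start of each cycle).
#' @export
simulate_molecule <- function(preset, protocol = protocol_config(),
                              ramp = ramp_profile(),
                              geometry = tether_geometry(),
                              params = polymer_params(), trace_rate = 20,
                              noise_cap = 15, molecule_id = "m1",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- "wrapped"
  traces <- vector("list", protocol$n_cycles)
  truth <- list()
  states <- character(protocol$n_cycles)
  for (cyc in seq_len(protocol$n_cycles)) {
    states[cyc] <- state
    res <- simulate_cycle(state, preset, ramp, geometry, params,
                          trace_rate, noise_cap, molecule_id, cyc)
    traces[[cyc]] <- res$trace
    truth[[cyc]] <- res$events
    state <- switch(res$end_state,
      unwrapped = if (stats::runif(1) < preset$p_maintain) "wrapped"
                  else "lost",
      partial = "wrapped",
      wrapped = "wrapped",
      lost = "lost")
  }
  list(traces = traces, truth = do.call(rbind, truth), states = states)
}

derive_child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a multi-molecule experiment
#'
#' Independent molecules under one condition preset, with per-molecule
#' child seeds derived deterministically from the master seed so the
#' trace set is bit-reproducible.
#'
#' @param preset A [condition_preset()] or preset name; calibrated
#'   automatically against `ramp` if needed.
#' @param n_molecules Number of molecules (>= 1).
#' @param protocol A [protocol_config()].
#' @param ramp A [ramp_profile()].
#' @param geometry,params,trace_rate,noise_cap See [simulate_cycle()].
#' @param seed Master integer seed.
#' @return An object of class `mt_traceset`: `traces` (flat list of
#'   `mt_trace`), `truth` (event data frame) and `meta`.
#' @export
simulate_experiment <- function(preset, n_molecules,
                                protocol = protocol_config(),
                                ramp = ramp_profile(),
                                geometry = tether_geometry(),
                                params = polymer_params(), trace_rate = 20,
                                noise_cap = 15, seed = 1) {
  if (n_molecules < 1) stop("n_molecules must be at least 1")
  if (is.character(preset)) preset <- get_preset(preset)
  if (is.null(preset$calibrated))
    preset <- calibrate_preset(preset, ramp, params)
  seeds <- derive_child_seeds(seed, n_molecules)
  traces <- list()
  truth <- list()
  for (i in seq_len(n_molecules)) {
    mol <- simulate_molecule(preset, protocol, ramp, geometry, params,
                             trace_rate, noise_cap,
                             molecule_id = sprintf("m%04d", i),
                             seed = seeds[i])
    traces <- c(traces, mol$traces)
    truth[[i]] <- mol$truth
  }
  structure(
    list(traces = traces,
         truth = do.call(rbind, truth),
         meta = list(preset = preset$name, n_molecules = n_molecules,
                     n_cycles = protocol$n_cycles, seed = seed,
                     trace_rate = trace_rate, schema_version = "1.0")),
    class = "mt_traceset"
  )
}

#' @export
print.mt_traceset <- function(x, ...) {
  cat(sprintf(
    "Trace set '%s': %d molecules x %d cycles (%d traces), %d true events\n",
    x$meta$preset, x$meta$n_molecules, x$meta$n_cycles, length(x$traces),
    if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Simulate a real-time dephosphorylation trace at constant force
#'
#' A Ser31-phosphorylated nucleosome is held at a constant force between
#' the wild-type outer-wrap and the phosphorylated rupture regimes while
#' phosphatase acts. The dephosphorylation waiting time is exponential
#' with rate `k_dephos` (force-independent chemistry); once
#' dephosphorylated, the outer wrap ruptures with the wild-type
#' Bell-Evans rate at the hold force, releasing the outer wrap as a
#' ~20 nm extension jump.
#'
#' @param preset_wt Calibrated wild-type preset (its first transition
#'   provides the outer-wrap kinetics), or a preset name.
#' @param k_dephos Dephosphorylation rate in 1/s.
#' @param hold_force Constant monitoring force in pN.
#' @param hold_time Monitoring duration in s.
#' @param geometry,params See [simulate_cycle()].
#' @param sample_rate Trace sampling rate in Hz.
#' @param ramp Ramp used to calibrate `preset_wt` if it arrives
#'   uncalibrated.
#' @param noise_cap Maximum noise sd in nm.
#' @param molecule_id Metadata label.
#' @param seed Optional integer seed.
#' @return A list with `trace` (constant-force `mt_trace`, meta field
#'   `constant_force` set) and `truth` (data frame with the
#'   dephosphorylation and rupture times, or zero rows if no event fired
#'   within the hold).
#' @export
simulate_dephos <- function(preset_wt = "h33_nuc", k_dephos = 1 / 60,
                            hold_force = 8.6, hold_time = 300,
                            geometry = tether_geometry(),
                            params = polymer_params(), sample_rate = 100,
                            ramp = ramp_profile(), noise_cap = 15,
                            molecule_id = "d1", seed = NULL) {
  stopifnot(k_dephos >= 0, hold_force > 0, hold_time > 0)
  if (is.character(preset_wt)) preset_wt <- get_preset(preset_wt)
  if (is.null(preset_wt$calibrated))
    preset_wt <- calibrate_preset(preset_wt, ramp, params)
  if (!is.null(seed)) set.seed(seed)
  outer <- preset_wt$transitions[[1]]
  t_dephos <- if (k_dephos > 0) stats::rexp(1, k_dephos) else Inf
  k_rup <- bell_rate(hold_force, outer$spec, params)
  t_rup <- t_dephos + stats::rexp(1, k_rup)

  tg <- seq(0, hold_time, by = 1 / sample_rate)
  g <- ewlc_rel_ext(hold_force, params)
  wrapped_bp <- sum(vapply(preset_wt$transitions,
                           function(tr) tr$released_bp, 0))
  handle_bp <- geometry$total_bp - wrapped_bp
  free_bp <- handle_bp + ifelse(tg >= t_rup, outer$released_bp, 0)
  z_clean <- free_bp * params$bp_rise * g
  sigma <- pmin(noise_cap,
                sqrt(params$thermal_energy * z_clean / hold_force))
  ext <- z_clean + stats::rnorm(length(tg), sd = sigma)
  meta <- list(molecule_id = molecule_id, cycle = 1L,
               preset = paste0(preset_wt$name, "_dephos"),
               trace_rate = sample_rate, constant_force = hold_force,
               schema_version = "1.0")
  truth <- if (t_rup <= hold_time) {
    data.frame(molecule_id = molecule_id, cycle = 1L, time = t_rup,
               force = hold_force, transition = "outer",
               released_bp = outer$released_bp,
               t_dephos = t_dephos, stringsAsFactors = FALSE)
  } else {
    cbind(empty_truth(), data.frame(t_dephos = numeric()))
  }
  list(trace = new_trace(tg, NA_real_, rep(hold_force, length(tg)), ext,
                         meta),
       truth = truth)
}

#' Simulate a dimer-deposition assay population
#'
#' Mixed population produced by chaperone-mediated H2A-H2B deposition
#' onto tetrasomes: each molecule is an assembled nucleosome (two-step
#' unwrapping) with probability `assembled_fraction`, otherwise a
#' tetrasome (one-step). Ground-truth assembly labels are retained in the
#' returned trace set (`meta$assembled`).
#'
#' @param preset_nucleosome,preset_tetrasome Presets (or names) for the
#'   two subpopulations.
#' @param assembled_fraction Probability of the nucleosome subpopulation.
#' @param n_molecules Number of molecules.
#' @param protocol,ramp,geometry,params,trace_rate,noise_cap See
#'   [simulate_experiment()].
#' @param seed Master integer seed.
#' @return An `mt_traceset` whose `meta$assembled` is the logical
#'   ground-truth assembly label per molecule.
#' @export
simulate_deposition <- function(preset_nucleosome, preset_tetrasome,
                                assembled_fraction, n_molecules,
                                protocol = protocol_config(),
                                ramp = ramp_profile(),
                                geometry = tether_geometry(),
                                params = polymer_params(), trace_rate = 20,
                                noise_cap = 15, seed = 1) {
  stopifnot(assembled_fraction >= 0, assembled_fraction <= 1,
            n_molecules >= 1)
  if (is.character(preset_nucleosome))
    preset_nucleosome <- get_preset(preset_nucleosome)
  if (is.character(preset_tetrasome))
    preset_tetrasome <- get_preset(preset_tetrasome)
  if (is.null(preset_nucleosome$calibrated))
    preset_nucleosome <- calibrate_preset(preset_nucleosome, ramp, params)
  if (is.null(preset_tetrasome$calibrated))
    preset_tetrasome <- calibrate_preset(preset_tetrasome, ramp, params)
  set.seed(seed)
  assembled <- stats::runif(n_molecules) < assembled_fraction
  seeds <- sample.int(.Machine$integer.max - 1L, n_molecules)
  traces <- list()
  truth <- list()
  for (i in seq_len(n_molecules)) {
    p <- if (assembled[i]) preset_nucleosome else preset_tetrasome
    mol <- simulate_molecule(p, protocol, ramp, geometry, params,
                             trace_rate, noise_cap,
                             molecule_id = sprintf("m%04d", i),
                             seed = seeds[i])
    traces <- c(traces, mol$traces)
    truth[[i]] <- mol$truth
  }
  structure(
    list(traces = traces, truth = do.call(rbind, truth),
         meta = list(preset = paste0("deposition_",
                                     preset_nucleosome$name),
                     n_molecules = n_molecules,
                     n_cycles = protocol$n_cycles, seed = seed,
                     trace_rate = trace_rate,
                     assembled_fraction = assembled_fraction,
                     assembled = assembled, schema_version = "1.0")),
    class = "mt_traceset"
  )
}
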