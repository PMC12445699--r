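#' Experimental condition preset
#'
#' Bundles the kinetic transitions, reassembly probability and assembled
#' fraction describing one experimental arm (histone variant, Ser31
#' modification, presence of the FACT chaperone, tetrasome vs nucleosome).
#' Transition rate parameters are usually left `NA` and filled in by
#' [calibrate_preset()] from the target rupture-force statistics.
#'
#' @param name Preset label.
#' @param transitions List describing each transition in firing order; each
#'   element is a list with `name`, `released_bp`, `target_mean`, optional
#'   `target_sd`, optional `dx` (used when no sd is targeted) and, once
#'   calibrated, `spec` (a [transition_spec()]).
#' @param p_maintain Probability that a fully unwrapped particle reassembles
#'   during the 0.1 pN relaxation hold, in \[0, 1\].
#' @param assembled_fraction Probability that a molecule starts as the
#'   intact particle (used by deposition assays; 1 otherwise).
#' @param sequential If `TRUE` (default) each transition's clock starts
#'   when the previous one fires; if `FALSE` all clocks start at the cycle
#'   start and rupture times are ordered (used when both wraps are
#'   destabilized to a similar force scale).
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name, transitions, p_maintain = 0.9,
                             assembled_fraction = 1, sequential = TRUE) {
  stopifnot(p_maintain >= 0, p_maintain <= 1,
            assembled_fraction >= 0, assembled_fraction <= 1,
            length(transitions) >= 1)
  total_bp <- sum(vapply(transitions, function(tr) tr$released_bp, 0))
  if (total_bp > 147)
    stop("total released bp across transitions must not exceed 147")
  structure(
    list(name = name, transitions = transitions, p_maintain = p_maintain,
         assembled_fraction = assembled_fraction, sequential = sequential),
    class = "condition_preset"
  )
}

#' Stretching protocol
#'
#' The repeated stretch-relax protocol: a force ramp from `f_start` to
#' `f_end`, then rapid relaxation to `hold_force` maintained for
#' `hold_time`, repeated `n_cycles` times on the same molecule. An
#' optional `constant_force` describes constant-force monitoring segments
#' (real-time dephosphorylation assay).
#'
#' @param n_cycles Number of stretching cycles (>= 1; the bench protocol
#'   uses at least three).
#' @param hold_force Relaxation hold force in pN (0.1).
#' @param hold_time Relaxation hold duration in s (300).
#' @param f_start,f_end Ramp endpoints in pN.
#' @param constant_force Optional constant monitoring force in pN.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_cycles = 3, hold_force = 0.1, hold_time = 300,
                            f_start = 0.1, f_end = 30,
                            constant_force = NULL) {
  stopifnot(n_cycles >= 1, hold_force < f_end, f_start < f_end)
  structure(
    list(n_cycles = as.integer(n_cycles), hold_force = hold_force,
         hold_time = hold_time, f_start = f_start, f_end = f_end,
         constant_force = constant_force),
    class = "protocol_config"
  )
}

# helper to write registry entries tersely
.tr <- function(name, bp, mean, sd = NULL, dx = NULL) {
  if (is.null(dx)) dx <- if (mean < 10) 6 else 2
  list(name = name, released_bp = bp, target_mean = mean, target_sd = sd,
       dx = dx)
}

#' Registry of experimental condition presets
#'
#' Returns the built-in presets for every single-molecule experimental
#' arm: canonical H3 and variant H3.3 nucleosomes, Ser31 phosphorylated
#' (S31ph) and mutant (S31A/S31E) nucleosomes, each with or without the
#' FACT chaperone, (H3-H4)2 tetrasomes, and the dimer-deposition arms.
#' Target rupture-force statistics per transition (pN):
#'
#' * `h3_nuc`, `h33_nuc`, `h33s31a_nuc`, `h33s31e_nuc`: outer 6.6,
#'   inner 22.9; nucleosomes are maintained across cycles for H3.3-family
#'   octamers (`p_maintain` 0.9) but not canonical H3 (0.05).
#' * `h33s31ph_nuc`: both wraps destabilized to a common 11.3 +/- 2.6
#'   scale; reversible (0.9).
#' * `h3_fact`: one cooperative 147 bp disruption at 6.7; maintained (0.9).
#' * `h33_fact`: outer 6.6, inner stabilized to 24.5; maintained (0.9).
#' * `h33s31ph_fact`: one cooperative disruption at 13.9 +/- 3.1; lost
#'   after the first cycle (`p_maintain` 0).
#' * `h33s31ae_fact`: outer 6.6, inner 25.4; maintained (0.9).
#' * `h3_tetra`, `h33_tetra`: single 85 bp transition at 22.5;
#'   `p_maintain` 0.05 / 0.9.
#' * `h3_depo`, `h33_depo`: deposition products (two-step nucleosome,
#'   maintained) with `assembled_fraction` 0.543 / 0.608; the unassembled
#'   remainder behaves as the corresponding tetrasome.
#'
#' Default distances to the transition state are 6 nm for low-force
#' (~6-7 pN) transitions and 2 nm for high-force (>= 20 pN) transitions;
#' where a target sd is given, `dx` is solved together with `k0`.
#'
#' @return Named list of [condition_preset()] objects.
#' @export
preset_registry <- function() {
  two_step <- function(inner_mean = 22.9)
    list(.tr("outer", 62, 6.6), .tr("inner", 85, inner_mean))
  reg <- list(
    h3_nuc = condition_preset("h3_nuc", two_step(), p_maintain = 0.05),
    h33_nuc = condition_preset("h33_nuc", two_step(), p_maintain = 0.9),
    h33s31a_nuc = condition_preset("h33s31a_nuc", two_step(),
                                   p_maintain = 0.9),
    h33s31e_nuc = condition_preset("h33s31e_nuc", two_step(),
                                   p_maintain = 0.9),
    h33s31ph_nuc = condition_preset(
      "h33s31ph_nuc",
      list(.tr("outer", 62, 11.3, sd = 2.6),
           .tr("inner", 85, 11.3, sd = 2.6)),
      p_maintain = 0.9, sequential = FALSE),
    h3_fact = condition_preset(
      "h3_fact", list(.tr("cooperative", 147, 6.7)), p_maintain = 0.9),
    h33_fact = condition_preset("h33_fact", two_step(24.5),
                                p_maintain = 0.9),
    h33s31ph_fact = condition_preset(
      "h33s31ph_fact", list(.tr("cooperative", 147, 13.9, sd = 3.1)),
      p_maintain = 0),
    h33s31ae_fact = condition_preset("h33s31ae_fact", two_step(25.4),
                                     p_maintain = 0.9),
    h3_tetra = condition_preset(
      "h3_tetra", list(.tr("inner", 85, 22.5)), p_maintain = 0.05),
    h33_tetra = condition_preset(
      "h33_tetra", list(.tr("inner", 85, 22.5)), p_maintain = 0.9),
    h3_depo = condition_preset("h3_depo", two_step(), p_maintain = 0.9,
                               assembled_fraction = 0.543),
    h33_depo = condition_preset("h33_depo", two_step(), p_maintain = 0.9,
                                assembled_fraction = 0.608)
  )
  reg
}

#' Fetch a preset by name
#'
#' @param name Preset name; see [preset_registry()].
#' @return A [condition_preset()].
#' @export
get_preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

.preset_cache <- new.env(parent = emptyenv())

#' Calibrate a preset's kinetic parameters to its targets
#'
#' Fills in each transition's `(k0, dx)` by [calibrate_rates()] so that
#' the semi-analytic rupture-force distribution on the given ramp matches
#' the preset's target mean (and sd, where specified). Results are cached
#' per session keyed on the preset name and ramp so repeated simulations
#' do not re-solve.
#'
#' Published rupture-force statistics describe detectable ruptures, so
#' the targets are matched by the distribution conditional on rupture at
#' or above `min_force`, the analysis force floor (see
#' [analysis_config()]); the sub-floor tail of a low-force transition
#' would otherwise bias every recovered mean upward.
#'
#' @param preset A [condition_preset()] or preset name.
#' @param ramp A [ramp_profile()].
#' @param params A [polymer_params()].
#' @param dt Quadrature step in s.
#' @param min_force Force floor (pN) the targets are conditioned on.
#' @return The preset with a calibrated `spec` in every transition.
#' @export
calibrate_preset <- function(preset, ramp = ramp_profile(),
                             params = polymer_params(), dt = 0.05,
                             min_force = 2) {
  if (is.character(preset)) preset <- get_preset(preset)
  targ <- vapply(preset$transitions, function(tr)
    paste(tr$name, tr$released_bp, tr$target_mean,
          if (is.null(tr$target_sd)) "-" else tr$target_sd, tr$dx,
          sep = ":"), "")
  key <- paste(preset$name, paste(targ, collapse = ";"),
               signif(ramp$duration, 10), signif(ramp$d_start, 10),
               params$persistence_length, params$stretch_modulus,
               dt, min_force, sep = "|")
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  grid <- ramp_grid(ramp, params, dt)
  preset$transitions <- lapply(preset$transitions, function(tr) {
    tr$spec <- calibrate_rates(
      target_mean = tr$target_mean, target_sd = tr$target_sd, ramp = grid,
      released_bp = tr$released_bp, name = tr$name, dx_default = tr$dx,
      params = params, dt = dt, min_force = min_force)
    tr
  })
  preset$calibrated <- TRUE
  .preset_cache[[key]] <- preset
  preset
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf(
    "Preset '%s': %d transition(s), p_maintain = %g, assembled_fraction = %g\n",
    x$name, length(x$transitions), x$p_maintain, x$assembled_fraction))
  for (tr in x$transitions) {
    cal <- if (!is.null(tr$spec))
      sprintf(" [k0 = %.3g /s, dx = %.3g nm]", tr$spec$k0, tr$spec$dx)
    else " [uncalibrated]"
    cat(sprintf("  %-11s %3d bp, target %g%s pN%s\n", tr$name,
                tr$released_bp, tr$target_mean,
                if (is.null(tr$target_sd)) "" else
                  paste0(" +/- ", tr$target_sd), cal))
  }
  invisible(x)
}
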