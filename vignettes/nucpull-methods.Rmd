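---
title: "Models and methods behind nucpull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucpull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nucpull simulates and analyzes single-nucleosome stretching experiments on
magnetic tweezers: a bead-tethered DNA molecule carrying one positioned
nucleosome is pulled by a receding pair of magnets, the outer and inner
DNA wraps release in discrete extension jumps, and the forces at which
they do — together with whether the particle reassembles after
relaxation — report on nucleosome stability and on the action of histone
variants, phosphomarks and chaperones. This vignette documents the models,
the tunable parameters, and the design choices where the design was
genuinely open.

## The tether: extensible worm-like chain

The DNA handle (and any released wrap) is described by the modified
Marko–Siggia interpolation with an enthalpic stretching term,

$$F = \frac{k_BT}{L_p}\left[\frac{1}{4(1 - z/L + F/S)^2} - \frac14
      + \frac{z}{L} - \frac{F}{S}\right],$$

solved for the extension $z$ of a chain of contour length $L$ by a
safeguarded Newton iteration (verified against plain bisection in the
test suite). Defaults are canonical dsDNA values at room temperature in
physiological salt: persistence length $L_p = 45$ nm, stretch modulus
$S = 1200$ pN, rise $0.338$ nm/bp, $k_BT = 4.09$ pN·nm. This
interpolation is accurate over the experimental 0.1–30 pN window and
approaches the Odijk limit at high force (property-tested at 2%).

Wrapped DNA contributes zero extension and the particle's physical
diameter (~5–10 nm) is ignored: the measurable signal is jump *sizes*,
not absolute extensions, and the eWLC is linear in contour length at
fixed force, so a release of $n$ bp produces a jump
$n \cdot 0.338\,\mathrm{nm} \cdot z/L(F)$ exactly.

The outer/inner split of the 147 wrapped bp is not taken from structural
turn lengths; it is calibrated from the one measurable anchor available:
a 20 nm jump at 8.6 pN. `calibrate_outer_release(20, 8.6)` gives 62 bp,
leaving 85 bp for the inner wrap. The analysis windows (outer 40–75 bp,
inner 65–110 bp, full ≥ 120 bp) are this split plus noise-propagated
slack; the 65–75 bp overlap is resolved by temporal order (the first
event of a two-event cycle is the outer wrap).

## The instrument layer

**Magnet map.** Force versus magnet distance follows a double
exponential $F(d) = 28\,e^{-d/0.35} + 2.5\,e^{-d/2.0}$ (pN, mm). The
constants are package defaults chosen so that 0.1→30 pN spans a few mm
of travel; at the bench speed of 10 µm/s the ramp lasts ≈ 643 s.
Magnet position is exactly linear in time; force inherits the map's
curvature, so the loading rate grows from ~0.005 pN/s at the start to
~0.6 pN/s near 23 pN.

**Brownian calibration traces.** The transverse (pendulum) coordinate of
the bead is an Ornstein–Uhlenbeck process with stiffness
$k = F/z_\mathrm{tether}$ and Stokes drag $\gamma = 6\pi\eta r$
($r = 1.4$ µm, $\eta = 10^{-3}$ Pa·s, so
$\gamma = 2.64\times10^{-5}$ pN·s/nm). The simulator uses the exact
discrete-time OU update, so the recorded series carries no integration
error at any sampling rate. The short-pendulum correction
($k = F/(z + r)$) is omitted; it would rescale all stiffnesses by a
common factor at the 10 kb calibration tether length and is irrelevant
to the recovery loop tested here.

**Spectral force estimate.** The fluctuation spectrum of an overdamped
tethered bead is Lorentzian with corner $f_c = k/2\pi\gamma$. Sampling
at 500 Hz folds the $1/f^2$ tail back into the recorded band, so the
package fits the *aliased* Lorentzian — the AR(1) spectrum
$S(f) \propto [1 - 2a\cos(2\pi f\,\Delta t) + a^2]^{-1}$ with
$a = e^{-2\pi f_c \Delta t}$ — to the Welch periodogram (8 segments, 50%
overlap, Hann window) in log space over $[4/T,\,0.8\,f_\mathrm{Nyq}]$.
Fitting the continuous Lorentzian instead overestimates the corner by
roughly 20% under these settings, which is why the aliased form is the
default; measured calibration bias is below 1% at 1–15 pN, comfortably
inside the 3% the pipeline demands. The equipartition estimate
$F = k_BT\,z/\mathrm{var}(y)$ serves as an independent cross-check, and
drift is removed by subtracting a surface-bead reference channel
recentred on its median.

## The stochastic generator

Wrap release is a Bell–Evans process, $k(F) = k_0 e^{F\Delta x/k_BT}$.
On a monotone ramp the rupture-force distribution follows from the
survival integral $S(t) = \exp(-\int_0^t k(F(u))\,du)$, evaluated by
trapezoidal quadrature on a 0.05 s grid; event times are drawn by
thinning against piecewise bounds of the time-varying rate (exact — no
Euler step anywhere in the draw).

**Calibration to target statistics.** Each preset transition stores a
target mean (and sometimes sd) rupture force; `calibrate_rates()` solves
for $k_0$ (and $\Delta x$ when an sd is given) so the survival-integral
distribution matches. Two choices matter here:

* *Conditioning on the detection floor.* Reported rupture statistics are
  statistics of detected ruptures, and the analyzer cannot score events
  below 2 pN. On this slow, near-exponential ramp a low-force transition
  has appreciable probability mass below that floor, so matching the
  unconditional mean would leave every recovered mean sitting above its
  target. Preset calibration therefore matches the distribution
  *conditional on rupture at ≥ 2 pN* (`min_force` argument; the
  unconditional behaviour remains the default of `calibrate_rates()`).
* *Default transition-state distances.* Where no sd is printed, $\Delta x$
  defaults to 6 nm for low-force (~6–7 pN) transitions and 2 nm for
  high-force (≥ 20 pN) ones. A single small default (e.g. 1.5 nm) is
  untenable for the low-force transitions: calibrated to a 6.6 pN mean it
  implies an sd of ~5.9 pN with 39% of ruptures below 2 pN, unlike the
  tight outer-wrap distributions the experiment shows. 6 nm gives
  sd ≈ 0.9 pN; 2 nm gives sd ≈ 3.1 pN, matching the 2.6–3.1 pN spreads
  that are printed for the arms that have them.

**State machine.** A molecule starts fully wrapped; transitions fire in
order (inner after outer) with the inner clock started at the outer
rupture — at a ≥ 16 pN separation the conditioning this induces is
negligible. The phosphorylated preset is the exception: both wraps are
destabilized to a common force scale, so both clocks run from the cycle
start, each calibrated to the printed pooled statistics (11.3 ± 2.6 pN),
and the earlier rupture is attributed to the outer wrap. Pooling the
ordered pair restores exactly the per-clock distribution, so the
analyzer's pooled mean and sd are directly comparable to the target.

After a cycle that ends fully unwrapped the particle reassembles during
the 0.1 pN / 5 min hold with probability `p_maintain` (0.9 for
H3.3-family arms, 0.05 for canonical H3, 0 for FACT-bound S31ph), else
it is bare DNA thereafter; partial openings rewrap deterministically at
the hold. Values of 0.9/0.05 are package choices — the experiment shows
maintenance and loss but prints no proportions. Reassembly is treated
as instantaneous and rewrapping *during* a ramp is disallowed.

**Traces.** The sampled extension is the eWLC extension of all free DNA
plus Gaussian noise with the equipartition scale
$\sigma(F) = \sqrt{k_BT\,z(F)/F}$, capped at 15 nm (at 0.1 pN the
uncapped value would diverge). Ramp traces are generated at 20 Hz —
dense enough that the 0.5–1.25 s detection windows hold dozens of
samples, sparse enough that a full 9-arm recovery study runs in minutes
on one core. Calibration traces keep the full 500 Hz. Noise is white;
the OU correlation of a real bead at these corner frequencies is
ignored on ramp traces, which mildly flatters the detector and is noted
as a limitation below.

**Condition presets.** The registry covers every experimental arm:
two-step nucleosomes (outer 6.6 / inner 22.9 pN) for H3, H3.3, S31A,
S31E; the common-scale S31ph nucleosome; FACT-bound arms (H3: one
cooperative 147 bp step at 6.7 pN; H3.3: inner stabilized to 24.5 pN;
S31ph: one step at 13.9 ± 3.1 pN, lost after the first cycle; S31A/E:
inner 25.4 pN); tetrasomes (one 85 bp step at 22.5 pN); and deposition
mixtures with assembled fractions 0.608 (H3.3) and 0.543 (H3).
Whether FACT-bound H3.3 nucleosomes keep a low-force outer transition is
not determinate from the reported measurements; the preset assumes they
do (outer 6.6 pN retained), which is the conservative reading.

**Dephosphorylation assay.** At a constant 8.6 pN hold the
dephosphorylation waiting time is exponential (`k_dephos`, default
1/60 s⁻¹ so that a typical event falls inside a 3–5 min hold —
force-independent chemistry), after which the outer wrap ruptures with
the wild-type Bell rate at 8.6 pN and releases the calibrated 62 bp
(≈ 20 nm).

## The analysis pipeline

Jump detection works in the time domain against a locally smoothed
baseline rather than by fitting a global eWLC model, so it is robust to
calibration error; the eWLC enters only when jumps are converted to
released bp. The extension passes through a short 5-sample median filter
(spike suppression only — a wide median prefilter smears a noisy step
response and halves the contrast), then the paired-window mean contrast
$\Delta(t)$ with half-width $w$ (default 25 samples) is computed at every
sample: the matched filter for a step in white noise. Samples where
$\Delta$ exceeds both the minimum jump (8 nm) and
`noise_z_threshold` = 4 standard errors of the contrast
($\sigma\sqrt{2/w}$, with $\sigma$ a running-median-of-|differences|
robust estimate) form candidate runs; each run contributes its contrast
maximum, candidates closer than the merge radius collapse to the
largest, and each survivor is re-measured on the raw trace with windows
extended up to $3w$ where event spacing permits (halving the
released-bp estimation noise). The re-measured jump must clear the same
size and z-score rule — two slightly different statistics both clearing
threshold suppresses marginal noise flukes. `ramp_analysis_config()`
sets the merge radius to the paired-window span so one rupture can
never be double-counted at any sampling rate; the measured
false-positive rate on bare-tether traces is below 0.01 per trace, with
≥ 95% of sub-floor-free true events recovered.

Events get the force of the trace's force channel at the detected time,
and released bp through the eWLC; events below 2 pN are dropped.
Classification follows the cycle pattern rules above. Two conventions
the experiment leaves open are made explicit:

* *Denominators*: maintenance and deposition proportions are computed
  over molecules with at least one cycle-1 event.
* *Pooling*: rupture-force tables are available pooled over all cycles
  or first cycles only; the package default is all cycles for maintained
  arms and first cycle for single-shot arms, and both modes are always
  reported side by side in `build_report()`.

The constant-force detector scans every split point of the hold segment
and maximizes the two-sided mean-contrast statistic, accepting at the
same size/z-score thresholds; if several well-separated split points
would be accepted the largest is returned and the trace is flagged.

Statistics follow the conventions of the field: n−1 sample sd, box
descriptors with type-7 (linear-interpolation) quantiles and
1.5 × IQR whiskers, Welch two-tailed t, Wilcoxon rank-sum with midranks,
exact matched-pairs signed-rank where untied, seeded percentile
bootstrap CIs (B = 2000), and no multiple-testing correction — every
p-value is labelled unadjusted.

## Reproducibility and problem sizes

Every stochastic step is seeded: experiments derive per-molecule child
seeds from a master seed, bootstrap draws are seeded from the call, and
`(configuration, seed)` determines `report.json` byte-for-byte. The
recovery studies in `analysis/` and `scripts/acceptance.R` run each arm
at its study sample size (85–189 molecules × 3 cycles; 500 for
deposition; 60 dephosphorylation traces) with ramp traces at 20 Hz —
about 7 minutes end-to-end on one core. The test suite uses smaller
instances of the same loops.

## What the generator does and does not emulate

Passing recovery tests show the pipeline is unbiased against data whose
noise is white, whose baseline is drift-free after reference
subtraction, and whose events are instantaneous steps from a calibrated
Bell process. Real traces add correlated bead noise, camera blur,
surface sticking, multi-tether beads and gradual (non-two-state)
unwrapping, none of which is modelled; quality control here is limited
to tether-length sanity. Torque, twist, sequence-dependent elasticity
and explicit FACT binding kinetics (FACT arms are distinct presets, not
ligand-binding models) are out of scope. Recovery of the configured
parameters on synthetic data is therefore a necessary, not sufficient,
validation for bench data.
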