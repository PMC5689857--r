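---
title: "Synthesizing spread-out Bragg peaks: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing spread-out Bragg peaks: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sobptools)
```

## The problem

A passively scattered proton unit delivers a pulsed beam through a rotating
range modulator wheel (RMW): each wheel step pulls the pristine Bragg peak
back by a fixed water-equivalent thickness, and the per-pulse beam current
(the BCM program) weights the pulled-back peaks so their sum — the
spread-out Bragg peak (SOBP) — has a flat high-dose plateau across the
target. Commissioning such a machine involves fitting per-step weights to
measured depth-dose data, adjusting the modulation width with stop pulses,
and comparing simulated against measured curves with a standard set of
scalar metrics. `sobptools` implements that computational layer at desk
scale: everything around the particle transport, with synthetic generators
standing in for the transport itself.

The central model is the weighted superposition

$$D(d) \;=\; \sum_i w_i\, p_i(d), \qquad w_i \ge 0,$$

with $p_i(d)$ the depth-dose curve of the $i$-th pulled-back pristine peak,
and the weights chosen to minimize the sum of squared errors

$$\mathrm{SSE} \;=\; \sum_{d = d_1}^{d_2} \bigl(D^{m}_d - D^{s}_d\bigr)^2$$

between a target (measured or idealized) and the composition, evaluated at
0.1 cm depth increments. Non-negativity is a physical constraint — weights
are fluences — so the fit is a non-negative least-squares (NNLS) problem,
convex and deterministic; we solve it with `pracma::lsqnonneg()`.

## The synthetic pristine peak

`generate_pristine_peak()` builds a peak from four scalar knobs:

* a Bragg–Kleeman stopping-power core $D_0(d) \propto (R-d)^{1/p-1}$ with
  $p = 1.77$, whose integrable singularity at the range $R$ is handled by
  exact cell averaging on an internal 0.01 cm grid;
* a linear nuclear-background ramp `background_fraction * (1 - d/R)`
  (default 0.02 of the peak maximum);
* a near-flat entrance pedestal scaled by `entrance_fraction` (default
  0.05), shaping the PDD(0.5)/peak ratio;
* Gaussian convolution of width `distal_spread_sigma` (cm), the proxy for
  beam energy spread.

After convolution the internal range is shifted iteratively until the
distal 90% crossing *measured on the requested output grid* equals the
requested `range_d90` within 0.02 cm, so the calibration contract holds for
the curve a user actually receives. Increasing `distal_spread_sigma` raises
the normalized entrance dose and stretches the distal 80–20% falloff — the
qualitative behavior commissioning source tuning relies on — and both
responses are monotone by construction (smoothing lowers the peak without
touching the entrance plateau).

Default `distal_spread_sigma` is $\max(0.012\,R^{0.935},\ 0.15)$ cm: the
first term is a Bortfeld-style range-straggling estimate, the 0.15 cm floor
stands in for the machine energy spread that dominates shallow-range
configurations (a shallow beam has passed through the most degrading
material). The defaults together give pristine entrance doses of roughly
20–35% of the peak and fully modulated SOBPs whose entrance sits at 85–95%
of the plateau — the structure the width metric (proximal-95% to
distal-90%) presupposes. These values were fixed once, while designing the
generator against the qualitative behaviors above, and are not tuned per
analysis.

Measurement noise (`add_measurement_noise()`) is multiplicative Gaussian
per point with an explicit seed, clipped at zero, with no autocorrelation —
the simplest model consistent with point-by-point scan data. What the
generator does *not* emulate: nuclear halo shape changes with depth,
detector volume averaging, positional scan jitter, or any lateral-depth
coupling; passing tests therefore validate the algorithms, not transport
fidelity on real machines.

## Wheel, pulses and fluence

A wheel is a list of angular sectors with non-decreasing pullbacks and an
optional blocked (brass-wedge) sector; a pulse train fires every `period`
seconds at 600 rpm, so the default 2 ms period gives exactly 50 pulses per
rotation. Each pulse has a uniform angular footprint (default 7.2°, making
consecutive pulses tile the circle); a footprint overlapping a step
boundary splits its fluence proportionally to angular overlap — the
"partial shining" case — and blocked sectors absorb fluence silently.
Pulses reaching an angular gap are an error: a wheel must be fully
specified wherever the beam can land. Fluence equalization gives every hit
step the same protons per rotation (3×10⁶ by default), exactly when no
pulse straddles a boundary and in the NNLS sense otherwise; steps hit by no
pulse are flagged, never silently dropped.

The default wheel geometry is the package's own choice (no public layout
exists for the real wheels): uniform pullback increments of about
1.5 × the distal smearing width (rounded to 0.05 cm, floor 0.2 cm), so
adjacent peaks overlap enough for a sub-1% plateau, with a 30° blocked
wedge. We initially tried a fixed 14-step wheel for every modulation width;
for 20 cm modulation that spaces peaks 1.5 cm apart against falloffs of
0.3–0.5 cm and the plateau ripples at the 10–20% level no matter the
weights, so the step count now scales with the modulation width. A 14-step
wheel still arises naturally for deep-group-like beams (10 cm modulation at
0.7 cm steps).

## Fitting a flat SOBP

`synthesize_sobp()` mirrors the machine's two-stage setup:

1. **Weight fit.** NNLS against a flat target over the *plateau* window.
   Two details matter, both found the hard way:
   * the window excludes the proximal entrance region. An idealized target
     is zero there, but physical peaks deposit ~30% entrance dose, and
     forcing the fit to cancel the uncancellable sags the plateau by
     10–35%;
   * the target's distal edge follows the deepest peak's own falloff
     (scaled, anchored so its D90 sits at the requested range). Any fixed
     taper the peaks cannot reproduce — too fast or too slow — makes NNLS
     overshoot the distal crest by several percent.
   For measured targets, which carry a physical entrance, `fit_weights()`
   keeps the conventional default window from 0.5 cm (excluding surface
   artifacts) to the distal 1% point.
2. **Width trim.** The fitted SOBP's proximal shoulder falls off at the
   pace the peak widths allow, so its proximal-95% depth lands slightly
   shallow of the request. The shallowest steps' weights are removed one
   at a time and the boundary step is scaled by a fraction found by
   bisection on the recomputed width — the weight-space analogue of stop
   pulses. Full-modulation requests (plateau reaching the surface) are
   left untrimmed.

## Stop pulses and modulation adjustment

At the pulse level, `pulse_weights_for_steps()` converts fitted step
weights into per-pulse beam-current multipliers by NNLS on the
pulse-to-step fluence-fraction system (a pulse cannot be physically split,
so with straddling pulses the reproduction is a least-squares compromise).
`stop_pulse_curve()` then removes pulses one at a time — pulses landing on
the shallowest steps first, ties broken by pulse index descending, a
deterministic order the package fixes since only "shallower peaks first"
is physically implied — recording the SOBP width after each removal.

`adjust_modulation()` looks up the bracketing integer stop pulses and
linearly interpolates the fraction of the last pulse to apply. On
libraries whose width-versus-pulse curve is locally nonlinear the
interpolated fraction can miss the request by a few tenths of a
centimetre, so by default the fraction is then polished by bisection
(width is monotone in the applied fraction); this restores the machine's
0.1 cm width granularity across the full sweep. Exact idempotence —
re-requesting an already-achieved width changing nothing — holds at
tabulated integer-stop widths; between them the achieved width is only
piecewise-linearly related to the fraction, so idempotence there is
approximate at the 0.1 cm granularity.

## Metrics and comparison conventions

All crossing metrics interpolate linearly within grid intervals; distal
crossings take the deepest interval crossing the level from above,
proximal the shallowest crossing from below, which resolves multi-crossing
ambiguity on noisy curves. Depth curves normalize to maximum = 100 (an
alternative plateau-mean normalization is available and agrees on D90 for
flat SOBPs); profiles normalize to 100 at the field center, the midpoint
of the two 50% crossings, so an off-center maximum may exceed 100. A curve
still at or above 95% at its first grid point (full modulation) takes the
first grid depth as its proximal-95% — the convention that makes
full-modulation widths well defined.

Profile flatness is $|D_{max}-D_{min}|/(D_{max}+D_{min}) \times 100$ over
the middle 80% of the field, with "field size" taken as the FWHM (the only
field-width measure the package computes); symmetry is
$|D_L - D_R|/(D_L + D_R) \times 100$ with trapezoidal integrals over the
left and right halves of that same middle-80% region. Both are reported as
absolute values — the defining ratios are signed, but reports
conventionally list magnitudes. Whether the symmetry integrals should run
over the full field or the middle 80% is a genuine convention choice; we
use the middle 80% for consistency with flatness. Penumbra is the per-side
80–20% crossing distance; comparisons use the left/right mean. Comparison
rows follow measured − simulated for signed differences, absolute values
for entrance-dose, penumbra and FWHM differences, and group summaries
average absolute values; rendering rounds to 0.1% / 0.01 cm for display
while rows retain full precision.

## Numerical choices

* Internal supersampling at 0.01 cm with linear resampling to the output
  grid avoids convolution artifacts at 0.1 cm; the Gaussian kernel is
  truncated at ±6σ and renormalized; dose is reflected at the surface and
  zero-padded distally.
* Range calibration iterates at most 25 times to a 0.002 cm tolerance on
  the output grid — well inside the 0.02 cm contract and tight enough
  that differences of paired calibrated peaks are meaningful at the
  0.005 cm level.
* Width bisections run 30–40 halvings (resolution ≪ 0.001 cm in the
  control variable); stop conditions test the recomputed metric, never the
  control variable.
* Curve CSVs print the shortest decimal representation that round-trips
  the double exactly, so write–read is bit-identical and read–write
  reproduces the file.
* The energy-spread parameter is a depth-space sigma in cm, not ΔE/E; for
  a rough mapping, σ ≈ 2.5 · (ΔE/E) · R.

## Problem sizes

The shipped tests and the acceptance script use libraries of 14–61 peaks
on 0.1 cm grids of 170–350 points, a 50-pulse train, 100-curve randomized
crossing suites, and a 2–20 cm width sweep in 0.1 cm requests; these sizes
exercise every code path while keeping a full run in well under a minute
of compute.

## Known limitations

* The synthetic peak is a four-knob phenomenological shape; it reproduces
  the qualitative commissioning behaviors but not absolute dosimetry, LET,
  or field-size dependence of output.
* Wheel geometry, pulse footprint and repetition period are plausible
  defaults, not vendor values; the pulse period in particular is exposed
  as a parameter because the machine's true repetition rate is only
  implied (~50 pulses per rotation at 600 rpm ⇒ ~2 ms).
* Whether a boundary-straddling pulse broadens the delivered peak
  (material mixing) or splits fluence between two clean peaks is not
  publicly specified; the package implements fluence splitting.
* Group summaries and report schemas follow the commissioning-report
  conventions; gamma analysis and 2-D/3-D dose comparison are out of
  scope.
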