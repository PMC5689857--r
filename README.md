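# sobptools

Desk-scale tools for the computational layer of passively scattered proton
beam commissioning. A passively scattered machine sweeps a pulsed beam over
a rotating range modulator wheel (RMW): each wheel step pulls the pristine
Bragg peak back in depth, and per-pulse beam-current weights shape the sum
of the pulled-back peaks into a spread-out Bragg peak (SOBP) with a flat
plateau across the target. Medical physicists commissioning such a unit fit
those weights to measured data, trim the modulation width with stop pulses,
and compare simulated against measured scans with a standard battery of
scalar metrics. `sobptools` implements all of that machinery, with
synthetic pristine-peak and lateral-profile generators standing in for
particle transport, so the algorithms can be developed, tested and taught
without a treatment head.

The core model is the weighted superposition

    D(d) = sum_i w_i p_i(d),     w_i >= 0

with the weights minimizing the sum of squared errors

    SSE = sum_{d1..d2} (D_m(d) - D_s(d))^2

on a 0.1 cm depth lattice — a non-negative least-squares problem, convex
and deterministic. Around it the package provides:

* **`beam_models`** — synthetic pristine Bragg peaks (Bragg–Kleeman core,
  nuclear background, entrance pedestal, Gaussian energy-spread smearing,
  range-calibrated to the requested distal 90% depth), erf-edged lateral
  profiles, and seeded multiplicative measurement noise.
* **`rmw_pulse`** — pulse timing on the wheel, boundary "partial shining"
  fluence splitting, per-step fluence equalization, and per-step peak
  libraries.
* **`sobp_builder`** — SOBP composition, NNLS weight fitting
  (`fit_weights`), flat-SOBP synthesis with width trimming
  (`synthesize_sobp`), stop-pulse curves and fractional-stop-pulse
  modulation adjustment (`adjust_modulation`).
* **`beam_metrics`** — D90, D20, proximal-95%, PDD(0.5), SOBP width,
  penumbra, FWHM, flatness and symmetry, with documented crossing and
  normalization conventions.
* **`compare_report`** — measured-versus-simulated comparison rows and
  group summaries at report precision, plus the published commissioning
  comparison tables as package data.
* **`io_cli`** — curve/weight/wheel file formats, the 24-configuration
  registry with group capability validation, and a CLI wrapper
  (`inst/exec/sobptools`).

## Worked example

Build a beam with 16 cm range and 10 cm modulation, inspect it, and trim
the modulation to 6 cm with a fractional stop pulse:

```r
library(sobptools)

wheel <- default_rmw(16, 10)
peaks <- build_step_peak_library(wheel, pristine_peak_params(16), depth_grid(18))
fit   <- synthesize_sobp(peaks, 16, 10)
fit
#> <sobp_fit> requested range 16.00 / modulation 10.00 cm -> achieved width 10.00 cm,
#>   D90 15.98 cm, plateau flatness 0.42%
fit$metrics
#> <pdd_metrics> D90 15.98 cm | D20 16.26 cm | prox95 5.98 cm | width 10.00 cm | PDD(0.5) 79.6%

map <- map_pulses_to_steps(wheel, pulse_train())   # 50 pulses per rotation
u   <- pulse_weights_for_steps(peaks, map, fit$weights)
sp  <- stop_pulse_curve(peaks, map, u)
sp
#> <stop_pulse_curve> 47 entries, width 10.13 -> 0.18 cm
adjust_modulation(sp, 6, peaks, map)
#> <adjusted_weights> fractional stop pulse 19.34 -> achieved width 6.00 cm
```

The achieved width is recomputed from the recomposed curve with the
proximal-95% to distal-90% metric, so "6.00 cm" is a measurement of the
delivered dose profile, not an echo of the request. Group summaries of the
published commissioning comparison:

```r
tab <- commissioning_table("pdd")
group_summary(tab[tab$group == "large", ], "large")
#> <group_summary> large (n=12): mean |PDD(0.5) diff| 0.9% (0.4..1.5),
#>   mean |D90 diff| 0.06 cm (0.04..0.09)
```

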