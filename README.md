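# depthresp

Contactless respiratory monitoring from depth-camera video.

Bedside tidal-volume measurement normally requires an airflow sensor in
the patient's airway, which is why it is rarely done outside mechanical
ventilation. An overhead depth camera offers a contact-free alternative:
as the chest rises and falls, the per-pixel distance between camera and
thorax mirrors the volume of air moved. `depthresp` implements the full
processing chain from depth frames to ventilator-equivalent parameters,
together with a synthetic breathing-torso phantom that makes every stage
verifiable by parameter recovery — no camera or patient data needed.

## Method

Inside an oriented-bounding-box region of interest (ROI) covering the
thorax, every pixel `(u, v)` with depth `d` (mm) is unprojected through
the pinhole model

    x = (u − cx)·d/fx,  y = (v − cy)·d/fy,  z = d,

and its 3D surface area `a(p)` (mm²) is the cross-product magnitude of
central-difference tangents built from the unprojected immediate
neighbours — exact on tilted surfaces, unlike the flat `d²/(fx·fy)`
approximation. With the area map frozen from a denoised reference
surface, the per-frame thoracic volume is

    V(k) = Σ_ROI d(p, k)·a(p) / 1000   [mL],

inverted and zeroed (`v′ = −(V − V(1))`, inspiration positive), low-pass
filtered (linear-phase FIR, order 10, 2 Hz cutoff ≙ 120 breaths/min),
and segmented into trough–peak–trough cycles (minimum peak distance
15 frames at 30 FPS, prominence ≥ 0.2 of the signal range). From the
cycles and the flow `dV/dt` the report derives RR, per-cycle and mean
Vt, minute ventilation (≡ mean Vt × RR), Ti, Te, I:E, and PIF/PEF.

The ROI comes either from a fixed user-drawn box or from a pluggable
detector; the shipped motion-variance heuristic (per-pixel temporal
depth deviation, 0.98-quantile threshold, minimum-area rotated
rectangle around the largest connected component) stands in for a
learned thorax detector behind the same contract.

## Worked example

```r
library(depthresp)

cfg <- phantom_config("adult", seed = 1)   # Vt 400 mL, RR 15, 30 s @ 30 FPS
gen <- generate_sequence(cfg)              # depth frames + analytic truth
res <- analyze_sequence(gen$sequence, roi = "variance")
res$report
#> <respiratory_report>
#>   RR       15.0 breaths/min   (6 complete cycles)
#>   Vt      400.7 mL            MV    6010 mL/min
#>   Ti       1.40 s   Te  2.60 s   I:E  1:1.86
#>   PIF       705 mL/s  PEF    707 mL/s  (difference convention)

evaluate_against_truth(res$report, res$filtered, gen$truth)
#> $pearson_r      0.999988
#> $vt_mape_pct    0.1695
#> $rr_error_bpm   0
#> $mev_error_pct  0.1695
```

RR is exact to the cycle-counting resolution, tidal volume is recovered
to a few tenths of a percent, and the filtered waveform tracks the true
volume trace with r > 0.9999. The `difference`-convention peak flows are
flow-extremum differences (≈ twice a ventilator's per-phase reading);
`peak_flows(..., convention = "standard")` gives the ventilator-style
values.

A command-line interface wraps the same functions
(`exec/depthresp`): `simulate --config cfg.json --out dir/`,
`analyze --in dir/ --roi variance|fixed:cu,cv,w,h,deg --out report.json
[--stream]`, and `evaluate --report report.json --truth truth.csv`.
Sequences are stored as a JSON sidecar plus one 16-bit little-endian
blob per frame (0.1 mm units, 0 = invalid).

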