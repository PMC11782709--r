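---
title: "Steady-state background phase in phase-contrast MRI: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state background phase in phase-contrast MRI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsteady)
```

## The problem

Phase-contrast MRI measures velocity as the phase difference between a
flow-compensated and a flow-encoded steady-state gradient-echo acquisition,
`v = (Δφ/π)·venc`. Background phases — concomitant-field and eddy-current
offsets that differ between the two gradient waveforms — bias the
measurement and are conventionally removed by masking static tissue,
fitting a second-order polynomial to its time-averaged phase and
subtracting the extrapolated field.

A steady-state GRE sequence, however, assumes a *constant* net phase per
repetition. Because the background phase accompanies only the flow-encoded
gradient set, interleaving the encodings (every TR, or every cardiac cycle)
makes the per-TR phase alternate and disrupts the steady state. Transverse
magnetization that survives the spoiler gradient carries phase memory
across repetitions, so the echo phase is no longer simply the injected
phase: an additional, history-dependent offset appears. This package exists
to quantify that offset and its effect on the polynomial correction.

## The voxel model

A voxel is an ensemble of isochromats on a grid of `n_slice` through-slice
positions × `n_spoiler` intravoxel spoiler positions `u = k/n_spoiler`.
Per repetition the simulator applies, in order:

1. **RF excitation** with flip `α·s(z)`, where `s(z)` is the slice profile —
   the Fourier transform of the pulse envelope (small-tip approximation),
   normalized to 1 at the slab center and truncated where its magnitude
   falls below 1 % of the peak. The rotation axis azimuth follows the RF
   phase schedule: zero for FISP, the quadratic recurrence
   `φ_k = φ_{k-1} + k·50°` for FLASH (receiver demodulated with the same
   phase).
2. **Background/flow phase injection** on flow-encoded repetitions only: a
   rotation of the transverse plane by `φ = (input %venc/100)·π`, placed
   between excitation and echo where the asymmetric encoding gradients act.
   The flow-compensated repetitions carry zero input phase, so an ideally
   spoiled sequence measures exactly the injected phase and every departure
   from it is the steady-state error under study. (Placing the injection
   after the echo instead would hide the input phase from a memoryless
   voxel entirely, which contradicts both the ideal-spoiling limit and the
   near-exact phase recovery of RF-spoiled sequences; the within-TR
   position is otherwise immaterial because it commutes with relaxation.)
3. **Relaxation** to the echo time TE, **signal sampling** (demodulated
   complex mean over isochromats), relaxation to the end of the TR.
4. **Gradient spoiling**: each isochromat's transverse phase advances by
   `2π·u`. The increment repeats every TR, so spoiler phase accumulates and
   echo pathways survive — this is what distinguishes FISP from ideal
   spoiling. A test-only `"perfect"` mode zeroes the transverse plane each
   TR; a `"fresh"` mode resets the full magnetization and emulates strong
   in-flow.

Relaxation is lumped into two intervals per TR (before/after the echo);
intra-pulse relaxation is neglected since pulses are short against T2. The
rotation convention is left-handed with flip 90° at RF phase 0 taking +z to
+y; phase-contrast differences are invariant to this choice.
Off-resonance across the slice is not modeled separately: the background
phase enters as a single per-voxel rotation.

## Sequence schedules

A cardiac cycle is `n_tr_per_cycle = 150` repetitions of `TR = 6.8` ms
(1020 ms R-R interval): `n_trigger_tr = 10` steady-state-trigger TRs
followed by a 140-TR acquisition window. RF and gradients never pause.
TR-interleaved encoding alternates compensated/encoded every repetition,
including through the trigger period. ECG-interleaved encoding holds one
encoding per cycle and switches at the end of the acquisition window, so
the trigger TRs already run the next cycle's encoding.

Phase contrast pairs the window echoes: consecutive (encoded, compensated)
repetitions within a cycle in TR mode; index-by-index pairing of an encoded
cycle with the adjacent preceding compensated cycle in ECG mode. The sign
convention makes the result converge to the injected phase in the
perfect-spoiling limit, and values are wrapped to `(−π, π]`. The
steady-state deviation is the mean measured-minus-injected phase, in
percent of venc, over the last 20 encoding pairs; the first two cycles are
discarded as warm-up in the sweep functions. All %venc quantities are
venc-independent by construction (the injected phase is specified as a
fraction of π).

## Key parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `tr`, `te` | 6.8 ms, `tr/2` | repetition/echo time; TE only attenuates both encodings equally, the phase contrast does not depend on it |
| `flip` | 10° | nominal flip angle |
| `rf_spoil_increment` | 50° (FLASH) | quadratic RF-phase increment |
| `n_tr_per_cycle`, `n_trigger_tr` | 150, 10 | cardiac cycle structure |
| `n_cycles` | 7 | simulated cycles (TR mode settles after one) |
| `n_slice`, `n_spoiler` | 33, 256 | isochromat discretization |
| `venc` | 30 cm/s | velocity encoding (results in %venc unaffected) |

The exact excitation pulse of the reference acquisitions is not available,
so the default is a reconstruction: a Hann-windowed sinc with
time-bandwidth product 2. A sensitivity scan over windows
(Hann/Hamming/rectangular/Gaussian) and time-bandwidth 1.5–4 moves the
FISP deviation at 5 %venc input by under 0.03 %venc and the FLASH residual
at 20 %venc by under 0.005 %venc, so the conclusions do not hinge on the
pulse details; a hard pulse (flat profile), by contrast, changes both
noticeably — the slice-profile wings carry low flip angles whose pathways
spoil differently, and they are a real feature of any sliced acquisition.

`n_spoiler = 256` was chosen by convergence: doubling to 512 changes
deviations by about 1e-5 %venc, while 20–60 spoiler positions alias the
RF-spoiling pathway structure badly enough to corrupt FLASH results by an
order of magnitude. `n_slice = 33` vs. 129 changes the FISP deviation by
3e-3 %venc. The bundled tests run coarser grids for speed where only FISP
(which converges much faster) is involved, and at least 128 spoiler
positions wherever FLASH is quantified.

## What the simulation reproduces

At the study conditions (long-relaxation gel, T1/T2 = 2000/160 ms):

* TR-interleaved FISP settles on a phase-contrast steady state within one
  cycle, but its value deviates from the injected phase — about +2 %venc at
  a +5 %venc input — growing with the input magnitude and odd in its sign.
* TR-interleaved FLASH is robust: the deviation stays below 0.1 %venc over
  the full ±20 %venc range, far inside the 0.4 %venc accuracy criterion
  usually quoted for background phase after correction.
* ECG-interleaved encoding perturbs every cycle: the phase contrast decays
  toward the injected value through the cardiac cycle without reaching it
  (FISP), or oscillates with smaller amplitude (FLASH).
* Longer T1 or T2 amplify all of these effects; very short relaxation
  times (≈10 ms) suppress them by an order of magnitude. The
  short-relaxation gel (720/40 ms) accordingly shows weaker perturbations
  than the long-relaxation gel (2000/160 ms).

These are the quantities `scripts/acceptance.R` recomputes and the test
suite asserts; none of them is stored — every number is produced by running
the simulator.

## The synthetic phantom and its limits

`make_scene()` builds three scenes: the two gel discs (115 mm diameter,
offset 120 mm in-plane, under a smooth polynomial background-phase field
rising with distance from the isocenter, spanning roughly ±10 %venc over
the field of view) and a vessel demo — a tissue disc with a small vessel
carrying a one-peak systolic waveform. The background field of the vessel
scene is deliberately one-signed over the scene, as it is over an
off-isocenter limb; with a field that changes sign across the static
tissue, the opposite fit biases would largely cancel in the net flow and
the sequence-dependent correction bias would be masked.

`render_timeseries()` runs the single-voxel simulation per pixel (pixels
sharing a tissue label and a background phase quantized to 0.05 %venc share
one run; the cache can be disabled for exact pixelwise oracles) and stacks
the window echoes of the final cycle (pair) into per-cardiac-phase
compensated/encoded images, optionally decimated to 35 phases by averaging
consecutive pairs and degraded with complex Gaussian noise under the scene
seed.

What the phantom does *not* emulate: coil sensitivities and parallel-imaging
reconstruction, k-space segmentation and ordering, concomitant-field
spatial structure (the injected field is a generic smooth polynomial, not
gradient physics), flow effects on the steady state inside the vessel
(vessels are rendered in a fresh-spin in-flow idealization, which the
strong-inflow limit justifies for small vessels), table vibrations, R-R
variability, and phase wrapping (velocities must stay below venc). Passing
tests therefore validate the steady-state mechanism and the correction
pipeline's arithmetic, not scanner-specific artifact levels.

## The correction and why it fails

`static_mask()` keeps pixels whose time-averaged magnitude is ≥20 % of the
image maximum and whose velocity temporal SD is ≤10 % of the image maximum
SD. The SD criterion is applied to the velocity series (a switch selects
magnitude-SD instead): the fit targets phase, and the mask must reject
pulsatile flow. A small numerical floor handles the all-static case where
the maximum SD is pure roundoff. `fit_background()` is unweighted OLS on
the six-term second-order polynomial in normalized pixel-center coordinates
(origin at the isocenter, x right, y down, both axes scaled by FOV/2); a
magnitude-weighted fit is available. The identical basis and coordinate
convention are used by the scene generator, so exact-polynomial recovery is
testable to 1e-9. No phase unwrapping is performed — synthetic truth keeps
|φ| < π.

With ideal spoiling the pipeline is exact: the static phase *is* the
polynomial field, the fit recovers it, corrected static velocity vanishes
and vessel flow matches ground truth. With a real spoiled steady state the
static-tissue phase is the injected field *plus* the steady-state error,
which depends nonlinearly on the local field value and on tissue relaxation
times — so the fitted polynomial is biased, the extrapolation to the vessel
(whose in-flowing spins do not share the error) subtracts the wrong field,
and the corrected flow depends on the sequence flavor: time-averaged
ECG-interleaved FISP *underestimates* the background phase (over-corrected
flow stays high), TR-interleaved FISP *overestimates* it (flow is pushed
low), and FLASH sits in between. `exp_correction_bias()` demonstrates both
orderings on the vessel scene and their disappearance under ideal spoiling.

## Numerical and design notes

* **Phase injection site.** Within-TR placement of the lumped background
  phase rotation is before the echo sample (see above); this is the only
  placement consistent with the ideal-spoiling limit measuring the injected
  phase.
* **RF-spoiling jitter.** Imperfect RF spoiling leaves a small TR-to-TR
  phase jitter (~1e-3 rad at converged discretization) even at zero input
  phase. Consequently the zero-input identity and the odd symmetry of the
  deviation curve are exact for FISP (machine precision, by a reflection
  symmetry of the spoiler grid) but only hold to the jitter scale
  (~1e-3…1e-2 %venc) for FLASH; tests assert them at those scales.
* **Steady-state settling.** The TR-interleaved pair-to-pair drift is
  ~1e-4 rad one cycle in and falls below 1e-6 rad by the seventh cycle;
  deviations average the last 20 pairs of 7 cycles.
* **Warm-up.** Sweeps discard the first 2 cycles before averaging or
  plotting (configurable).
* **Ties and degenerate inputs.** Unpaired trailing window repetitions are
  dropped with a warning; ECG runs need ≥2 cycles; the polynomial fit
  refuses <6 masked pixels or a rank-deficient design with explicit errors;
  T2 > T1 grid points are skipped with a warning in relaxation sweeps.
* **Problem sizes.** The bundled tests simulate compact configurations
  (7–17 slice × 24–128 spoiler isochromats, 24–60 TR cycles, 12×12–20×20
  phantom grids); the acceptance script runs the full 33 × 256 voxel and
  150-TR cycles. These sizes keep the entire suite around a minute on one
  core while every assertion still runs the genuine mechanism.

## Known limitations

The model treats the background phase as a spatially smooth injected field,
not as computed gradient physics; it ignores flow-induced steady-state
effects (fresh-spin vessels), in-plane encoding, retrospective gating and
acceleration. The reconstruction of the excitation pulse is a stand-in for
an unavailable product pulse, with the sensitivity analysis above bounding
its influence. FLASH results require fine spoiler discretization; treat any
FLASH quantity computed with fewer than ~100 spoiler isochromats as
unreliable.
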