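# pcsteady

Steady-state background phase errors in phase-contrast MRI, simulated from
first principles.

Phase-contrast (PC) MRI encodes through-plane velocity into the signal phase
of a steady-state gradient-echo (GRE) sequence: two acquisitions with
different first gradient moments (flow-compensated and flow-encoded) are
subtracted, and `v = (delta-phi / pi) * venc`. Spurious *background phases*
from concomitant fields and eddy currents corrupt the measurement and are
routinely removed by fitting a low-order polynomial to the phase of static
tissue and extrapolating it over the vessel.

There is a third, less familiar contribution. The background phase itself
alternates with the encoding gradients, so it violates the GRE steady-state
condition of a constant net phase per repetition. The surviving transverse
coherence pathways then convert the alternating input phase into an
additional, tissue- and sequence-dependent phase error. This package
simulates that mechanism with an isochromat Bloch model and demonstrates its
consequence: the standard static-tissue correction cannot remove it, and
different sequence flavors (FISP vs. FLASH contrast, TR- vs. ECG-interleaved
encoding) disagree after correction.

`pcsteady` provides:

* **Bloch engine** — a single-voxel isochromat ensemble (realistic slice
  profile from the Fourier transform of the RF pulse, 2-pi gradient spoiler
  per repetition, optional quadratic RF spoiling) with the elementary
  operators `apply_rf()`, `relax()`, `precess_phase()`, `spoil_gradient()`,
  `read_signal()`.
* **Sequence simulator** — `run_sequence()` drives the ensemble through
  prospectively triggered PC-GRE schedules (FISP/FLASH, TR-/ECG-interleaved,
  steady-state trigger); `phase_contrast()`, `steady_state_deviation()`,
  `sweep_background()` and `sweep_relaxation()` extract per-cardiac-phase
  series and deviation metrics.
* **Phantom renderer** — `make_scene()` / `render_timeseries()` apply the
  voxel simulation per pixel under a smooth polynomial background-phase
  field, with an optional pulsatile vessel, noise, and NIfTI + JSON export.
* **Correction** — `static_mask()` (magnitude and temporal-SD thresholds),
  `fit_background()` (second-order 2D polynomial OLS), `apply_correction()`
  and `flow_rate()`; `correct_stack()` chains the full pipeline.
* **Experiments** — `exp_ecg_interleaved()`, `exp_tr_interleaved()`,
  `exp_relaxation()`, `exp_correction_bias()` reproduce the simulation
  studies end to end and write CSV/JSON outputs.

All results in percent of venc are venc-independent; 100 %venc corresponds
to a phase difference of pi.

## Worked example

Simulate a TR-interleaved FISP acquisition of a long-relaxation gel
(T1/T2 = 2000/160 ms) with a +5 %venc background phase on the encoded
repetitions:

```r
library(pcsteady)

cfg <- sequence_config(contrast = "FISP", interleave = "TR")
cfg
#> <pc_config> FISP, TR-interleaved | TR 6.8 ms, TE 3.4 ms, flip 10 deg, venc 30 cm/s
#>   7 cycles x 150 TR (10 trigger), 33 x 256 isochromats, gradient spoiling

series <- run_sequence(cfg, tissue_p2(), bg = 5) |> phase_contrast()
series
#> # A tibble: 490 × 8
#>    pair cycle phase_index time_ms dphi_rad magnitude pct_venc velocity_cms
#>   <int> <int>       <int>   <dbl>    <dbl>     <dbl>    <dbl>        <dbl>
#> 1     1     1           1    74.8    0.177    0.0624     5.64         1.69
#> 2     2     1           2    88.4    0.185    0.0577     5.88         1.76
#> 3     3     1           3   102      0.193    0.0535     6.14         1.84
#> # ...

steady_state_deviation(series, bg = 5)
#> [1] 2.05908
```

The measured phase contrast settles near 7 %venc although only 5 %venc was
injected: the steady-state disruption adds about **+2 %venc**. The same
experiment with RF-spoiled FLASH is two orders of magnitude cleaner:

```r
sw <- sweep_background(sequence_config(contrast = "FLASH", interleave = "TR"),
                       tissue_p2(), phi_list = c(-20, -5, 5, 20))
tidy(sw)
#> # A tibble: 4 × 6
#>   phi_pct_venc t1_ms t2_ms contrast interleave deviation_pct_venc
#> 1          -20  2000   160 FLASH    TR                     0.0641
#> 2           -5  2000   160 FLASH    TR                     0.0172
#> 3            5  2000   160 FLASH    TR                    -0.0172
#> 4           20  2000   160 FLASH    TR                    -0.0641
```

`autoplot(sw)` plots deviation against injected phase;
`exp_correction_bias()` runs the full synthetic-vessel pipeline and shows
that after static-tissue correction, ECG-interleaved FISP overestimates and
TR-interleaved FISP underestimates flow relative to FLASH.

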