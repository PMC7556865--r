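# aosloflow

Label-free adaptive-optics scanning-light ophthalmoscopy (AOSLO) with a
phase-contrast detection scheme makes translucent immune cells visible in
the living retina using near-infrared light alone, while a 15 kHz line scan
across a single vessel records every passing blood cell. `aosloflow` is an R
package for quantifying both physiologies from such recordings — and for
validating every step of that quantification against a synthetic video
generator with exact ground truth, so no instrument data are needed to test
the pipeline.

For whom: researchers analysing intravital retinal time-lapse imaging of
immune-cell behaviour and single-vessel blood flow (e.g. in ocular
inflammation models), and developers who need a fully testable reference
implementation of this measurement chain.

## The measurements

**Immune-cell dynamics.** Videos are de-sinusoided (resonant-scanner
distortion `x = (1-a)u + a(1-cos(pi u))/2`), registered by FFT
cross-correlation (with optional moving-object masking for fields dominated
by migrating cells), and temporally averaged in 5-frame windows. A heat-map
detector — a trainable ridge-regression filter-bank model or a classical
matched filter — yields per-frame probability maps thresholded at 0.90;
counts are averaged over the first 25 averaged frames (5 s) and converted
to cells/mm². Detections are linked by greedy mutual nearest neighbours and
quality-controlled; per cell the package reports

* displacement over 100 s (µm), and
* confinement ratio = displacement / path length in [0, 1]
  (1 = ballistic, → 0 = confined).

**Single-vessel hemodynamics.** In the space–time (kymograph) image of a
line scan, a cell moving at velocity `v` traces a streak of slope `v`;
shifted-column cross-correlation recovers that slope per time window, and
averaging over whole cardiac cycles cancels the pulsatile modulation
`v(t) = V0(1 + m sin(2π f_c t))`. Lumen diameter is the full width at half
maximum of the motion-contrast (temporal SD / mean) profile taken
perpendicular to the vessel axis. Flow combines both:

```
Q [nL/s] = k · (π/4) · D² [µm²] · V [mm/s] · 10⁻³
```

Longitudinally, relative changes of `V`, `D` and `Q` against baseline, the
arteriole-versus-venule flow-conservation regression (R² of paired percent
flow changes), and the `V/D²` ratio — which separates velocity-driven
(arteriole-like) from diameter-driven (venule-like) flow changes — are
computed per vessel cohort.

## Worked example

```r
library(aosloflow)

cfg <- pipeline_config(
  seed = 5, outdir = "demo_out", log_level = "quiet",
  detector = list(kind = "learned"),
  cell_video = list(frame_shape = c(128, 128), n_frames = 130, n_cells = 6))
report <- run_pipeline(cfg)

round(report$cells$count_first_25, 2)
#> [1] 6
round(report$cells$density_cells_mm2, 1)
#> [1] 207.6
round(report$cells$motility$mean_displacement_um, 2)
#> [1] 2.62
round(report$vessels$venule_dd_pct, 1)       # venule diameter change, %
#> [1]  0.0  8.4 30.5 12.3  2.8
round(report$vessels$arteriole_dv_pct, 1)    # arteriole velocity change, %
#> [1]  0.0 19.2 47.2 19.4  4.8
round(report$vessels$conservation$r_squared, 3)
#> [1] 0.99
```

The demo simulates a 130-frame field of 6 random-walking cells (the
first-25-frame count recovers the 6 simulated cells exactly; density is
count over the 170 µm × 170 µm field; the mean displacement of 2.62 µm is
over the 5 s the short demo spans, not the 100 s motility window) and one
arteriole/venule pair followed over five timepoints with conserved flow:
the venule carries its flow increase by dilating (+30.5% measured diameter
at the peak timepoint) while the arteriole carries its by speeding up
(+47.2% measured velocity), and the paired flow changes correlate with
R² = 0.99. `demo_out/` holds the detection/track/measurement CSVs, a
deterministic `report.json` (byte-identical for a fixed seed), the
effective configuration, a log, and figures.

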