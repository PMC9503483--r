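# beamvitals

Simulation and benchmarking of **non-contact vital-sign monitoring with a
60 GHz FMCW MIMO radar**, comparing phase-based breathing-rate (BR) and
heart-rate (HR) extraction **with and without delay-and-sum receiver
beamforming** across target distances and arrival angles.

Chest micro-motion `x(t)` (mm-scale breathing, sub-mm heartbeat) modulates
the echo phase at the chest's range bin by `4πx(t)/λ`.  Off-the-shelf
radars have directional antennas, so echo power — and with it heart-rate
accuracy — degrades away from boresight.  A 2 TX × 4 RX sensor forms an
8-element half-wavelength virtual uniform linear array; steering it with
the unit-modulus weights

```
w_n = exp(-jπ (n-1) sin θ),   n = 1 … 8
```

adds the channels coherently for arrival angle θ (amplitude gain 8,
noise gain √8).  The package provides:

* `simulate_recording()` / `slow_time_cube()` — per-virtual-channel complex
  IF synthesis for a breathing chest plus static clutter and complex noise
  (the synthetic stand-in for human recordings);
* `range_fft()`, `beam_scan()`, `estimate_aoa()`, `apply_beamforming()`,
  `phase_alignment_check()` — radar data cube, range–angle maps,
  delay-and-sum steering;
* `extract_vitals()` — clutter filtering, target detection, phase
  unwrapping, dual band-pass (BR 0.1–0.6 Hz, HR 0.8–2.2 Hz with
  breathing-harmonic notching), windowed spectral rates with moving-mean
  smoothing;
* `run_grid()`, `run_benefit_experiment()`, `mae()`, `improvement_pct()` —
  the 15-point distance×angle benchmark (0.9/1.2/1.5 m × 0/±20/±40°), both
  pipeline arms scored on the *same* cubes, MAE tables and improvement
  percentages.

See `vignettes/beamforming-methods.Rmd` for the model, parameter rationale
and limitations.

## Worked example

A subject at 1.2 m, 40° off boresight, breathing 16 /min with heart rate
72 beats/min, under noise heavy enough to break the single-channel arm:

```r
library(beamvitals)
cfg   <- radar_config()                     # 60 GHz, B = 3.89 GHz, 2x4 MIMO
scene <- make_scene(1.2, 40,
                    motion = chest_motion(f_br = 16/60, f_hr = 72/60),
                    noise_std = 60, seed = 42)
cube  <- slow_time_cube(cfg, scene, duration = 45, noise_model = "spectral")

estimate_aoa(beam_scan(cube))               # 41.4 deg (2 deg scan grid)

extract_vitals(cube, beamform = TRUE, angle = 40)
#> <vitals_result> 16 windows, beamformed @ 40.0 deg, target bin 31
#>   median BR 15.98 breaths/min, median HR 72.01 beats/min

extract_vitals(cube, beamform = FALSE)      # single-channel baseline
#> <vitals_result> 16 windows, single channel (no beamforming), target bin 31
#>   median BR 12.83 breaths/min, median HR 67.60 beats/min
```

Both arms find the chest at range bin 31 (31 × 3.86 cm ≈ 1.2 m).  With
beamforming the heart-rate MAE over the 16 windows is 0.08 beats/min;
without, phase unwrapping starts to break and the MAE is 6.15 beats/min —
an improvement of 98.7 %.  At boresight the two arms are nearly identical;
the benefit grows with the angle, which is exactly what `run_grid()` /
`run_benefit_experiment()` quantify.

## CLI

```sh
inst/cli/beamvitals simulate --config inst/extdata/grid15.ini --point 8 \
    --duration 60 --output cube.rds
inst/cli/beamvitals scan     --input cube.rds --output map.csv
inst/cli/beamvitals extract  --input cube.rds --output rates.csv [--no-beamform]
inst/cli/beamvitals evaluate --out-dir report/ --seeds 6 --duration 60
```
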