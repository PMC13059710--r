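# chemosignal

Quantitative analysis of the three assays used to measure repellent
chemotaxis of *Escherichia coli* away from oxidizing environments
(reactive oxygen species, ROS-generating antibiotics):

1. **Bead-assay motor analysis** — turn bead x/y trajectories into
   rotation direction, CW bias, reversal rates, and pre/post-stimulus
   Student's t comparisons. CW bias is the fraction of time a motor
   rotates clockwise, `CWbias = CWtime / (CWtime + CCWtime)`, the
   behavioral readout of CheA kinase activity.
2. **Single-cell E-FRET kinase activity** — convert three-channel
   fluorescence time series into photobleach-corrected apparent FRET
   efficiency and per-cell normalized kinase activity,

   ```
   E_app = (IDA − a·IAA − d·IDD) / (IDA − a·IAA + (G − d)·IDD)
   ```

   with bi-exponential bleach correction, single-label calibration of the
   bleed-through constants `a` and `d`, per-cell min–max normalization
   against saturating stimuli, and adaptation-time estimation.
3. **Defocused-ring 3D tracking** — infer cell heights inside a ~150 µm
   swarm colony from diffraction-ring diameters via a linear
   diameter-to-z calibration, estimate diameters from ring images to
   sub-pixel accuracy, and compare vertical distributions across
   conditions with paired t-tests on replicate means.

Every pipeline is paired with a seeded forward model (two-state switching
motor, step-stimulus kinase with adaptation, bleaching and cross-talk,
ring-image renderer), so all estimators are validated against known
ground truth without real microscopy data. The package targets
experimentalists analyzing bead, FRET, or swarm-imaging recordings, and
methodologists who need ground-truthed synthetic benchmarks of the same.

## Worked example

Simulate a wild-type motor exposed to a saturating oxidant at 60 s
(preset: 39.07 reversals/min baseline, 64.53 reversals/min repellent
response), then analyze the trajectory as one would a real recording:

```r
library(chemosignal)

model <- preset_switching_model("wt_peroxide")
sim   <- simulate_motor_trace(model, duration_s = 120, fps = 250, seed = 1)
ds    <- classify_direction(estimate_rotation(sim$trace))

summarize_motor(ds, window = c(0, 60))    # baseline
#> Motor summary over [0.0, 60.0] s
#>   CW bias        : 0.138
#>   reversal rate  : 42.00 /min
#>   mean speed     : 49.86 Hz

summarize_motor(ds, window = c(60, 120))  # after oxidant addition
#> Motor summary over [60.0, 120.0] s
#>   CW bias        : 0.259
#>   reversal rate  : 56.00 /min
#>   mean speed     : 49.81 Hz
```

The repellent response is visible as the jump in reversal rate and CW
bias after the stimulus; single-motor values scatter around the preset
statistics (here 42 vs the 39.07/min baseline target), and averaging
motors recovers them — `compare_pre_post()` runs the across-motor t-test.
`run_pipeline(run_config(...))` wraps simulate → write → analyze →
JSON summary for all three modules, and `write_motor_simulation()`
stores traces with ground-truth sidecars.

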