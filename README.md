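# srvpulse

Time-resolved Doppler OCT analysis of spontaneous retinal venous pulsation
(SRVP).

## The problem

Major retinal veins at the optic nerve head can pulsate with the cardiac
cycle — rhythmically collapsing and re-expanding. Clinically this has been
judged from en-face imaging (ophthalmoscopy, fundus video, scanning laser
ophthalmoscopy), which only sees the *transversal* vessel diameter. The
collapse, however, is predominantly *axial*: a cross-sectional, functional
measurement sees far more of it. Phase-resolved Doppler OCT provides exactly
that: complex-valued B-scan sequences in which the inter-A-scan phase
difference

$$\Delta\phi = \frac{4\pi\, n\, v_z\, \tau}{\lambda_0}$$

maps axial blood velocity ($\tau$ the A-scan period, $\lambda_0$ the centre
wavelength, $n$ the tissue index), so the perfused lumen can be delineated at
the borderline between static and dynamic tissue and tracked over the cardiac
cycle.

`srvpulse` is for researchers in functional ophthalmic imaging who need a
tested, reproducible implementation of that analysis:

* a **synthetic phantom generator** (`phantom_config()`, `phantom_preset()`,
  `simulate_complex_sequence()`, `simulate_slo_sequence()`) emulating
  single-channel 100 kHz and inter-A-scan-switched dual-channel 50 kHz
  acquisitions of a partially collapsing vein, with full ground truth;
* **Doppler processing** (`process_sequence()`,
  `phase_difference_tomogram()`, `demux_channels()`,
  `bulk_motion_correct()`, `phase_to_velocity()`);
* **lumen quantification** (`segment_flow_region()`, `measure_sequence()`,
  `pulsatility()`): per-frame transversal/axial diameter, perfused area,
  mean phase difference, flow proxy (mean phase × area), cardiac-cycle
  detection, pulsation amplitudes `(max − min)/max` and the
  area-vs-diameter sensitivity ratio;
* **dual-site pulse-wave analysis** (`estimate_delay()`, `pwv_from_delay()`,
  `check_flow_conservation()`);
* **ROI intensity pulsatility** in OCT and SLO-like video
  (`roi_mean_intensity()`, `compare_modalities()`);
* a **pipeline orchestrator** (`run_config()`, `run_pipeline()`) with YAML
  configuration, CSV/JSON outputs and a thin command-line wrapper in
  `inst/cli/srvp.R`.

Results are tibbles throughout, with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` visualisations. The methods vignette
(`vignettes/srvp-methods.Rmd`) documents the forward model, the automated
reader, and every numerical choice.

## Worked example

```r
library(srvpulse)

report <- run_pipeline(run_config(preset = "phantom_S2"))
print(report)
#> <srvp_report>
#>   diameter change: 19.3%  area change: 59.2%  ratio: 3.06
#>   flow oscillation: +/-20.0%
#>   OCT/SLO intensity correlation: 0.98
```

The preset simulates a 3.2 s, 24 fps Doppler OCT recording (SNR 25 dB) of a
vein whose axial semi-axis collapses by 50% and lateral semi-axis by 20% at
peak collapse. The pipeline then recovers, from the synthetic tomograms
alone: a maximum relative transversal-diameter change of ~20% (what an
en-face modality could see), a maximum relative perfused-area change of ~59%
(the tomographic measurement), and hence a detection-sensitivity ratio near
3 — the cross-sectional DOCT measurement is about three times more sensitive
to the pulsation than the transversal diameter. The flow proxy oscillates
within about ±20% of its mean, and the pulsatile lumen intensity in the OCT
data correlates strongly with the simulated SLO video of the same scene.

For a dual-site acquisition:

```r
flow <- run_pipeline(run_config(preset = "phantom_flow"))
tidy(flow$pulse_wave)
#> # A tibble: 1 x 9
#>   delay_s delay_frames detectable peak_r pwv_mm_s max_resolvable_pwv_mm_s ...
```

At 24 fps and 0.9 mm site separation a pulse wave travelling at ≥100 mm/s
produces a delay far below one frame interval, so the package reports it as
not detectable (maximum resolvable PWV: 0.9 mm × 24 fps = 21.6 mm/s) rather
than quoting a spurious velocity — while the flow-conservation correlation
between the two sites remains near 1.

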