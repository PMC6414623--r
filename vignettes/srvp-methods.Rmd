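---
title: "Quantifying spontaneous retinal venous pulsation with Doppler OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spontaneous retinal venous pulsation with Doppler OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srvpulse)
```

## The problem

Spontaneous retinal venous pulsation (SRVP) is the rhythmic, cardiac-synchronous
caliber oscillation of major retinal veins at the optic nerve head. Clinically it
has mostly been assessed from en-face imaging (ophthalmoscopy, fundus video,
scanning laser ophthalmoscopy), which only sees the *transversal* (lateral)
vessel diameter. Cross-sectional Doppler OCT sees the full lumen: both the
axial-dominant caliber collapse and the flow signal inside it. This package
implements a complete, testable analysis chain for such recordings:

1. a **phantom generator** producing complex-valued B-scan sequences of a
   partially collapsing vein with known ground truth,
2. **Doppler processing** (phase-difference tomograms, channel de-interleaving,
   bulk-phase correction),
3. **lumen quantification** (dynamic-region segmentation, per-frame diameter /
   area / mean phase / flow proxy, cardiac-cycle detection, pulsation
   amplitudes, the area-vs-diameter sensitivity ratio),
4. **dual-site pulse-wave analysis** (delay, PWV detectability, flow
   conservation), and
5. **ROI intensity pulsatility** in OCT and SLO-like video.

Because no raw in-vivo recordings of this kind are publicly deposited, the
phantom is the package's reference instrument: every quantitative claim the
package makes is validated as parameter recovery on calibrated phantoms.

## The forward model

### Doppler contrast

Phase-resolved OCT measures axial scatterer motion between successive A-scans.
For inter-A-scan period $\tau$, centre wavelength $\lambda_0$ and tissue group
index $n$, a scatterer moving with axial velocity $v_z$ imprints a phase
difference between laterally adjacent A-scans of

$$\Delta\phi \;=\; \frac{4\pi\, n\, v_z\, \tau}{\lambda_0},$$

wrapped to $[-\pi, \pi)$. `phase_to_velocity()` inverts this relation; the
absolute velocity $v = v_z/\cos\theta$ is only defined when the Doppler angle
$\theta$ is usefully far from 90° (the package flags $|\cos\theta| \le 0.05$,
i.e. $\theta$ within about 2.9° of perpendicular, as undetermined).

The acquisition geometry mirrors a swept-source prototype at
$\lambda_0 = 1045$ nm and a 100 kHz sweep rate. In double-channel mode two
beams image laterally separated B-scans (default 0.9 mm apart) with
inter-A-scan switching, so each channel runs at 50 kHz ($\tau$ doubles, and so
does $\Delta\phi$ for the same velocity).

### Vessel and cardiac models

The lumen cross-section is an ellipse whose semi-axes are modulated
independently by the collapse waveform $c(t) \in [0,1]$:

$$a(t) = a_0\,(1 - m_\text{lat}\, c(t)), \qquad
  b(t) = b_0\,(1 - m_\text{ax}\, c(t)), \qquad
  A(t) = \pi\, a(t)\, b(t).$$

At full collapse the relative area reduction is
$1 - (1-m_\text{lat})(1-m_\text{ax})$. The ellipse is deliberately the minimal
parametric shape consistent with the axial-dominant collapse
($m_\text{ax} > m_\text{lat}$); real collapses are irregular, and nothing in
the analysis chain assumes ellipticity.

The cardiac driver is an arterial pulse (Gaussian systolic peak plus dicrotic
bump, per-cycle period jittered by a heart-rate-variability fraction), from
which the venous flow profile is derived by Gaussian low-pass filtering
(default 0.08 s), reproducing the washed-out venous pulse shape. The collapse
waveform is the venous waveform with a configurable phase offset, zero by
default so that collapse peaks coincide with arterial systole. Flow through
the collapsing section is conserved by default: the centreline velocity scales
with $A_0/A(t)$ on top of the flow waveform, whose peak fractional deviation
from its mean is `flow_mod`.

Blood flow is parabolic on the elliptical lumen, zero at the wall, projected
through the Doppler angle. A preset (`phantom_along`) sweeps the Doppler angle
linearly through 90° across the scan to reproduce the characteristic sign flip
of the Doppler signal along an inclined vessel.

### Speckle and noise

Static tissue is fully developed speckle: per-pixel amplitudes follow the
Rayleigh law of a circular complex Gaussian field, with depth-decaying mean
intensity and a signal-free vitreous band above the tissue. The deterministic
phase is laterally coherent (the fully-oversampled-beam limit), so a noise-free
static phantom has exactly zero inter-A-scan phase difference — the property
that makes "static vs dynamic" a well-defined borderline. Phase noise enters
physically, through additive complex Gaussian noise that sets the configured
lumen SNR (default 25 dB); in this regime the phase-difference noise scales as
SNR$^{-1/2}$ and acquires the heavy tail characteristic of speckle nulls.
Collapse-synchronous hyperreflectivity multiplies the lumen intensity by
$(1 + \text{intensity\_mod}\cdot c(t))$.

We do not model the axial point-spread function (the source bandwidth is
carried as metadata only), k-space resampling, galvo geometry, or the
hourglass scattering pattern of oriented red blood cells; the SLO-like video
is a depth-integrated reflectance image, not a device simulation. These
simplifications matter for image realism, not for the segmentation and
time-series statistics the package is designed to test — but they do mean a
pass on phantoms bounds algorithmic, not instrumental, error.

## The automated reader

The in-vivo reference procedure is an expert reader marking the vessel at the
borderline between static and dynamic image components. The package
operationalises that borderline:

* 3×3 median filter on the phase-difference frame (vectorised median-of-9
  sorting network);
* dynamic iff $|\Delta\phi| > k\hat\sigma$ with $k = 3$ and $\hat\sigma$ a
  *robust* circular scale (1.4826 × median absolute deviation about the
  circular median) of static-tissue phase. The robust scale is essential: the
  speckle-null tail inflates the resultant-length circular SD several-fold,
  which would push the threshold into the flow signal itself;
* morphological closing (radius 1), then the largest connected component
  inside the user's search ROI; an empty mask (total collapse) is legal and
  flagged.

Because the threshold sits at $k\hat\sigma$ above zero, it clips the slow-flow
rim where the parabolic profile has not yet risen above the noise. For a
parabolic profile this missing annulus is the fraction
$\varepsilon = k\hat\sigma / \Delta\phi_\text{peak}$ of the lumen area (about
$\varepsilon/2$ of each diameter), and the mean phase over the clipped mask is
$(\Delta\phi_\text{peak} + k\hat\sigma)/2$ rather than
$\Delta\phi_\text{peak}/2$. `measure_frame()` applies these closed-form
corrections (capped at $\varepsilon = 0.5$), which places the reported
boundary at the true static/dynamic borderline and makes the flow proxy scale
linearly with velocity. The corrections vanish as noise goes to zero, and the
uncorrected mask area is also reported.

Per-frame measures are: transversal diameter (lateral extent of the mask at
its widest row band), axial diameter, perfused area, sign-preserving circular
mean phase difference, and the flow proxy (mean phase × area, proportional to
volumetric flow at fixed Doppler geometry).

## Time-series analysis

Cardiac cycles are detected at successive maxima of a reference trace — the
arterial waveform where available, otherwise the inverted area trace, whose
maxima are the collapse events — with a minimum peak separation of one period
at the upper heart-rate bound (default band 40–120 bpm). A trailing window of
median period length is appended when at least ~one period of data follows the
last peak, so a three-cycle recording yields three windows.

Pulsation amplitude is the relative excursion $(\max - \min)/\max$ of the raw
trace, reported per cycle (median across cycles as the robust summary) and
over the whole sequence; the per-sequence maximum is the headline number. The
transversal diameter is read at the widest row band of the mask (mean lateral
extent over the widest row and its two neighbours) and its trace passes a
3-frame rolling median before the excursion read-out: diameters are
pixel-quantised, and a single ±1 px edge flicker would otherwise bias the
sequence maximum upward. The area, mean-phase and flow traces are
area-integrated and continuous-valued, so their extremes are read raw — a
median there would shave the genuine, few-frame-wide collapse minimum.
Normalisation is always to the window maximum. The sensitivity ratio is the
area amplitude divided by the transversal-diameter amplitude.

Flow oscillation is summarised as the maximum absolute fractional deviation of
the normalised flow trace from its mean (the ±x% convention for pulsatile
flow).

For dual-site recordings, `estimate_delay()` maximises the normalised
cross-correlation over lags within one cardiac period, with parabolic
sub-frame interpolation around the peak. A delay only counts as *detectable*
at $|\text{delay}| \ge$ one frame interval: sub-frame estimates exist
numerically but are below the acquisition's temporal resolution, and the
package deliberately refuses to convert them into a pulse wave velocity. The
undetermined case carries the maximum resolvable PWV
(separation × frame rate) as a diagnostic — 21.6 mm/s at 0.9 mm and 24 fps,
which is why an arterial pulse travelling at ≳1 m/s cannot be timed with
these parameters. Flow conservation across the collapse is checked as RMSD
and Pearson correlation of the delay-aligned normalised flow traces.

ROI intensity pulsatility averages *linear* intensity (dB frames are
converted back before averaging; mean reflectivity is the physical quantity,
and SLO video is linear already). When comparing OCT (24 fps) with SLO
(10 fps) the faster trace is linearly resampled onto the slower grid — no
information is invented at 10 fps.

## Numerical and design choices

* Wrapping uses the half-open convention $[-\pi, \pi)$, so $+\pi$ has the
  single representation $-\pi$; all phase aggregation uses circular
  statistics (resultant-vector mean; median and MAD computed on residuals
  about the circular mean/median).
* The Doppler frame is one column narrower than its source (no wrap-around
  A-scan pair); the intensity frame is cropped to match. Indices and ROIs are
  1-based inclusive, the R convention.
* Bulk-phase correction subtracts the per-A-scan circular median over
  static-tissue pixels (valid pixels outside the lumen ROI); it is exactly
  zero-mean on phantoms without bulk motion, toggleable off, and skipped with
  a flag when fewer than 100 tissue pixels are available.
* All randomness derives from one integer seed per configuration;
  channel-specific and SLO sub-seeds are fixed offsets of it. Identical
  configurations reproduce outputs bit-identically.
* Degenerate inputs fail loudly and early: all-zero frames, constant series,
  windows without cycles, flat traces in the delay estimator, out-of-bounds
  ROIs.
* Containers: complex sequences are stored via R serialisation, SLO video as
  multi-page 16-bit TIFF with a JSON sidecar, measurements as CSV, summaries
  as JSON validated against the schema shipped in `inst/extdata/`.

## Problem sizes and defaults

The calibrated presets run 3.2 s at 24 fps (76 frames) with 512 A-scans over
a 0.8 mm scan and 128 depth pixels (1.56 × 3 µm pitch) — enough lateral
sampling that a ±1 px segmentation flicker is ~1% of the ~120 µm resting
diameter. The resting vessel (semi-axes 60 × 55 µm, centreline velocity
15 mm/s, Doppler angle 70°) gives a resting centre phase difference of
~0.85 rad at 100 kHz, leaving headroom below π for the conserved-flow
velocity increase at peak collapse. These caliber/velocity values are
plausible retinal-vein numbers, not measurements of any subject. Property
tests use a geometrically identical phantom at 160 × 80 pixels and 2.2–2.6 s,
where a full simulate–process–quantify cycle takes under two seconds; the
noise-robustness sweep deliberately lowers the centreline velocity to 6 mm/s
so that the threshold-to-signal ratio, not discretisation, limits accuracy
across the 30–15 dB range.

## Worked example

```{r example, eval = FALSE}
report <- run_pipeline(run_config(preset = "phantom_S2"))
print(report)
glance(report)
autoplot(report$channels[[1]]$pulsatility)
```

On the subject-2-like preset the pipeline reports a transversal diameter
change of ~19%, an area change of ~59%, and a sensitivity ratio of ~3 —
the tomographic area measurement detects the pulsation about three times more
sensitively than the en-face diameter, which is the package's central
reproducible result.

## Known limitations

* The phantom's speckle is laterally phase-coherent and per-frame
  independent inside the lumen; it does not model partial decorrelation,
  transverse flow decorrelation, or eye-motion artifacts beyond an optional
  linear drift.
* The wall-bias correction assumes a parabolic profile; for plug-like or
  skewed profiles it would over- or under-correct by the profile mismatch.
* The sensitivity ratio is undefined when no lateral pulsation is detected
  (division by a zero diameter amplitude); the package errors rather than
  reporting infinity.
* Absolute volumetric flow (µL/min) is out of scope: it requires a calibrated
  Doppler angle, while the flow proxy is proportional only.
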