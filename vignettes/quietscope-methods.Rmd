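---
title: "quietscope: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quietscope: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

quietscope supports the design and analysis workflow of a *silent*
two-photon microscope for auditory neuroscience: a laser-scanning system
whose scan mechanism is an acousto-optic deflector (AOD) pair rather than a
mechanical (galvo/resonant) scanner, so that imaging produces essentially no
sound inside the hearing range of the experimental animal. The package has
four analysis layers — paraxial scan-design calculators, calibrated acoustic
noise assessment, auditory stimulus construction, and a calcium-imaging
frequency-response-area (FRA) pipeline — plus a ground-truth simulator that
makes the whole pipeline testable end to end without any recorded data.

## 1. Chirped AOD raster scanning

An AOD deflects a laser beam by Bragg diffraction off a travelling acoustic
wave; the deflection angle is proportional to the drive frequency. Sweeping
the drive frequency linearly at rate $r$ (Hz/s) makes the instantaneous
deflection vary across the beam aperture, which is optically equivalent to
inserting a cylindrical lens of focal length

$$F = \frac{v^2}{\lambda\,|r|},$$

where $v$ is the acoustic velocity in the crystal and $\lambda$ the optical
wavelength. A convex *divergence compensation lens* (DvCL) of focal length
$f$ placed after the AOD pair collimates the beam exactly when $F = f$,
i.e. at the nominal chirp rate $r_0 = v^2/(\lambda f)$. Sweeping the full
AOD bandwidth $B$ at that rate takes one line time

$$T = \frac{B\,\lambda\,f}{v^2}.$$

With the package defaults ($B = 30$ MHz, $\lambda = 920$ nm, $v = 650$ m/s,
TeO$_2$ slow shear) and $f = 1000$ mm this gives $T = 65.3\ \mu s$.

Frame geometry follows a reporting convention that the calculators make
explicit: line times are quantized to 0.1 $\mu$s, pixels per line is
`floor(line_time x 10 MHz)` (the pixel digitizer rate), and the slow-axis
chirp range is set "one pixel" short, so a frame has one line fewer than it
has pixels per line. This is the only convention simultaneously consistent
with the three design points 23.5 fps ($f=1000$ mm, 653 x 652 px),
41.7 fps ($f=750$ mm) and 93.8 fps ($f=500$ mm); an un-quantized mode is
available via `rounding = 0`.

The field of view is the full scan angle $\lambda B / v$ relayed through
the scan-lens/tube-lens telescope (angular magnification
$f_\text{scan}/f_\text{tube} = 100/200$) onto the objective:
$\text{FOV} = (\lambda B / v)(f_s/f_t) f_\text{obj}$, giving 0.585-$\mu$m
pixels with an 18-mm objective at 653 px/line.

**Multi-layer depth shift.** Chirping off-nominal leaves residual vergence
$V_0 = 1/f - 1/F(r)$ after the DvCL. The telescope scales vergence by
$(f_s/f_t)^2$ and the objective turns input vergence $V_1$ into an axial
focus shift $\Delta z = -V_1 f_\text{obj}^2/(1 + V_1 f_\text{obj})$. The
sign convention is positive = deeper (farther from the objective); chirping
faster than nominal focuses deeper. Because no printed depth-shift values
exist, the test suite validates this against an independent ray-transfer
(ABCD) matrix model of the four-lens chain, to better than 1% over the
$|\Delta z| < 100\ \mu m$ regime.

**Dark periphery and transition time.** Between lines the acoustic wave must
refill the illuminated aperture, costing $t = D/v$ (about 13 $\mu$s for an
8.45-mm beam). The dark fraction of each line is $t/T$, so faster frames
(shorter DvCL focal lengths) waste proportionally more of the field of
view. The beam diameter default is inferred from the 13-$\mu$s figure, not
a measured datum, and is configurable.

**Pulse dispersion.** Ultrafast pulse widths are estimated from intensity
autocorrelations (sech$^2$ deconvolution factor 0.65; Gaussian
$1/\sqrt{2}$), and group-delay-dispersion broadening uses the Gaussian
formula $\tau_\text{out} = \tau_\text{in}\sqrt{1 + (4\ln 2\,
\text{GDD}/\tau_\text{in}^2)^2}$ for both shapes — exact sech$^2$
propagation is deliberately out of scope, and the approximation is noted in
the function documentation.

## 2. Acoustic noise assessment

The assessment is two-step: first a physical description of the sound
(power spectral density in dB SPL/Hz), then a perceptual one (a
species-specific excitation pattern in dB SPL compared against the hearing
threshold).

`compute_psd()` Fourier-transforms the full calibrated pressure record and
power-sums the fine periodogram bins into 1-Hz bands. The estimator is
Parseval-consistent — summing band powers recovers the mean-square pressure
— so a 1-Pa-RMS tone reads $20\log_{10}(1/20\mu\text{Pa}) = 94.0$ dB in its
bin, and `band_level()` integrates any band by power summation. Spectra from
two microphones (a low-noise audio-band unit and an extended-range unit)
are merged at a crossover, 23 kHz by default. A Welch option (1-s Hann
segments, 50% overlap) reduces variance when desired; the single-FFT mode
is the default because the 1-Hz binning convention *is* the method.

`excitation_pattern()` passes the PSD through a bank of rounded-exponential
(roex) auditory filters $W(g) = (1+pg)e^{-pg}$, $g = |f-f_c|/f_c$, with
$p = 4f_c/B_s(f_c)$ chosen so each filter's equivalent rectangular
bandwidth equals the species' tuning bandwidth $B_s(f_c)$:

$$E(f_c) = 10\log_{10}\!\sum_i W\!\left(\tfrac{|f_i-f_c|}{f_c}\right)
10^{L_i/10}\,\Delta f .$$

The filters are symmetric and level-independent — the frequency-selectivity
front end of a loudness model, not a full loudness model: level-dependent
asymmetric filters and specific-loudness compression are intentionally not
implemented. Three consequences are tested as invariants: unit gain for an
on-centre tone, $E = N_0 + 10\log_{10} B_s$ for white noise, and exact
level linearity (+k dB in, +k dB out). No outer/middle-ear transfer
function is applied.

Species profiles bundle an audiogram (monotone-cubic interpolated in
log-frequency, never extrapolated) and a power-law fit $B_s(f) = a f^b$.
The packaged marmoset, CBA/CaJ and C57BL/6J profiles are literature-shaped
approximations with provenance notes — the marmoset audiogram is anchored
at 10.6 dB SPL / 8 kHz — and should be re-digitized from primary sources
for publication-grade use. `threshold_exceedance()` reports
$E(f) - \text{threshold}(f)$; any sustained positive excursion means the
sound can drive that species' auditory system.

## 3. Auditory stimuli

Two experiment types are constructed. Tone pips are 0.2 s with 20-ms
sine-squared (raised-cosine) on/off ramps — "sine ramps" read as the common
$\sin^2$ envelope — calibrated so the plateau RMS matches the requested
dB SPL. Sweep sequences step exactly one semitone ($2^{1/12}$) per pip
(73 pips from 440 Hz end at 28160 Hz); descending is the exact reverse.

The FRA grid crosses 31 frequencies (2-semitone steps from 440 Hz) with 5
levels (5-65 dB SPL, 15-dB steps): 155 trial types. The printed top
frequency conflicts between sources (7040 Hz vs a 5-octave span); the
default spans 5 octaves to 14080 Hz and the 25-frequency/7040-Hz variant is
available via `n_freqs = 25`. Trials are 3 s (0.6 pre / 0.6 stimulus /
1.8 post) with three contiguous pips filling the stimulus window exactly
(no inter-pip gap, since $3 \times 0.2$ s fills 0.6 s). Schedules are
seeded: each cycle is an independent permutation of the full grid, with no
constraint across cycle boundaries.

## 4. From movie to best-frequency map

Motion correction follows a two-stage hierarchical protocol with a rigid
translation engine: (1) all frames of a trial are registered to a template
averaged across 10 mid-trial frames; (2) the corrected within-trial
averages are registered across trials (to their grand average) and the
cross-trial shifts are applied back to every frame. The engine estimates
shifts by FFT cross-correlation with subpixel refinement via matrix-DFT
upsampling (factor 16) of the correlation surface around its peak, and
applies corrections with separable Catmull-Rom cubic interpolation and
replicated edges. Cubic rather than linear interpolation matters here:
somata are only a few pixels wide, and linear interpolation attenuates
pixel-scale structure by several percent at half-pixel shifts, which
contaminates trial-resolved amplitudes.

A registered session has no absolute reference: the corrected movie sits at
the session-mean position of the data-derived template. ROI masks must
therefore live in the *corrected* movie's coordinates — in practice they are
drawn on the registered mean image. `shift_roi_mask()` exists for moving
masks between frames of reference (the simulator's truth masks are in scene
coordinates).

Trace extraction is the mean over ROI pixels (chosen over the sum for gain
invariance). Neuropil correction extracts a ring of pixels within 5 px of
the ROI (exact Euclidean dilation, starting at the ROI boundary — no gap),
excludes the pixels of *every* ROI in the field from the ring so a
neighbouring soma never leaks into the neuropil estimate, and subtracts 0.4
times the ring trace. $\Delta F/F$ is computed per trial against the mean
fluorescence of that trial's pre-stimulus window ([0, 0.6) s; stimulus
window [0.6, 1.2) s; both configurable); a non-positive baseline flags the
cell rather than silently clipping. The response amplitude is the mean
$\Delta F/F$ over the stimulus window, the FRA cell value is the mean over
its (nominally 10) repetitions, and BF/BL are the argmax of the mean
matrix, ties broken toward the lowest level then the lowest frequency.
Correction order is neuropil subtraction, then $\Delta F/F$, then
amplitude. No responsiveness criterion is applied before mapping BF/BL.

## 5. The synthetic-session simulator

The simulator emulates the statistical structure this pipeline assumes:

* **Tuning surfaces.** Each neuron is V-, I- or O-shaped. All are Gaussian
  in log2 frequency with bandwidth `bw_oct` — a full width at half maximum
  in octaves, drawn from 0.5-1.0 oct. V-shapes widen with level (top-level
  FWHM 0.5-2 oct, the range reported for primary auditory cortex) with a
  monotone level gain, I-shapes keep a level-independent bandwidth, and
  O-shapes are separable Gaussians in frequency and level peaked at
  (BF, BL) with a 15-dB level sigma. The recorded ground truth is the
  argmax of the surface over the actual stimulus grid, so recovery tests
  have an exact reference.
* **Kinetics.** A double-exponential calcium impulse response (rise 0.2 s,
  decay 1.5 s, GCaMP6s-like) convolved with a per-trial drive; the kernel
  is normalized so a trial's peak $\Delta F/F$ equals its tuning-surface
  amplitude. Peak amplitudes are drawn from 0.1-1.0 $\Delta F/F$ (a
  simulator convention for somatic GCaMP6s, not a measured fact).
* **Scene.** Gaussian soma profiles with $\sigma = r/2$, so the nominal
  mask (disc of radius $r$) contains ~86% of the emission — somatic
  labelling is compact; plus a diffuse neuropil background with broad
  blobs that give the registration some low-frequency texture. Somas are
  placed non-overlapping (centre distance > $2r$) and at least the motion
  cap away from the frame edge, so moving cells never wrap around the
  frame.
* **Motion.** A ~4-Hz heartbeat oscillation (2 px amplitude at the
  full-resolution 0.585-um pixel size) with ~5% beat-to-beat frequency
  jitter (heart-rate variability — a perfectly metronomic sinusoid would
  phase-lock to the frame clock and collapse the motion onto a few
  discrete positions, which real cardiac motion never does), plus a slow
  drift (3 px per session), capped at 5 px per axis. Motion is applied by
  Fourier (sinc) subpixel translation — deliberately a *different*
  interpolator from the registration engine's cubic one, so the oracle
  and the method stay independent. Note that these pixel values are tied
  to the 0.585-um pixel size: a spatially downscaled session with coarser
  pixels sees the same physical motion as proportionally fewer pixels
  (e.g. 0.5 px heartbeat at ~2.4-um pixels).
* **Noise.** Gaussian shot-like noise with variance
  $\sigma^2 = \text{read}^2 + g F$. The default gain $g = 0.2$ at a
  baseline of ~100 counts corresponds to roughly 200 photons/pixel/frame
  (a few thousand photons per soma per frame), at which simulated
  single-trial transients are clearly visible — matching the character of
  published single-trial calcium traces. Exact Poisson noise is not used;
  the Gaussian approximation is accurate at these counts and much faster.

Everything is a pure function of (config, seed).

**What passing the closed loop does and does not show.** The end-to-end
test (simulate, register, extract, FRA, BF/BL) at 100 neurons and
10 x 155 trials recovers >= 90% of high-SNR neurons' BF within one
2-semitone step and BL within one 15-dB step, and the displacement table
matches the simulated motion with RMSE < 0.3 px. This validates the
pipeline's bookkeeping, geometry, timing and statistical machinery under
the noise and motion structure the simulator encodes. It does not validate
performance under features real movies have and the simulator does not:
non-rigid (within-frame) deformation, slow photobleaching, neuropil that is
itself stimulus-locked, overlapping or z-drifting cells, and segmentation
errors (masks here are exact).

## 6. Numerical choices and problem sizes

* Line-time quantum 0.1 $\mu$s; pixel counts take a 1e-6-pixel float
  guard before `floor`.
* dB floor sentinel at -120 dB SPL/Hz for zero-power bins; excitation
  grids default to 64 points/octave.
* Registration upsampling factor 16 (0.0625-px resolution); correlation
  peak search over a +/- 1 px refinement window; degenerate (constant)
  images raise an error rather than returning a shift.
* The packaged test suite runs sessions downscaled in space and frame
  rate — typically 40 x 40 to 96 x 96 px at 10 fps, 1-10 cycles, with
  motion expressed in the downscaled pixel units — sizes chosen so the
  full suite exercises every stage, including a full-schedule 100-neuron
  closed loop and a full-resolution-geometry registration check, in a few
  minutes on one core. The simulator's own defaults remain the full-scale
  acquisition (653 x 652 px at 23.5 fps).
* All seeds flow through `withr::with_seed`; the closed-loop session uses
  offset seeds for population, motion, background and noise so each
  component can be varied independently.

## 7. Known limitations

* The depth-shift model is paraxial and thin-lens; it ignores aberrations
  and assumes perfect telecentric spacing (the ABCD oracle shares the
  spacing assumption, not the algebra).
* The excitation model has no level-dependent filter asymmetry, no
  outer/middle-ear correction, and the packaged species parameters are
  approximations.
* The registration engine is strictly rigid; real tissue deforms
  non-rigidly, and the two-stage protocol inherits whatever bias the
  mid-trial template has under fast motion.
* WAV support covers PCM 16/24 and float32 mono/multichannel, without
  metadata chunks beyond `fmt`/`data`.
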