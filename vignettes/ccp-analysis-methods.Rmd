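---
title: "Models and methods for quantifying clathrin-coated pit dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying clathrin-coated pit dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ccptools)
```

This vignette explains the models behind `ccptools`, the parameters that
matter, what the synthetic-movie generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The imaging model

A clathrin-coated pit (CCP) is imaged in two channels: a pioneer channel
(FCHO2-like) and a clathrin channel. The optical model has four ingredients:

1. **Projection.** Each object is a distribution of fluorophores on a
   surface. The pioneer geometry is flat at the membrane: a uniform disk
   ("patch") of radius $r_1$, or a Gaussian annulus of peak radius $r_1$ and
   FWHM width $r_2$. The clathrin coat is a spherical cap of base radius
   $r_b$ and height $h$ (up to a hemisphere, $h \le r_b$), with uniform
   fluorophore density per unit cap area; $z = 0$ at the coverslip.
2. **Evanescent excitation.** TIRF illumination decays as
   $w(z) = e^{-z/d}$ with penetration depth $d$ (default 100 nm). The mean
   detected fraction for a cap follows in closed form from the spherical
   zone area element $dA = 2\pi R\,dz$:
   $\bar w = \frac{d}{h}\left(1 - e^{-h/d}\right)$.
   A grown dome is therefore dimmer on axis and, together with the secant
   factor $R/\sqrt{R^2 - r^2}$ of the projection, appears as an annulus —
   the reason mature pits look ring-shaped in the clathrin channel.
3. **PSF.** An isotropic 2D Gaussian with
   $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$; SIM-like default 90 nm FWHM,
   TIRF-like 250 nm. No structured-illumination reconstruction artefacts are
   simulated; the PSF model is also the detection model.
4. **Noise and bleaching.** Per-channel double-exponential bleaching
   $Y(x) = a e^{bx} + c e^{dx}$ multiplies each frame; Poisson shot noise
   (with a gain scaling) and Gaussian read noise are sampled per raw
   sub-frame. SIM acquisitions record `n_raw_per_timepoint = 9` raw images
   per time point (three pattern angles × three phases); the analysis
   averages them back into one snapshot per time point.

Painting happens on a 4× supersampled local patch which is renormalised so
the painted total equals amplitude × projection weight exactly:
discretisation affects only the shape, never the photon count. The PSF is
applied by exact circular FFT convolution with a kernel normalised to sum 1,
so integrated intensity is conserved to machine precision — the basis of the
photon-conservation tests.

## The synthetic lifecycle

`build_scenario()` draws objects through five phases: (1) a pioneer patch
assembles (no clathrin), (2) clathrin nucleates as a flat disk while the
pioneer reorganises into a ring, (3) the ring expands as the coat domes,
(4) the pioneer decays, (5) only clathrin remains until scission. Defaults
(see `lifecycle_defaults()`):

* mean lifetime 60 s (lognormal, CV 0.25) — the canonical 1–2 min CCP
  lifetime;
* pioneer patch radius 50 nm; ring radius 80 nm at nucleation, expanding
  rapidly to 120 nm at the start of the growth phase; ring width 60 nm FWHM;
* coat footprint diameter N(122 nm, 2 nm) — pits are strikingly uniform in
  size; the cap height grows to 0.9 of the base radius;
* peak amplitude 2000 photons/frame (CV 0.15) over a 10 photon/px
  background with unit Poisson gain and read noise of 2 — a peak-pixel SNR
  of roughly 8;
* amplitude rises follow a smoothstep ($3u^2 - 2u^3$): cooperative assembly
  has sigmoid kinetics, and a cohort-averaged sigmoid has an interior
  inflection point for the cubic timing fit (a linear ramp would not);
* 10% of objects are subthreshold transients: lifetime 4–16 s (< 20 s) with
  10–30% of the regular amplitude, aborting after a brief nucleation —
  operationalising "a stable CCP nucleus fails to form";
* 10% of regular objects receive a hotspot successor born within 2 px of
  the predecessor, separated by 3–5 dark frames and starting directly in
  phase 2 (the pioneer machinery is already in place at a hotspot). The
  dark gap exceeds the tracker's `max_gap` so the two events remain
  separate tracks.

Random streams are split per object and per frame with a deterministic seed
hash, so adding objects does not perturb existing ones and renders are
bit-identical.

**What the generator does not emulate:** lateral CCP motion, cell-edge
geometry, camera fixed-pattern noise, SIM reconstruction artefacts, spatially
varying background, or fluorophore blinking. Passing tests therefore show
that the analysis chain recovers the stated geometric and kinetic parameters
under idealised, stationary imaging — not that it is robust to every
artefact of real microscopes.

## Detection, tracking and classification

Detection models a spot as $A\,G_\sigma(x - x_0, y - y_0) + b$: candidates
are local maxima of a Laplacian-of-Gaussian filter at scale $\sigma$
(threshold 4.5 robust SDs of the filter response), each refined by
Gauss–Newton least squares with $(A, b)$ profiled out, and kept when the
one-sided t-test of $A$ against the local residual noise gives
$p < \alpha$ (default 0.05). The candidate threshold was set so blank noise
frames yield well under the tolerated false-detection budget while spots at
SNR 10 are found with sub-0.1 px accuracy.

On SIM-resolution movies detection and tracking run at the **CCP image
scale** (260 nm FWHM, `detect_fwhm`), not the 90-nm PSF: a mature pit is
annular at SIM resolution, and a PSF-sized Gaussian fit locks onto rim
maxima and fragments tracks. Tracking on diffraction-limited blobs and
morphometry on the SIM frames mirrors how such data are analysed in
practice.

Linking is greedy mutual-nearest-neighbour with `max_disp = 2` px and gap
closing over `max_gap = 2` frames; ties break by distance then detection
index, making the result independent of detection order. Classification
flags: censored (alive at movie start/end — never counted as initiations),
border (within $3\sigma$ of the field edge), hotspot members (birth within
`r_h = 2` px and `delta_t = 5` frames of another track's death; both
members flagged), subthreshold (lifetime < 20 s or peak amplitude < 0.4 of
the median non-censored peak). None of these thresholds is canonical; all
are arguments with these defaults.

## Photometry

The bleach fit is deterministic: a single exponential on log-means seeds a
Levenberg–Marquardt fit of the double exponential with the two rates split
10:1 and bounded non-positive; a constant trace short-circuits to the exact
degenerate solution and collinear terms fall back to the nested single
exponential. Compensation multiplies frame $x$ by $Y(0)/Y(x)$ — frame 0 is
the anchor because cohorts are aligned at appearance, and whether the
original analysis normalised to the first frame or the fitted asymptote is
not stated; first-frame normalisation is the documented choice here.

The cross-channel coefficient minimises
$\sum_q (Q_1(q) - s\,Q_2(q))^2$ over 101 matched intensity quantiles, with
the closed-form solution $s = \sum Q_1 Q_2 / \sum Q_2^2$. Matching
quantiles is the reading of "minimising the difference between average
histograms" that a multiplicative intensity coefficient can actually
optimise; bin-wise histogram matching is available as an alternative mode.

## Dual-channel timing

Master/slave analysis reads the slave channel in a 3×3 px window at the
master positions, background-subtracted with an annulus at 4–6 px, over
`[birth - n_buffer, death + n_buffer]` with `n_buffer = 25` — large enough
to capture the pioneer's pre-appearance rise. Buffer frames reuse the
track's first/last position; frames outside the movie are missing, never
zero-filled. Hotspot tracks are excluded by default since they cannot show
de novo pioneer recruitment.

Recruitment order is timed with a least-squares cubic
$y = c_3 t^3 + c_2 t^2 + c_1 t + c_0$, inflection $t^* = -c_2/(3c_3)$. A
single cubic is the documented reading of "approximating cubic polynomial"
(it could also mean a spline). The fit window brackets the channel's own
rise: from 2 frames before the last frame still within 10% of baseline to
the first frame reaching 95% of maximum. Windowing on the *master's* birth
alone — the first design tried — cannot work for the slave, whose rise
happens inside the buffer, and extending a single cubic over baseline,
rise and plateau together makes the inflection drift to the window
boundary; bracketing the rise keeps the cubic well-posed for both channels.

## Morphometry

Snapshots are 21×21 px ROIs; the centroid is refined by iterated
intensity-weighted centre of mass on the background-subtracted window —
unbiased for annular spots where a Gaussian fit is misspecified — with the
mass restricted to a central circular mask (0.6 of the half-width) and the
total walk capped at 2 px, so a neighbouring structure in a window corner
cannot drag the centroid.

Radial profiles average intensity in annular bins (default one pixel).
`classify_shape()` computes a finer profile on a 3× bilinearly resampled
grid with half-pixel bins — coarse binning lets the peak migrate between
bins and is the dominant noise in the central-dip statistic. A ring is
declared when the profile peak radius is at least one pixel-equivalent and
the central dip $1 - I(0)/I(\mathrm{peak})$ is at least 0.1; the thresholds
are set so a PSF-limited point source is never a ring, and are exposed as
arguments.

Blur shifts an annulus peak inward — severely near the resolution limit.
Where the true annulus radius is wanted, the Gaussian-blurred thin-ring
model $I(r) \propto e^{-(r^2+r_0^2)/2\sigma^2} I_0(r r_0/\sigma^2)$ is
inverted numerically (`ring_radius_from_profile()`, and
`classify_shape(..., psf_fwhm =)`); sub-resolution rings (e.g. 60 nm at a
90 nm PSF) are recoverable this way from averaged profiles.

The through-centre FWHM is averaged over 4 line orientations (0°, 45°, 90°,
135°) rather than a single line, which reduces orientation noise; background
is the mean of the outer 10% of samples and crossings are located by linear
interpolation. Two estimators of the coat footprint diameter are provided —
the half-max crossing distance (FWHM) of the flat nucleation-stage image,
and twice the annulus peak radius — because how the printed mean diameter
was operationally measured is not fully specified; the blind experiment
measurement uses the FWHM of late-nucleation (flat disk) snapshots, for
which the half-max crossings of a blurred disk sit at the disk edge almost
exactly.

The footprint→vesicle conversion treats the footprint as a flat disk:
$\pi (d/2)^2 = 4 \pi (D/2)^2 \Rightarrow D = d/2$, reproducing ~61 nm from
122 nm; the hemispherical-cap alternative ($D = d/\sqrt{2} \approx 86$ nm)
is provided but non-default.

### Five-phase classification

Per-frame rules on the two channels' windowed amplitudes and the pioneer's
ring morphometry: phase 1 while only the pioneer is above detection; 2 once
clathrin is detected; 3 when the pioneer ring has expanded at least one
pixel-equivalent (32.5 nm) beyond its initial ring radius; 4 when the
smoothed pioneer amplitude falls below 50% of its track maximum with
non-positive slope; 5 when the pioneer is below detection *and* below 10%
of its maximum (the extra condition is hysteresis: without it a single
noisy late-phase-4 frame flips the monotone labels to 5 early). The
detection level is 3 standard deviations *of the windowed mean* — the
per-pixel background SD scaled by the effective number of independent
samples in the readout window, which PSF correlation roughly quarters.
Labels are forced monotone by a running maximum. The pioneer readout window
(11×11 px, background annulus 7–9 px) must contain the expanded ring;
smaller windows leak ring signal into the background annulus and corrupt
the amplitude.

### Ground truth for the blind experiment

The generator specifies 3D geometry, but what an experiment can recover is
the *imaged* appearance. The scenario-level truth for the inter-channel
radial peak offset is therefore defined by `expected_ring_offset()`: one
isolated, noise-free, bleach-free object rendered at the generator's
lifecycle parameters, its growth-phase snapshots averaged exactly as the
analysis does, and the two channels' profile peaks taken from that. A blind
analysis of a full, noisy, crowded experiment is expected to reproduce this
value within one radial bin; the footprint diameter is compared directly to
the generator's 122 nm mean.

## Problem sizes and determinism

The shipped tests run the generator at desk scale: fields of 128–384 px,
25–100 time points at 1 s sampling, 5–150 objects, chosen so the full suite
completes in minutes while every module still sees crowded, noisy,
multi-phase data. Temporal sampling in the SIM-like test scenarios is 1 s
rather than the 100 ms of a real acquisition — a pure problem-size choice;
lifecycle durations are specified in seconds and scale with
`frame_interval`. All stochastic stages derive from one integer seed;
identical configurations give bit-identical movies, tables and summaries.

## Known limitations

* The Gaussian-PSF detection model is misspecified for annular SIM spots by
  design; tracking therefore runs at the CCP image scale and sub-pixel
  positions for morphometry come from the centre-of-mass refinement, not
  the tracker.
* The thin-ring blur inversion assumes the annulus width is small or known;
  with an unknown width it under-corrects.
* No merging/splitting of tracks, no motion models, no field-dependent
  chromatic distortion, no spatially varying bleach.
* Phase boundaries are rule-based operationalisations; near transitions a
  few frames of disagreement with scripted truth are expected, and the
  running maximum trades early-phase errors for label monotonicity.
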