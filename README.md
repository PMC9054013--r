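# ccptools

Quantitative analysis of clathrin-coated pit (CCP) dynamics in two-channel
live-cell fluorescence movies (TIRF and TIRF-SIM), together with a seeded
synthetic-movie generator that emulates the pioneer-protein/clathrin imaging
experiment and provides full ground truth.

## The scientific problem

Clathrin-mediated endocytosis begins when pioneer proteins (FCHO, Eps15,
AP2) assemble on the plasma membrane and nucleate a clathrin coat. Dual-color
superresolution TIRF-SIM imaging shows the pioneer FCHO2 arriving first as a
diffraction-limited patch, reorganising into a ring at the periphery of the
nucleating pit, expanding as the coat domes, and dissipating before
scission — a lifecycle that can be dissected into five phases from the two
channels' amplitudes and morphologies. Quantifying this requires a chain of
image-analysis steps, each of which this package implements as a tested,
reusable function:

* **Synthetic data** (`build_scenario()`, `render_movie()`) — two-channel
  movies of five-phase CCP lifecycles. The pioneer channel is painted as a
  flat patch or a Gaussian annulus; the clathrin channel as a spherical cap
  whose surface elements are weighted by the evanescent excitation
  `w(z) = exp(-z/d)`, so a grown dome projects as an annulus. Objects are
  blurred with an isotropic Gaussian PSF, bleached with a double
  exponential, chromatically offset between channels, and sampled with
  Poisson + Gaussian read noise. All randomness is split per object, channel
  and frame from one seed; renders are bit-identical for equal inputs.
* **Registration** (`estimate_transform()`, `apply_transform()`) — chromatic
  correction from fiducial-bead images: 2D Gaussian bead localisation,
  mutual-nearest-neighbour matching, least-squares translation / rigid /
  affine fit, bicubic resampling.
* **Photometry** (`fit_bleach()`, `correct_bleach()`,
  `estimate_channel_scale()`) — photobleaching compensation with
  `Y(x) = a e^{bx} + c e^{dx}` fitted to frame means (frames rescaled by
  `Y(0)/Y(x)`), and a closed-form quantile-matching estimate of the
  cross-channel intensity coefficient.
* **Detection & tracking** (`detect_movie()`, `link_tracks()`,
  `classify_tracks()`, `initiation_density()`) — spots modelled as an
  isotropic 2D Gaussian `A·G_σ + b` above local background, candidates from
  a Laplacian-of-Gaussian filter, amplitudes tested against local residual
  noise; greedy mutual-nearest-neighbour linking with gap closing; track
  flags for censoring, border contact, hotspots (a CCP forming right after
  another at the same spot) and short dim subthreshold structures;
  initiation densities per µm² per minute.
* **Dual-channel master/slave analysis** (`extract_paired_traces()`,
  `cohort_average()`, `inflection_time()`) — slave-channel intensities read
  at master-track positions with buffer frames (default 25) before
  appearance and after disappearance, lifetime-cohort averages aligned at
  appearance, and recruitment timing from the inflection
  `t* = -c2/(3 c3)` of a least-squares cubic fitted to the rise.
* **Morphometry** (`extract_snapshot()`, `average_snapshots()`,
  `radial_profile()`, `fwhm()`, `classify_shape()`, `peak_offset()`,
  `size_statistics()`, `vesicle_diameter_from_footprint()`,
  `classify_phase()`) — 21×21-px ROIs with automated centroid refinement,
  snapshot averaging, azimuthal radial profiles, through-centre FWHM,
  ring-versus-patch classification, inter-channel radial peak offsets, CCP
  size statistics, the flat-footprint→vesicle size conversion
  (`π(d/2)² = 4π(D/2)² ⇒ D = d/2`), and rule-based five-phase lifetime
  labels forced monotone along each track.
* **Pipeline** (`run_pipeline()`) — one seeded configuration driving
  simulate → register → photometry → track → dual-channel → morphometry
  into a run directory with a manifest; re-running a completed directory is
  a no-op unless forced.

## Worked example

```r
library(ccptools)

optics   <- sim_optics(frame_interval = 1, n_raw_per_timepoint = 1)
scenario <- build_scenario(n_objects = 15, field_size = c(160, 160),
                           duration = 80, optics = optics, seed = 5)
movie    <- render_movie(scenario, optics)

# track in the clathrin channel at the CCP image scale
det_optics <- sim_optics(frame_interval = 1, n_raw_per_timepoint = 1,
                         psf_fwhm = 260)
det    <- detect_movie(movie$channel2, det_optics)
tracks <- classify_tracks(link_tracks(det), movie$channel2, det_optics)
res    <- measure_experiment(movie$channel1, movie$channel2, tracks, optics,
                             min_snapshots = 20)
res$mean_diameter_nm
#> [1] 121.9603
vesicle_diameter_from_footprint(res$mean_diameter_nm)
#> [1] 60.98016
res$ring_peak_offset_nm
#> [1] 101.3998
```

The measured mean coat footprint diameter (122.0 nm here) recovers the
generator's 122 nm mean; the flat-disk area equivalence converts it to a
~61 nm vesicle; and the pioneer-ring versus clathrin radial peak offset
(101.4 nm) agrees with the model-expected appearance under these optics
(`expected_ring_offset(optics)$offset_nm`, 95.2 nm) to within one pixel.

The same analysis as a step-by-step workflow lives under `analysis/`
(`01_simulate.R` … `06_morphometry.R`); each script prints what it found and
writes its tables under `results/run/`.

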