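---
title: "From interstitial-space geometry to shear stress and cardiovascular readouts: methods and design choices"
author: "ifshear authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From interstitial-space geometry to shear stress and cardiovascular readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifshear)
```

# The problem

Rhythmic head motion (for example the ~2 Hz vertical acceleration of a jog,
or a passive analogue of it) generates low-amplitude pressure waves in the
brain that move interstitial fluid through the narrow extracellular channels
of the tissue. In the rostral ventrolateral medulla (RVLM) — the brainstem
region that sets basal sympathetic vasomotor tone — that flow exerts a fluid
shear stress on cell surfaces, and shear of the right magnitude
down-regulates angiotensin II type-1 receptor expression in astrocytes,
lowering blood pressure in hypertensive animals and people.

`ifshear` implements the quantitative chain behind that argument as a
reusable, tested pipeline:

1. **interstitial geometry** — segment channel-like interstitial structures
   from 3D fluorescence volumes, fit ellipses to their cross-sections,
   summarise the pore-size distribution (log-normal mode and FWHM), and
   measure channel orientation against the brainstem centroidal line;
2. **tracer spread** — quantify contrast-agent spread along anatomical axes
   in CT-like volumes and convert the motion-induced fold increase into an
   interstitial flow-velocity estimate;
3. **permeability and shear** — Kozeny–Carman permeability and the Darcy
   shear-stress envelope over biophysical parameter ranges;
4. **cardiovascular variability** — beat-by-beat blood-pressure/RRI
   artifact rejection, recording-validity rules, and Hanning-windowed
   LF/HF band powers;
5. **nerve activity** — rectified–integrated processing of multifibre
   baroreceptor/sympathetic recordings normalised per heartbeat;
6. **synthetic data** — seeded generators for all of the above with
   complete ground truth, so the entire chain is testable without any raw
   recording.

# Image geometry

## Preprocessing

`preprocessVolume()` resamples a volume to an isotropic grid by trilinear
interpolation (the working resolution is 0.2072 µm voxels, the grid on
which 20 µm two-photon stacks become 100 cubic voxels) and smooths with a
uniform box filter of width 5 voxels (≈1 µm). The box filter divides by
the in-volume window size at the edges, so constant volumes pass through
unchanged. Voxel centres live at `(index − 0.5) × spacing`; every output is
in physical units.

## Cluster extraction

`extractInterstitialClusters()` encodes the extraction rule for interstitial
space, whose premise is that the extracellular space occupies roughly 20 %
of brain tissue:

* foreground = voxels **strictly above** the `1 − topFraction` sample
  quantile (linear-interpolation quantile, type 7). Strict inequality means
  a constant image yields an empty foreground rather than an error;
* connected components at 26-connectivity (8-connectivity in-plane).
  Maximal connectivity avoids artificially splitting thin diagonal
  channels; `labelComponents()` exposes both 6 and 26 and is verified
  against an exhaustive flood-fill oracle in the tests;
* components above 5,000 voxels are trimmed: exactly
  `ceiling(trimFraction × size)` lowest-intensity voxels are removed, ties
  broken by voxel index, and the survivors re-labelled (re-labelling makes
  the subsequent size filter well defined);
* components below 50 voxels are deleted.

## Ellipses, pore sizes, orientation

`fitClusterEllipses()` returns the second-central-moment (covariance)
ellipse of each cluster's footprint on the analysis plane — axis lengths
`4·sqrt(eigenvalue)`, the standard image-moments convention — with the
plane chosen by the highest mean fluorescence along the stack direction. A
voxel-extent term (`spacing²/12`) on the diagonal moments keeps one-voxel-wide
footprints from degenerating to a zero minor axis.

`estimateCrossSectionDistribution()` fits areas by closed-form maximum
likelihood for the log-normal. The mode is `exp(µ − σ²)`; the full width at
half maximum of the fitted density has the closed form
`mode·exp(±σ·sqrt(2 ln 2))` — the FWHM is measured on the fitted continuous
density, never on a histogram, because any histogram binning would be an
arbitrary extra parameter. The tests confirm the closed form against
numeric root-finding and the MLE against `fitdistrplus`.

`computeCentroidalLine()` fits per-slice mask centroids along the
rostral–caudal axis: the left–right coordinate by linear least squares and
the dorsal–ventral coordinate by a 4-parameter sigmoid
`c + d/(1 + exp(−(y − y₀)/s))` (Levenberg–Marquardt via `minpack.lm`),
falling back to a linear fit with a flag when the sigmoid does not
converge. The split — linear in one transverse plane, sigmoidal in the
other — reflects the anatomy: the lower brainstem bends dorsoventrally
along its longest diameter. How the original analysis combined "least
squares and sigmoid fitting" is not fully specified anywhere we could
verify, so this concrete split is a design choice of this package.

`orientationSummary()` reports the acute angle between each major axis and
the centroidal-line direction projected into the analysis plane, plus axial
circular statistics (doubled-angle resultant length and circular s.d.).
Note that an in-plane ellipse can only see the in-plane projection of a 3D
direction: for channels jittered isotropically around the preferred axis by
polar angle σ, the recoverable in-plane dispersion is σ/√2, and the
recovery tests compare against the projected ground truth, not the raw 3D
jitter.

# Tracer spread and flow velocity

`segmentTracer()` thresholds at `1.02 ×` the mean intensity over a
user-supplied air ROI — **inclusive**, so a voxel at exactly 1.02× air
belongs to the cluster — and keeps the largest connected component (one
bolus; speckle suppressed). "Spread" is the axis-aligned bounding-box
extent `(max − min + 1) × spacing`: the simplest quantity consistent with
reporting per-axis distances; second moments or convex hulls would be
alternatives, but nothing in the source analysis requires them.
`spreadFoldChange()` is the elementwise post/pre ratio, and
`estimateFlowVelocity()` converts a fold range into a velocity range:
the sedentary interstitial flow baseline of 0.2 µm/s scaled by the observed
two-to-three-fold enhancement gives the working range 0.4–0.6 µm/s.
Serial scans are assumed pre-aligned; no registration is attempted.

# Permeability and shear stress

The permeability model is Kozeny–Carman,

$$K_p = \frac{\varepsilon^3 d^2}{36\,K\,(1-\varepsilon)^2},$$

with ε the extracellular volume fraction, K the Kozeny constant
(4.5–5.5 for channel-like geometry) and d the equivalent circular diameter
of the measured cross-section, `d = sqrt(4·area/π)`. The shear stress at
the interstitial cell surface is the standard porous-media estimate

$$\tau = \mu u / \sqrt{K_p}.$$

Both formulas are pluggable strategy functions in `shearStressRange()`, so
an alternative algebra can be swapped without touching callers. τ is
monotone in every argument, so the envelope over input ranges is attained
at corner combinations; `shearStressRange()` evaluates all corners and
reports which corner attains each bound, and the tests verify the corner
envelope against a dense grid search.

**Parameter defaults** (`shearConfig()`): u = 0.4–0.6 µm/s,
K = 4.5–5.5, area = 0.0083–0.18 µm², ε = 0.2 (the accepted brain
extracellular volume fraction), µ = 0.8 mPa·s. Viscosity deserves a note:
interstitial fluid at body temperature plausibly spans 0.7–1.0 mPa·s, but
the reported stress envelope of 0.076–0.53 Pa for this tissue is only
consistent with a fixed viscosity — the envelope's bound ratio matches
scanning u and area alone, and µ·√K ≈ 0.8 mPa·s·√4.5 reproduces both
printed bounds almost exactly. Treating µ as a range would widen the upper
bound by ~39 %. We therefore ship µ as the point value 0.8 mPa·s and leave
the range to the caller:

```{r}
tauRange(shearStressRange(shearConfig()))
```

# Cardiovascular variability

* `computeMAP()`: MAP = DBP + (SBP − DBP)/3.
* `valueOfDay()` / `valueOfWeek()`: mean of exactly three same-morning cuff
  measurements; weekly mean defined only with ≥3 recorded days (fewer gives
  an explicit undefined value, not an error).
* `cleanRRI()`: two fixed-order passes — absolute limits first (intervals
  <0.5 s or >1.5 s removed), then the relative rule (outside 0.6–1.4× the
  mean of the 10 immediately preceding **retained** intervals). The first
  10 retained intervals are exempt, because no 10-interval history exists
  for them; the original description is silent on this warm-up, and the
  exemption is the least-surprising completion. The pass order genuinely
  changes outcomes and is pinned by a test.
* `validateSegment()`: over the last 5 min, a beat fails blood pressure if
  the value is missing or SBP < 50 mm Hg (50 itself passes); the modality
  fails when failed-beat time exceeds 4 % of the window, and RRI fails when
  cleaning removes more than 10 % of intervals. All three boundaries are
  tested exactly.
* `bandPower()`: the beat series is cubic-spline interpolated to 4 Hz over
  the central 256 s of the last 5 min, demeaned, Hanning-windowed with
  power compensation (division by the window mean square), and the
  one-sided periodogram summed over the band. 4 Hz is the conventional
  tachogram rate and comfortably resolves the 0.4 Hz band edge; the
  original resampling rate and interpolation are unstated, so these are
  package choices. Bands are half-open (`lower ≤ f < upper`) so the shared
  0.15 Hz edge is never double-counted. For a noiseless in-band sinusoid of
  amplitude a the result is a²/2 within windowing tolerance (≈0.02 % in the
  tests).
* `spectralSummary()`: LF power of SBP variability (vascular sympathetic
  index) and LF/HF of RRI variability (sympatho-vagal balance). RRI is
  cleaned first and interpolated over time (tachogram against time, not
  beat index) so SBP and RRI share a frequency axis; interpolation bridges
  removed beats, while recording validity is the separate
  `validateSegment()` gate. Whether LF/HF should use absolute or normalised
  units before baseline scaling is moot for the ratio; absolute units are
  reported.
* `normalizeToBaseline()` / `summarizeSessions()`: group values scaled by
  the begin-period mean; per-participant period means require ≥4 valid
  sessions (the documented single 3-session exception is expressed by
  lowering `minSessions`).

# Nerve activity

`integrateNerveSignal()` mirrors the hardware chain: mean subtraction (DC
removal), 50–10,000 Hz band-pass — realised as a 2nd-order Butterworth run
forward–backward, i.e. zero-phase with 4th-order magnitude; only the pass
band is specified by the acquisition description, the order is a package
choice — full-wave rectification, and first-order leaky integration with
τ = 3 ms (`y_t = α·x_t + (1−α)·y_{t−1}`, `α = Δt/(τ+Δt)`), the standard
reading of "integrated and smoothed with a time constant". At 3 kHz
sampling the 10 kHz upper edge exceeds Nyquist and is clipped to
0.45 × rate with a message. `beatAverageRelative()` averages the trace per
beat interval, subtracts the post-mortem background level, and scales by
the mean of the 10 beats immediately before the event marker (baseline
= 100 %).

# The synthetic-data module

Every generator returns complete ground truth and is bit-reproducible for a
fixed spec and seed; randomness is local to the call (the caller's RNG
state is untouched).

**Pore volumes** (`generatePoreVolume()`): straight elliptic cylinders with
i.i.d. log-normal cross-sectional areas and directions jittered around a
preferred axis (polar angle ~ N(0, σ), uniform azimuth). Defaults are sized
to the biology and the working grid: 64³ voxels at 0.2072 µm, 16 channels
whose default log-normal (µ = 0.69, σ = 0.4 in log µm², modal area
≈1.7 µm² ≈ 40 voxels) jointly occupies ≈20 % of the volume — the same
volume fraction the top-20 % extraction rule presumes, which keeps the
quantile threshold inside the foreground–background gap. The
measured-tissue envelope 0.0083–0.18 µm² corresponds to
(µ, σ) = (−1.55, 1.31) and is sub-voxel on this grid, so it is exercised
where only the distributional fit matters, not through voxelised recovery.
Channel centres sit on a jittered square lattice in the transverse plane
(roughly evenly spaced channels; random sequential placement at 20 %
occupancy with a clearance would jam), the largest channels are placed
first, and candidates whose 0.5 µm-padded cross-section touches an
existing channel are re-jittered; persistent overlap is an error.

**Tracer volumes** (`generateTracerVolumes()`): an anisotropic Gaussian
blob on a background equal to the air level (so only the blob crosses the
1.02× air threshold), with a fixed corner air box — the original µCT method
needs an air reference but does not describe its selection. Ground truth
includes the analytic per-axis extent of the super-threshold level set, and
blobs clipped by the volume boundary are flagged.

**Beat series** (`generateBeatSeries()`): intervals
`meanRri + lfAmp·sin(2π·0.1·t) + hfAmp·sin(2π·0.25·t)` laid down
iteratively, SBP modulated analogously; defaults emulate a 10-min resting
recording of a hypertensive adult (RRI 1 s, SBP 140 mm Hg, 2 % ectopics,
2 % dropouts). Ectopics halve or double the interval — the canonical
violations of the 0.6–1.4× cleaning rule — at `round(rate·n)` seeded
positions after the 15th beat, so every ectopic has the history the
relative rule needs and artifact counts are exact; beat times are rebuilt
as the cumulative interval sum so `RRI_i = t_i − t_{i−1}` holds exactly.

**Nerve signals** (`generateNerveSignal()`): DC offset + one
Gaussian-envelope burst per heartbeat (20 ms envelope, 300 Hz carrier
inside the pass band) + white noise, with per-beat burst energy recorded.

What the generators deliberately do **not** model: two-photon PSF blur, CT
beam hardening, baroreflex closed-loop dynamics, real ectopic morphology,
or respiratory non-stationarity. Passing the recovery tests therefore shows
the analysis chain is correct on data matching its stated assumptions — it
does not certify performance on raw microscope or bedside recordings.

# Numerical choices and degenerate inputs

* Quantile: type 7 (linear interpolation); exact `floor(0.2·N)` foreground
  counts hold for distinct intensities when `0.2·(N−1)` is integral, as in
  the tests.
* Log-normal fit: ML variant (divisor n); fewer than 10 areas, any
  non-positive area, or numerically equal areas are errors.
* Ellipse angle: `0.5·atan2(2µ₁₁, µ₂₀−µ₀₂)` mapped to [−π/2, π/2); an
  isotropic footprint reports 0 by convention.
* Sigmoid start values: `c = min`, `d = range`, `y₀ = median(y)`,
  `s = range(y)/10`; non-convergence falls back to linear with a flag (a
  straight-cuboid mask exercises this path).
* Leaky integrator initial state is 0; the discrete step response reaches
  95 % within ≈3τ (within 10 %, as tested).
* Corner evaluation of τ relies on monotonicity in each argument over the
  physical domain (ε ≤ 0.5); the grid cross-check guards the assumption.

# Problem sizes

The recovery suites run at sizes chosen to give stable statistics while
staying desk-sized: pore recovery pools ~112 channels per replicate over
seven 64×64×32 volumes and repeats across five independent seed sets;
orientation recovery pools ~80 ellipses over five volumes; spectral
robustness uses 100 random 10 %-deletion replicates of a 600 s series. At
these sizes the observed errors sit at roughly half the asserted bounds.

# Known limitations

* Cross-sectional areas are recovered from voxel counts; channels narrower
  than ~2 voxels are quantisation-limited, which is why the sub-voxel
  measured-tissue envelope is fitted distributionally rather than through
  the full imaging chain.
* The exact algebra behind the published shear-stress table is not public;
  the Kozeny–Carman + Darcy forms used here reproduce the printed envelope
  only approximately (lower bound exactly, upper bound ≈11 % high), and the
  viscosity/Kozeny pairing is identifiable only as the product µ√K.
* `segmentTracer()` assumes serial scans are already aligned.
* The spectral path assumes beat annotations exist; no R-peak detection is
  performed.
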