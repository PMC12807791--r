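---
title: "Methods: automated LSNR analysis of freehand sphere-phantom sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated LSNR analysis of freehand sphere-phantom sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

A random hypoechoic sphere phantom is a block of tissue-mimicking gel
containing randomly placed spheres of lower backscatter than the
background (here 2 mm diameter, about 48 spheres per mL — a 20% volume
fraction — at −40 dB relative backscatter, in a background attenuating at
0.5 dB cm⁻¹ MHz⁻¹). The operator sweeps a linear-array transducer across
the phantom by hand while the scanner records a cine loop; stacking the
frames gives a 3D volume whose third axis is the sweep (elevational)
direction. Each detected sphere *i* is scored at the elevational frame
where its cross-section is largest:

$$\mathrm{LSNR}_i = \frac{S_{f,i} - S_{b,i}}{\sigma_{b,i}},$$

negative for hypoechoic lesions, and sphere scores are averaged in 25
uniform depth slabs to give the LSNR-vs-depth curve with uncertainty
$\varepsilon_k = \sigma_{\mathrm{LSNR},k}/\sqrt{N_k}$ (sample SD; slabs
with one sphere carry no uncertainty, empty slabs no point).

The maximum cross-section — rather than the mass centroid used with
mechanically guided sweeps — matters for freehand scans: uneven hand speed
samples a sphere asymmetrically, pulling the area-weighted centroid off the
true centre plane and shrinking the measured cross-section. The argmax
frame is insensitive to that asymmetry.

Two conventions are fixed throughout: indices are 1-based `(row, column,
frame)` with depth increasing away from the transducer, and the elevational
axis carries **no physical spacing** — freehand sweeps make it unknown and
non-uniform, so every elevational operation works in frame units.

## Pipeline and parameters

**Volume extraction.** Frames are stacked in acquisition order with
intensities preserved bit-exactly; no display look-up table is applied,
because all statistics must come from the recorded image. The display
overlay is cropped at the first all-zero row/column scanning outward from
50 pixels off the frame centre (so anatomy-free central lines cannot
trigger a crop), and the first and last 10 depth rows — surface reflection
and poor-signal zones — are discarded. The result, `x0`, is the volume all
LSNR statistics are computed on.

**Preprocessing (segmentation volume only).** 3D non-local means with a
9-pixel isotropic search window, 3-pixel comparison patches, and strength
`sd(x0)/8`, followed by multiplicative bias-field correction: a tensor
B-spline surface (8 control points along depth, 4 along each other axis —
attenuation varies mainly with depth) is least-squares fitted to the
log-intensities and divided out, preserving the global mean. The fit is
made robust to the spheres — a fifth of the voxels, all dark — by
iteratively imputing voxels whose log-residual falls below −2 background
scales (estimated by mirroring the non-negative residuals) from the current
fit and refitting; without this the 128-degree-of-freedom field chases
sphere clusters and *adds* background variance instead of removing shading.
Window and patch "size" are read as full widths (radii 4 and 1); NLM
windows are clipped at volume borders; zero voxels are shifted by
`1e-3 × mean` before the log.

**Depth-adaptive thresholding.** The volume is split into 10 depth slabs
(boundaries at `round(k·n/10)`). Within a slab, all-voxel mean/SD would be
badly biased by the 20% sphere fraction, so the background Gaussian is
estimated from the histogram instead: its peak `μ_k` (256 uniform bins over
the slab's range; ties to the lowest bin, the conservative direction) is
the background mean, and since the background is the brighter component,
every voxel at or above `μ_k` is background — mirroring that right
half-sample around `μ_k` reconstructs the full Gaussian, whose *population*
SD is `σ_k` (the mirrored set is a constructed distribution with known mean,
not a sample). The threshold is `T_k = μ_k − 2σ_k`; voxels strictly below
it form the raw mask `m0` (boundary values are background). Three
iterations of binary opening clean `m0` into `m1`. The opening uses the
**in-plane 4-connected cross, frame by frame**: at realistic freehand frame
spacings a 2 mm sphere spans only 2–5 frames, and even one erosion along
the elevational axis of a 3D structuring element would annihilate every
sphere; the in-plane opening removes speckle-sized responses while leaving
the elevational structure intact.

**Splitting touching spheres.** At 20% volume fraction most spheres touch a
neighbour, so `m1` is broken into single spheres by a seeded watershed: the
exact Euclidean distance transform of `m1` (voxel units, elevational axis
treated as isotropic — consistent with the pixel-unit seed rule), seed
candidates where the distance equals its maximum over an 11³ window,
connected candidate plateaus collapsed to their strongest voxel, then a
greedy strongest-first pass enforcing the 5-voxel minimum seed separation;
flooding proceeds by decreasing distance with 6-connectivity, restricted to
`m1`, FIFO on ties, so the labelling is deterministic. Any component left
seedless by the separation rule keeps its own label, so the labelled
support always equals `m1`. Labels touching the first or last frame are
flagged: their maximum cross-section may lie outside the acquired stack
(excluded from eligibility by default, configurable).

**Eligibility.** A cleanly segmented sphere of diameter *d* has a maximum
cross-section of `πd²/4`; objects outside `[0.5, 1.25]` times that area are
under-split clusters or over-split fragments and are excluded (inclusive
bounds). At 0.14 mm pixels and d = 2 mm the band is roughly 80–200 pixels.

**LSNR.** The sphere mask in the argmax frame is eroded by 3 pixels
(in-plane cross) so the PSF-blurred rim does not dilute the lesion mean; if
erosion empties the mask the sphere is dropped with a logged reason. The
background for sphere *i* is a cylinder of diameter 4d centred at the
sphere's in-plane position and spanning *all* frames — the background is
statistically identical at equal depth across frames, and pooling shrinks
the estimate's variance — minus the raw mask `m0` dilated by one voxel
(6-connected); the raw rather than opened mask is used because it excludes
more sphere-contaminated voxels. `σ_b` is the population SD over the
thousands of cylinder voxels, while slab statistics across few spheres use
the sample SD. Spheres with fewer than 100 background voxels or zero noise
are dropped with a warning.

**Repeatability.** Across repeated acquisitions on identical depth
settings, curves are aligned by slab index and the per-slab relative SD
(sample SD across acquisitions over |mean|, in percent) is averaged over
slabs where every acquisition has a value; sphere-count curves are treated
identically, and a single-depth report (e.g. 2.2 cm) is available.

## The simulator

The generator emulates the study conditions in the display domain rather
than simulating RF physics, because the analysis consumes display images
and every behaviour tested here — thresholding, splitting, LSNR invariances,
freehand asymmetry — depends only on image-domain statistics. Defaults are
the phantom/acquisition design: 2 mm spheres at a 20% volume fraction
(48/mL), −40 dB sphere backscatter (amplitude ratio 0.01), 0.5 dB cm⁻¹ MHz⁻¹
two-way attenuation at 15 MHz, 0.14 × 0.14 mm² pixels, 62-frame loops of
4.13 s. Sphere centres are dart-thrown with a minimum separation of one
diameter: the physical phantom contains solid gel spheres, which touch but
cannot interpenetrate (overlapping placements would create objects no
method could resolve). Each frame receives partial-volume-weighted sphere
amplitudes over a 1 mm slice thickness (5 elevational quadrature points),
depth attenuation, multiplicative Rayleigh speckle (unit mean) blurred by
an anisotropic in-plane PSF — σ = 0.5 px axial and 1.1 px lateral,
i.e. ≈0.16/0.36 mm FWHM, the resolution scale of a 15 MHz linear array —
constant-SD additive electronic noise (so deep-region SNR falls), and
logarithmic compression over a 60 dB display range quantized to 8 bits.
Freehand motion is modelled by perturbing uniform frame steps with Gaussian
jitter (fractional SD `speed_jitter`) and renormalizing to the coverage.
Optional exact-inverse gain compensation is off by default. The default
phantom block is 2 × 1.6 × 4 cm — large enough for several hundred spheres
while keeping an analysis under ~15 s on one core; scale the tests'
problem sizes, not their logic.

What the simulator does **not** emulate: diffraction and speckle
correlation from a real beam, scan-line geometry, reverberation or shadow
artefacts, true log-compression constants of any vendor, or elevational
beam profiles beyond a rectangular slice-thickness window. Passing tests
therefore show the *algorithm* behaves as designed on images with the right
first-order statistics, not that any particular scanner meets a spec.

## Sampling and the splitting of touching spheres

The seed rule — local distance-map maxima at least 5 voxels apart — is an
empirical parameter of the method. In a freehand stack its unit mixes
0.14 mm pixels in-plane with one *frame* elevationally, and that has a
practical consequence we derived and verified with controlled two-sphere
experiments: the distance-map peaks of a touching, sweep-aligned sphere
pair sit approximately `(s − 0.6 mm)/Δ` frames apart (s = centre distance,
Δ = interframe spacing; the 0.6 mm is peak pull-in from the slice
thickness), so touching pairs (s = d = 2 mm) are only split when
Δ ≲ d/8 ≈ 0.25 mm. At Δ = 0.33 mm (a 2 cm sweep in a 62-frame loop, the
slowest of the emulated sweep speeds) about 10–13% of fully imaged
spheres share a label with a sweep-aligned neighbour and one of each such
pair is lost, capping one-to-one recovery at ≈0.87–0.90; at Δ ≈ d/8 the
pipeline recovers 98–100% of fully imaged spheres with a mean equivalent
diameter within 0.5% of the design. Note the standard d/4 sampling rule
only protects the *size* of the maximum cross-section (worst-case diameter
underestimate `1 − sqrt(1 − (Δ/d)²)` ≈ 3.2%, ≈1% on average); reliable
*splitting* of touching spheres is the stricter constraint. Practical
guidance: for sphere-count fidelity, sweep slowly enough that the
interframe distance approaches d/8. The LSNR curve itself is far more
forgiving — losing one sphere of a touching identical pair barely moves a
slab mean, which is why LSNR repeatability stays near 5% while sphere
counts scatter by 15–30% under speed jitter.

## Numerical and design choices

- **Histogram bins**: 256 uniform bins over the slab range; robust to
  rescaling and matches 8-bit provenance. Configurable.
- **Peak ties** go to the lowest bin: a lower `μ_k` lowers the threshold
  and admits fewer false sphere voxels.
- **NLM weights** use `exp(−D/h²)` with D the mean squared patch
  difference, tabulated on a 1024-entry grid (weights below 1.2 × 10⁻⁷
  treated as zero); the offset decomposition makes the cost linear in
  voxels × offsets, and each symmetric offset pair is visited once.
- **Bias correction** uses 4 impute-and-refit passes; the complete-grid
  tensor least-squares factorizes mode by mode, so each pass costs three
  small matrix products.
- **Watershed determinism**: priority queue ordered by (distance,
  insertion order), so re-running an analysis is byte-identical.
- **Degenerate inputs**: all-overlay frames, sub-32×32 FOVs, <3 frames,
  missing spacing and non-positive volumes raise classed errors
  (input/config/numeric) that the CLI maps to exit codes 2/3/4; empty
  masks, zero-contrast scans and empty curves are valid results, not
  errors.
- **Depth of a sphere** is `depth_offset + (row − 1) × axial_spacing`;
  curve slabs bin half-open `[y_k, y_{k+1})` with the deepest edge closed.
- **Affine display transforms** (`a·x + b`, a > 0) cancel exactly in the
  LSNR, which the tests exploit as the gain-invariance property; clipping
  the display ceiling deflates `σ_b` and *inflates* |LSNR| — the
  dynamic-range artefact — reproduced directionally on simulated volumes.

## Known limitations

- Linear-array geometry only; no scan conversion or curved-array handling,
  no Doppler/colour overlay parsing.
- DICOM containers are not read directly; export cine frames to PNG/TIFF
  or NIfTI first.
- Sweep-aligned touching spheres merge at interframe spacings coarser than
  ≈d/8 (see above); counts are affected, LSNR curves only marginally.
- The bias model is a smooth multiplicative field on a fixed control grid;
  focal banding sharper than the grid spacing is not corrected (the
  depth-adaptive thresholds absorb the residual).
- Multiple acquisitions are compared by slab index and require identical
  depth settings; no depth registration is attempted.
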