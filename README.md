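# rhsp — automated LSNR analysis for random hypoechoic sphere phantom scans

Ultrasound QA/QC needs a quantitative, operator-independent measure of how
well a scanner lets a reader detect small low-contrast lesions. A random
hypoechoic sphere phantom (RHSP) — tissue-mimicking gel densely packed with
2 mm spheres whose backscatter sits 40 dB below the background — provides
exactly that: sweep a transducer freehand across the phantom while recording
a cine loop, stack the frames into a volume, segment every sphere, and score
each one with its **lesion signal-to-noise ratio**

```
LSNR_i = (Sf_i − Sb_i) / σb_i
```

where `Sf_i` is the mean intensity inside sphere *i* at its maximum
elevational cross-section, and `Sb_i`, `σb_i` are the mean and standard
deviation of the surrounding background. LSNR is negative for hypoechoic
lesions; larger magnitude means better detectability. Averaging spheres in
depth slabs yields the LSNR-vs-depth curve, the phantom's summary of system
performance, with per-slab uncertainty `ε_k = σ_LSNR,k / √N_k`.

The package implements the full analysis pipeline for freehand sweeps —
where the frame-to-frame distance is unknown and uneven — plus a speckle
phantom simulator with known ground truth so every stage is testable without
a scanner:

1. **Volume extraction** — stack the cine frames, crop the display overlay,
   drop the unreliable first/last 10 depth rows (`read_cine()`,
   `extract_fov()`).
2. **Preprocessing** — 3D non-local-means denoising (9-pixel search window,
   3-pixel patches, strength `sd(x0)/8`) then B-spline bias-field correction
   on an 8×4×4 control grid (`nlm_denoise()`, `bias_correct()`). Used only
   for segmentation; all LSNR statistics come from the raw volume.
3. **Depth-adaptive thresholding** — 10 depth slabs; in each, the background
   Gaussian is estimated from the histogram peak and the mirrored right
   half-sample (robust to the ~20% sphere voxels), threshold `T_k = μ_k −
   2σ_k`; 3 iterations of in-plane binary opening (`slab_thresholds()`,
   `segment()`).
4. **Sphere separation** — Euclidean distance transform, seed points at its
   local maxima with 5-voxel minimum separation, seeded 3D watershed
   (`split_connected()`); maximum elevational cross-section per label, and
   an area band `[0.5, 1.25]·πd²/4` rejecting merged or fragmented objects
   (`max_cross_sections()`, `area_filter()`).
5. **LSNR measurement and curves** — per-sphere signal from the 3-pixel
   eroded max cross-section, background from a 4d-diameter cylinder across
   all frames minus the dilated raw mask, 25-slab LSNR-vs-depth curve
   (`measure_lsnr()`, `lsnr_curve()`), repeatability RSDs across
   acquisitions (`variability()`, `compare_acquisitions()`).

## Worked example

Simulate a default phantom (2 mm spheres, 20% volume fraction, −40 dB
contrast, 0.5 dB/cm/MHz attenuation at 15 MHz) swept over 2 cm in a
62-frame loop, and analyze it:

```r
library(rhsp)

sim <- simulate_acquisition(phantom_spec(), scan_profile(coverage_cm = 2),
                            seed = 1)
a <- analyze(sim$volume)
a
#> <rhsp_analysis> 247 labelled objects, 176 eligible spheres
#>   peak LSNR -12.51 at 0.31 cm; depth range 0.14-1.85 cm

glance(a)
#> # A tibble: 1 × 5
#>   n_eligible n_measured peak_lsnr peak_depth_cm mean_equiv_diameter_mm
#> 1        176        176     -12.5         0.311                   1.98

head(a$curve)
#> # A tibble: 6 × 6
#>    slab depth_cm   lsnr sigma_lsnr epsilon n_spheres
#> 1     1    0.174 -12.3       4.15    1.85          5
#> 2     2    0.242 -12.5       2.43    0.860        8
#> 3     3    0.311 -12.5       0.366   0.150        6
#> ...

truth_recovery(a, sim$truth)$recall
#> [1] 0.887
```

176 eligible spheres were measured; their mean equivalent diameter
(1.98 mm) recovers the designed 2 mm, the LSNR is strongest (−12.5) in the
shallow slabs and decays with depth as attenuation erodes the signal, and
88.7% of the fully imaged true spheres map one-to-one to eligible
measurements at this sweep speed (touching sphere pairs aligned with the
sweep merge unless the interframe spacing is below about d/8 — see the
methods vignette). `autoplot(a$curve)` draws the LSNR-vs-depth curve with
error bars; `write_analysis(a, "results/")` persists the per-sphere table,
the curve and a JSON summary; `compare_acquisitions()` turns repeated runs
into the repeatability report. A thin command-line front end with
`simulate` / `analyze` / `compare` subcommands lives in `inst/cli/rhsp.R`.

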