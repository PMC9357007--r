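---
title: "Quantifying fibrillar collagen architecture and matrisome dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrillar collagen architecture and matrisome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrarch)
```

`fibrarch` quantifies how fibrillar collagen is organised in microscopy
images and how the matrisome — the ensemble of extracellular-matrix (ECM)
and ECM-associated proteins — changes over time in label-free proteomics.
The motivating biology is the remodelling of the breast-tumour
microenvironment: as tumours progress, stromal fibroblasts deposit and
reorganise collagen I into thicker, more aligned, more correlated
bundles, the tissue stiffens, and cancer cells invade more readily. Every
analysis the package implements returns a scalar or a small table that
can be compared across conditions, and every input it needs can be
generated synthetically with known ground truth, so the entire pipeline
is testable without any external data.

This vignette explains the models and procedures, the tunable parameters
with their defaults and units, what the synthetic generators do and do
not emulate, and the numerical choices made where the design was open.

## Image analyses

### Coordinate and calibration conventions

Images are numeric matrices, row-major with the origin at top-left. The
x axis is the column axis; angles are measured from +x, anticlockwise
positive (y up), and fibre orientations live on the axial half-circle
(−90°, 90°] with period 180°. Physical calibration is µm per pixel;
`read_image()` resolves it with the precedence *explicit override → TIFF
resolution tags → plain-text `.calib` sidecar → error*. The bundled TIFF
writer cannot emit resolution tags, so `write_image()` records the pixel
size in the sidecar; externally produced TIFFs with proper tags are read
directly. Microscope vendor formats (LIF/CZI) are out of scope.

### GLCM correlation curves

The grey-level co-occurrence matrix (GLCM) at offset distance *d* and
direction θ is the joint histogram of pixel-value pairs (value at p,
value at p + offset). Its Haralick correlation

$$\rho(d, \theta) = \sum_{i,j} \frac{(i-\mu_i)(j-\mu_j)\,p(i,j)}{\sigma_i \sigma_j}$$

measures how predictable the signal is across distance *d*: an organised
fibre network stays correlated over longer offsets than a disordered
one. `glcm_correlation_curve()` evaluates ρ at d = 1..D in the four axis
directions (0°, 90°, 180°, 270°), reports the per-distance direction
mean, a normalised curve (each distance divided by the d = 1 value, for
cross-image averaging), and the scalar summary — the average of the
direction-mean correlation over all distances. Defaults: D = 50 px and
64 grey levels (8-bit images rebinned uniformly), a common Haralick
compromise between count sparsity and grey resolution; both are
arguments. Direction-specific (asymmetric) counts are retained; the 0°
and 180° matrices are transposes, and the equality of their correlations
is asserted in the tests as a self-check. Undefined entries (zero
marginal variance) are flagged and excluded from means rather than
silently zeroed.

### Structure-tensor orientation and the peak-to-baseline ratio

Local fibre orientation comes from the structure tensor. Spatial
derivatives are taken from the cubic B-spline representation of the
image: the recursive prefilter (pole $\sqrt3 - 2$) yields spline
coefficients, and the exact derivative of the spline at the sample
points reduces to a [−½, 0, ½] convolution of the coefficients along the
derivative axis and the sampled B-spline [1/6, 2/3, 1/6] along the
other. The tensor components ⟨fx²⟩, ⟨fy²⟩, ⟨fx fy⟩ are Gaussian
window averages (default SD 4 px — common structure-tensor practice, and
an argument). The gradient direction is ½·atan2(2Jxy, Jxx − Jyy); the
reported angle is the *fibre* direction, i.e. the gradient rotated by
90°, wrapped to (−90°, 90°]. Coherency is the eigenvalue contrast
(λ₁ − λ₂)/(λ₁ + λ₂) in [0, 1], defined as 0 where the tensor trace
(energy) vanishes.

`orientation_distribution()` histograms the per-pixel angles over the
half-circle (default 180 bins, an argument) with selectable weighting:
`coherency_energy` (default — suppresses background), `energy`, or
`none`. `align_and_ratio()` circularly shifts each curve so its smoothed
mode (moving average, window 3 bins) sits at 0°, enabling group mean ±
SEM curves, and summarises alignment as peak / baseline. The baseline is
the mean of the lowest quartile of the smoothed curve; the bare minimum
is noise-sensitive, so the rule is exposed
(`min | lowest_quartile_mean | lowest_decile_mean`). A delta
distribution has zero baseline and reports `Inf`. The ratio is ≈1 for an
isotropic fibre field and grows with alignment; it is invariant to
global intensity scaling.

### SHG peak signal and fibre-bundle widths

For second-harmonic-generation (SHG) z-stacks, `shg_peak_signal()`
computes a per-plane statistic (mean by default, or the 99th percentile)
and reports the maximum over planes with its plane index — the peak
multi-photon signal of the acquisition.

`profile_peak_widths()` measures fibre-bundle diameters from intensity
profiles: the image is tiled 3 × 3 (the grid is an argument); in each
tile, profile lines (5 per tile by default) run perpendicular to the
tile's dominant orientation taken from the structure tensor, since a
transect across the fibres is what makes a peak width a diameter.
Fixed-axis profiles (`axis = "horizontal"` or `"vertical"`) are
available for strict mimicry of manual line profiles. Intensity is
sampled along each line by bilinear interpolation at 0.25-px steps;
peaks must rise above 0.3 × the tile dynamic range in prominence
(argument `prominence_frac`), and each peak's width is the full width at
half prominence with linearly interpolated crossings, converted to µm.
Peaks narrower than 2 px (sub-resolution) or truncated at a profile end
are discarded. A flat image returns an explicit empty result, never a
zero width.

### Stain segmentation in HSB space

Histological quantification uses hue–saturation–brightness boxes on
0–255 integer scales (the ImageJ convention; hue is a 0–255 wheel). The
fibrillar-collagen (picrosirius red) box is H 200–240, S 150–255,
B 0–255, read as lo ≤ channel ≤ hi. The birefringence profile adds
yellow (H 30–60) and green (H 70–140) boxes with the same S/B ranges —
these two hue ranges are package defaults, exposed in `stain_boxes()`,
not literature values. Tissue is defined as "not white slide
background": B ≤ 230 or S ≥ 30 (both arguments), and class areas are
reported as fractions of tissue area. Overlapping class boxes are an
error unless explicitly allowed. DAB-positive area defaults to a brown
HSB box (H 0–30, S 50–255, B 20–220, a package default); a standard
H-DAB colour-deconvolution path (Ruifrok–Johnston stain vectors,
threshold on the DAB optical-density channel, default 0.15) is the
alternative.

## Study morphometrics

Closed-form metrics follow their operational definitions with strict
boundary semantics:

* **Invasive index** = invading / (invading + non-invading), where a
  cell invades only when strictly deeper than 50 µm below the matrix
  surface (the 50-µm cell is non-invading). Undefined for zero cells.
* **Tumour volume** = (max dimension² × min dimension) × 0.52, in mm³;
  10 mm × 10 mm gives 520 mm³. Swapped dimensions are corrected with a
  warning; the formula is homogeneous of degree 3.
* **Metastasis burden** counts foci strictly larger than 100 µm²,
  normalised to total lung cross-sectional area; a 100 µm² focus is
  excluded. `focus_areas_from_mask()` converts a labelled mask to areas
  via the pixel calibration; segmentation itself is out of scope.
* **Compressive elastic modulus** is the slope of the linear
  viscoelastic region of a stress–strain curve (kPa), with force
  converted to stress by the contact area when needed.

The linear-region delimitation deserves detail because no standard
exists. A window of 30% of the points (argument) slides across the
curve; the *latest* (highest-strain) window whose OLS fit reaches
R² ≥ 0.99 (relaxed stepwise by 0.01 with a warning when noise makes
0.99 unattainable) seeds the estimate — in unconfined compression the
linear region sits at high strain, and a latest-window rule cannot seed
inside the toe, whereas a global max-R² pick can when noise is
comparable to the signal. The seed fit is then refined by iteratively
trimmed least squares over the whole curve: points deviating more than
2 residual-SEs from the current line are dropped and the line refitted
until membership stabilises. Refitting-free outward growth was rejected
during development: judging candidates against a fit that absorbs them
lets the concave toe creep in, while R²-based stopping is insensitive
because R² keeps *rising* as the toe adds variance. The retained point
range is always reported (`region`, `strain_range`) so the selection is
auditable.

## The matrisome temporal pipeline

The proteomics arm starts from a proteins × samples matrix of raw
positive intensities with missing values, a design of two tissues
(healthy, tumour) × three stages (early, mid, late), and a matrisome
annotation (division and category per the Naba scheme).

1. **Presence filter**: proteins quantified in ≥ 70% of all samples are
   retained (`min_frac` argument); a protein present in 20/29 samples
   (69.0%) is removed, 21/29 (72.4%) retained.
2. **Transform**: log2, then per-sample median centring; doubling all
   raw intensities changes nothing downstream. For clustering, each
   protein's six condition medians are z-scored.
3. **Differential abundance**: one-way ANOVA across the six
   tissue × stage groups, computed vectorised over matrix rows
   (validated against `oneway.test` in the tests), with
   Benjamini–Hochberg q-values and a 0.05 FDR flag. Missing values are
   dropped per protein; no imputation is performed — a protein without
   two groups of ≥ 2 observations, or with zero residual variance, is
   flagged untestable and never significant. BH was chosen over
   permutation-based FDR because it is deterministic and directly
   testable against the step-up definition; the null calibration of the
   whole pipeline is itself a test.
4. **Volcano statistics**: per-stage Welch t between tissues on the
   transformed values; the log2 fold change is the tumour − healthy
   mean difference.
5. **Temporal clustering**: agglomerative clustering of the z-scored
   condition-median profiles, Euclidean distance, average linkage
   (argument), cut at k = 4. Cluster labels are canonicalised by
   descending mean tumour-late z-score so C1..C4 are stable across runs
   and row orders. Proteins with a fully missing condition are excluded
   and reported.
6. **Category enrichment**: two-sided Fisher exact test on the 2 × 2
   table of each cluster × category pair, BH-adjusted across all pairs.
7. **PCA**: SVD-based, samples as observations, restricted to proteins
   present in all samples; scores, loadings, variance explained and the
   top-|loading| proteins per component.

## Synthetic data: what it emulates and what it does not

`make_fibre_phantom()` renders straight fibre segments with Gaussian
cross-section (FWHM in px), axial von Mises orientations (sampled on
the doubled angle with the Best–Fisher rejection method, then halved —
the standard axial construction; κ = 0 is isotropic, κ ≥ 10⁶ the
all-parallel limit), uniform centres, additive Gaussian noise and a
constant background. Overlaps combine by maximum rather than sum so the
per-fibre width ground truth stays valid — SHG intensity of overlapping
fibrils does not add linearly in the FWHM sense. The phantom emulates
geometry and first-order noise only: no optical point-spread function,
no depth attenuation, no fibre curvature or branching. Passing tests on
phantoms therefore demonstrate the correctness of the estimators on
known geometry, not their robustness to every property of real tissue.

`make_stain_phantom()` plants exact pixel counts per HSB class
(`round(fraction × n_pixels)`), drawing channel values uniformly inside
each box with a 3-step interior margin and brightness ≥ 80, because the
integer RGB grid quantises hue and saturation coarsely at low
brightness and would otherwise move edge pixels across a box boundary
on round-trip. Pixels outside every class are pale pseudo-tissue
(inside the tissue mask, outside all boxes), so planted fractions are
fractions of tissue area. No histological texture is synthesised.

`simulate_abundance()` plants four temporal profiles over the six
conditions (in log2 units, scaled by `effect_size`, default 2): a
cluster rising in both tissues but higher and faster in tumour; one
uniformly elevated in tumour at all stages; one progressively
downregulated with progression; one down at early/mid and up at late;
plus a null set. Defaults follow the study design the package targets:
five replicates per group, residual SD 0.5 in log2 space, 10% missing
completely at random — MCAR because the filter under test is
presence-count based; intensity-dependent missingness is deliberately
not modelled. `simulate_stress_strain()` produces a quadratic toe
(stress = E·s²/(2·toe_strain), C¹-continuous with the linear region of
slope E) plus Gaussian noise; real tissue viscoelasticity
(time-dependence, hysteresis) is not modelled.

## Study conditions used by the tests and the acceptance script

All recovery experiments run at sizes chosen to exercise the estimators
well inside a desktop run: orientation phantoms are 384 × 384 px with
2000 fibres of length 40 px and noise SD 15 (a dense quasi-isotropic
network needs many independent fibre patches for a flat histogram —
about 10⁵ effective orientation samples); mode recovery uses 36 bins
and the alignment-ratio sweep 12 bins with energy weighting, whose
noise floor keeps the baseline finite even for strongly aligned fields;
GLCM oracle equivalence uses 200 random images up to 16 × 16 at 2–8
grey levels; the FDR calibration uses 200 null simulations of 500
proteins; cluster recovery uses 40 proteins per planted cluster over 10
seeds; modulus recovery 20 curves of 100 points at noise SD 0.01 kPa.

## Reproducible runs

`run_pipeline()` executes selected stages from a single flat YAML (or
list) config. Unknown keys are rejected before any computation; every
output TSV carries a provenance header (package version, stage, seed,
parameters) and the run directory a `manifest.json` with md5 checksums.
With the same config and seed, payloads are byte-identical. A thin
command-line wrapper lives at `inst/cli/fibrarch.R`; the R functions
are the primary interface.

## Known limitations

* 2-D only: no 3-D orientation tensors or volumetric GLCM; z-stacks are
  analysed plane-wise.
* The structure-tensor mode is quantised to the histogram bin width;
  with 36 bins the mode cannot be localised better than ±2.5°.
* The peak-to-baseline ratio is unbounded for fields with an empty
  baseline; comparisons across images should fix the bin count and
  weighting.
* The hue-wheel convention of the picrosirius thresholds (0–255) and
  the reading of the printed relations as lo ≤ H ≤ hi are documented
  interpretations, exposed as configuration.
* No stain normalisation, nuclei counting, whole-slide tiling, raw
  mass-spectrometry search, or survival modelling: the package begins
  at calibrated images, segmented foci and protein-abundance matrices.
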