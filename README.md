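# fibrarch

Quantification of fibrillar-collagen architecture from microscopy images
and of matrisome dynamics from label-free proteomics.

## What it is for

In solid tumours — the breast-tumour microenvironment in particular —
stromal fibroblasts progressively remodel fibrillar collagen: bundles
thicken, align, and become spatially more correlated, tissue stiffens,
and cancer-cell invasion and metastatic dissemination increase. Testing
such hypotheses requires turning images, histology, mechanics and
proteomics into comparable numbers. `fibrarch` implements that
quantification layer for R users:

* **Texture** — grey-level co-occurrence (GLCM) Haralick correlation as
  a function of pixel offset in four directions, with the scalar mean
  correlation summarising network organisation:
  ρ(d, θ) = Σᵢⱼ (i−μᵢ)(j−μⱼ) p(i,j) / (σᵢσⱼ).
* **Orientation** — per-pixel fibre angle and coherency from cubic
  B-spline structure tensors; angular histograms aligned on their mode
  and summarised by the peak-to-baseline ratio (≈1 isotropic, large for
  aligned fields).
* **Morphometry** — SHG peak signal over z-stacks; fibre-bundle widths
  as full width at half prominence of intensity profiles run
  perpendicular to the local fibre direction, in µm.
* **Histology** — picrosirius-red, birefringence hue-class (red /
  yellow / green) and DAB-positive areas as fractions of tissue area by
  HSB thresholding (H 200–240, S 150–255, B 0–255 for fibrillar
  collagen on the 0–255 wheel), with an optional H-DAB
  colour-deconvolution path.
* **Study metrics** — invasive index (invading / total, strict > 50 µm
  depth rule), calliper tumour volume ((max² × min) × 0.52 mm³),
  metastasis burden (foci strictly > 100 µm², normalised to lung area),
  and compressive elastic modulus as the slope of the linear
  viscoelastic region of a stress–strain curve.
* **Matrisome proteomics** — 70% presence filtering, log2 per-sample
  median centring, vectorised one-way ANOVA and Welch volcano
  statistics with Benjamini–Hochberg control, hierarchical temporal
  clustering of condition-median z-profiles into four canonical
  clusters, Fisher category enrichment, and PCA.
* **Synthetic data** — fibre phantoms with axial von Mises
  orientations, stained-slide phantoms with exact planted hue-class
  fractions, abundance matrices with planted temporal clusters, and
  toe + linear stress–strain curves: every analysis is testable with
  known ground truth and no downloads.

See `vignettes/fibrarch-methods.Rmd` for the models, parameter
defaults, and design decisions.

## Worked example

```r
library(fibrarch)

## a dense, partially aligned fibre network with known ground truth
phantom <- make_fibre_phantom(c(256, 256), n_fibres = 900,
                              fibre_length_px = 40, mean_angle = 30,
                              kappa = 4, noise_sd = 15, seed = 1)

field <- structure_tensor(phantom$image)
align_and_ratio(orientation_distribution(field, n_bins = 36,
                                         weighting = "energy"))$bin_offsets_deg
#> [1] 32.5
align_and_ratio(orientation_distribution(field, n_bins = 12,
                                         weighting = "energy"))$peak_to_baseline
#> [1] 675.0404
glcm_correlation_curve(phantom$image, max_distance_px = 30)
#> glcm_curve: d = 1..30, 64 levels, summary mean correlation 0.1111 (0 undefined entries)
profile_peak_widths(phantom$image)
#> bundle widths: 94 peaks, mean 11.7 um
```

The recovered orientation mode (32.5°) sits within one 5°-bin of the
planted 30°; the large peak-to-baseline ratio reflects the strong
alignment at κ = 4 (an isotropic κ = 0 phantom gives ≈1.4); the GLCM
summary drops when the same density is rendered isotropically; bundle
widths are means over detected profile peaks (overlapping fibres merge
into wider bundles than the single-fibre FWHM).

Mechanics and the closed-form metrics:

```r
sc <- simulate_stress_strain(modulus = 12, toe_strain = 0.05,
                             noise_sd = 0.01, n_points = 100, seed = 1)
bulk_modulus(sc$strain, sc$stress)
#> Compressive elastic modulus: 11.98 kPa
#>   linear region: points 22-100 (strain 0.042-0.200), R^2 = 0.9998
tumour_volume(10, 10)
#> [1] 520
```

The modulus fit reports the strain region it used, so the
linear-region selection is auditable; the 10 mm × 10 mm calliper
volume is the 520 mm³ humane-endpoint value.

Temporal proteomics on simulated data with planted clusters:

```r
sim <- simulate_abundance(n_per_cluster = 40, n_null = 0, seed = 1)
norm <- normalise_abundance(filter_presence(sim$matrix))
temporal_cluster(condition_profiles(norm, sim$design), k = 4)
#> temporal clustering: 160 proteins into 4 clusters (average linkage)
#> C1 C2 C3 C4
#> 40 40 40 40
```

All 4 × 40 planted proteins land in their own cluster; labels are
canonicalised by descending tumour-late z-score, so C1..C4 are stable
across runs.

Multi-stage reproducible runs go through `run_pipeline()` (flat YAML
config, provenance headers, manifest with checksums); a thin
command-line wrapper is installed at `inst/cli/fibrarch.R`.

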