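# gliavasc

Quantification of glial activation and glia–vasculature physical contact
from calibrated multi-channel 3-D fluorescence microscopy stacks.

## The problem

In the neurovascular unit, perivascular astrocytes and microglia respond to
systemic inflammation with two coupled morphological programs: their cell
bodies hypertrophy, and their physical apposition to blood vessels changes —
astrocytic endfeet retract from vessel walls while microglial processes
increase their vessel contact, with perivascular aquaporin-4 (AQP4)
declining alongside. gliavasc implements the image-analysis side of that
biology for two-channel (glial + vascular) two-photon stacks and
CD31/AQP4-stained confocal stacks:

* **Soma volumetry** — mean glial cell-body volume V̄ (µm³): whole-stack
  Rényi-entropy thresholding of the glial channel, morphological opening
  with an anisotropic ellipsoid (pixel radii 5.5, 5.5, 2 in x, y, z) to
  strip processes, marker-based watershed on the Euclidean distance
  transform to split touching somata, then feature filters
  (V ≥ 200 µm³, mean intensity ≥ 60, flatness R2/R3 ≤ 3.5).
* **Contact ratio** — 100 · |G ∧ V| / |V|, the percentage of vessel volume
  overlapped by the glial mask, after Gaussian smoothing (σ = 2 px),
  0.7 % contrast saturation, spectral-crosstalk subtraction of the vessel
  channel from the glial channel, and Otsu segmentation of both channels.
* **AQP4 surface contact** — 100 · |surface voxels within Chebyshev
  distance 1 of AQP4| / |vessel surface voxels|, plus total AQP4 volume.
* **2-D immunopositive area** — Iba1⁺/GFAP⁺ area (µm²) on
  maximum-intensity projections (IsoData "Default" and MaxEntropy
  thresholds respectively).
* **Group statistics** — Shapiro–Wilk screening, ordinary or
  repeated-measures one-way ANOVA, Tukey HSD or Welch t follow-ups, and
  percent-change summaries against a baseline condition.

Because raw intravital data of this kind are rarely shareable, the package
ships a synthetic-volume generator (`generate_stack()`) producing
calibrated stacks — tubular vessels, ellipsoidal somata with processes,
perivascular endfoot sleeves with controllable vessel coverage, an AQP4
shell with controllable surface coverage, spectral crosstalk and Gaussian
noise — together with exact ground truth, so every pipeline stage is
validated by parameter recovery.

## Worked example

```r
library(gliavasc)

# a synthetic glial stack: 3 somata of known volume, two-photon calibration
sim <- generate_stack(synth_params(
  shape = c(64, 192, 192), n_vessels = 0, n_cells = 3,
  soma_volume_range = c(250, 500), coverage_fraction = 0,
  noise_sd = 237, seed = 7))

soma <- quantify_soma(sim$stack)
tidy(soma)
#> # A tibble: 3 x 8
#>   label voxel_count volume_um3 mean_intensity flatness    cz    cy    cx
#>   <int>       <int>      <dbl>          <dbl>    <dbl> <dbl> <dbl> <dbl>
#> 1     1       12729       261.          3099.     1.01  55.3 12.3   8.23
#> 2     2       16213       332.          3100.     1.10  20.1  9.25  9.24
#> 3     3       16013       328.          3100.     1.08  39.3 13.4  13.6
glance(soma)
#> # A tibble: 1 x 4
#>   n_objects n_segmented mean_volume_um3 sd_volume_um3
#>       <int>       <int>           <dbl>         <dbl>
#> 1         3           3            307.          40.1
mean(sim$truth$true_soma_volumes)
#> [1] 315.12
```

The per-object table carries voxel count, physical volume, mean native
intensity, equivalent-ellipsoid flatness and the centroid in µm; the
estimated mean soma volume (307 µm³) recovers the ground truth (315 µm³)
to within ~2.5 %. A stack with a vessel channel feeds the contact
pipeline the same way:

```r
vsim <- generate_stack(synth_params(shape = c(64, 192, 192), n_cells = 3,
                                    soma_volume_range = c(250, 500),
                                    coverage_fraction = 0.12, seed = 7))
tidy(quantify_contact(vsim$stack))
#> # A tibble: 1 x 4
#>   glia_voxels vessel_voxels overlap_voxels contact_ratio_percent
#>         <int>         <int>          <int>                 <dbl>
#> 1       76090         43987           4339                  9.86
vsim$truth$true_contact_ratio_percent
#> [1] 12.07
```

Here 9.9 % of the vessel volume is detected as glia-contacted against a
mask truth of 12.1 %. Group-level analysis chains with the pipe:

```r
percent_change(226.9, 334.9)   # e.g. baseline -> day-4 soma volume
#> [1] 47.6
measurements |> build_report(baseline = "control", paired = TRUE)
```

`read_stack()` / `write_stack()` handle calibrated multi-page TIFF
(OME metadata is parsed on read; a YAML sidecar carries voxel size, roles
and bit depth on write), and `run_experiment()` drives a full
simulate → quantify → report run from one YAML configuration (see
`inst/extdata/default-config.yaml`).

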