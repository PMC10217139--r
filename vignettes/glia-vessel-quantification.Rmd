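---
title: "Quantifying glial activation and glia-vessel contact in 3-D fluorescence volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial activation and glia-vessel contact in 3-D fluorescence volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

Perivascular astrocytes and microglia respond to systemic inflammation with
two coupled morphological programs: their cell bodies hypertrophy, and their
physical apposition to the brain vasculature changes — astrocytic endfeet
retract from vessel walls while microglial processes increase their vessel
contact. gliavasc turns calibrated two-channel (glial + vascular) 3-D
fluorescence stacks into four quantitative readouts of this process:

1. **Soma volumetry** — mean glial cell-body volume (µm³) from the glial
   channel alone.
2. **Contact ratio** — the percentage of vessel volume overlapped by the
   glial mask, `100 · |glia ∧ vessel| / |vessel|`.
3. **AQP4 surface contact** — the percentage of the vessel (CD31) surface in
   contact with aquaporin-4, plus total AQP4 volume (µm³), for
   immunostained confocal sections.
4. **2-D immunopositive area** — Iba1⁺/GFAP⁺ area (µm²) on maximum-intensity
   projections, the standard reactivity readout on sections.

A synthetic-volume generator with exact ground truth accompanies the
pipelines so that each stage is testable without any acquired data.

## Pipelines

### Soma volumetry

The glial channel is binarised at a single whole-stack histogram threshold
(Rényi entropy by default; computing the threshold per slice would let one
cell change label across slices). A morphological opening with a discrete
anisotropic ellipsoid of pixel radii (5.5, 5.5, 2) in (x, y, z) removes the
thin processes: one lateral radius, one smaller axial radius matching the
lateral/axial voxel anisotropy of two-photon stacks. Touching cell bodies
are then split by a marker-based watershed on the inverted Euclidean
distance transform of the mask, with markers at the h-maxima of the
distance map (dynamic `h`, default 1 scaled pixel; smaller values oversplit
but never violate the conservation property — the union of labels always
equals the opened mask). Each object is measured on the *original* channel
(opening is a mask operation; intensity filters refer to real signal), and
spurious detections are removed by three inclusive-boundary filters:
volume ≥ 200 µm³, mean native intensity ≥ 60, flatness ≤ 3.5.

Flatness is the equivalent-ellipsoid semi-axis ratio R2/R3 (R1 ≥ R2 ≥ R3),
with semi-axes `Rk = sqrt(5·λk)` from the eigenvalues of the µm-scaled
second-moment matrix; the √5 factor is exact for a uniform solid ellipsoid
and cancels in the ratio. A per-axis voxel self-moment `d²/12` is added so
single-voxel objects have finite, unit flatness. R1/R3 is available via
`flatness_mode` for users who prefer an elongation-type descriptor; R2/R3
is the default because it rejects plate-like artefacts while keeping the
elongated amoeboid somata of activated microglia.

```{r}
library(gliavasc)
stack <- read_stack("stack.tif", roles = c("glia", "vessel"))
soma <- quantify_soma(stack, soma_params())
tidy(soma)     # per-object table
glance(soma)   # mean soma volume
```

### Glia-vessel contact ratio

Both channels are smoothed with a Gaussian of σ = 2 px laterally; the axial
sigma is scaled by the voxel aspect (`σz = σ·dx/dz`) so the kernel is
near-isotropic in physical units (a literal 2-px axial sigma is available
via `sigma_z = "literal"`). Contrast is enhanced by a linear stretch that
saturates 0.7 % of voxels, split equally over both tails (configurable to
one-tailed). Spectral crosstalk of the vascular dye into the glial channel
is removed by voxelwise subtraction of the vessel channel, clamped at zero.
Both channels are segmented by Otsu's method and the contact ratio is the
voxelwise AND of the masks over all z slices, relative to the vessel mask.

**Subtraction order.** The subtraction operates on the *raw* channels,
before the per-channel contrast enhancement (`crosstalk = "before"`). This
was a genuinely open design point, and we resolved it empirically: the
stretch maps each channel onto the full native range, so subtracting the
stretched vessel channel cancels genuine glial signal wherever it
co-localises with a bright vessel — which is exactly the perivascular
signal the contact ratio is supposed to measure. In parameter-recovery
simulations the stretched-subtraction ordering under-estimates known
coverage by roughly four-fold, while raw-channel subtraction tracks the
ground truth; both orderings remain available through
`contact_params(crosstalk = ...)`.

### AQP4-vessel surface contact

The vessel (CD31) and AQP4 channels are smoothed (σ = 1 px) and segmented;
the vessel "surface" is discretised as its 6-connectivity boundary voxels,
and a surface voxel is "in contact" when its Chebyshev distance to the
nearest AQP4 voxel is at most `contact_distance` (default 1). Boundary
voxel counts stand proxy for surface area: the quantity compared across
groups is a relative percentage, for which voxel counting is adequate and,
unlike mesh-based estimates, deterministic and monotone in
`contact_distance`. The CD31 channel uses Otsu; the AQP4 channel defaults
to the Kapur maximum-entropy threshold because perivascular AQP4 occupies
a tiny fraction of the volume and Otsu's between-class variance criterion
provably degenerates to a split of the background noise under extreme
class imbalance (with 0.1 % of voxels in the foreground, splitting the
background Gaussian in half scores a higher between-class variance than
the true split).

### 2-D immunopositive area

Maximum-intensity projection over z followed by automatic thresholding and
pixel counting; the published marker pairing is the default (IsoData
"Default" for Iba1/microglia, MaxEntropy for GFAP/astrocytes). Areas are
reported per field of view; aggregation to per-animal means happens in the
reporting layer.

## Threshold methods

All four methods operate on a 256-bin histogram, also for 16-bit input
(min–max mapped), matching the macro environment the pipelines replicate.
Foreground is always *strictly above* the returned bin. Ties break to the
smallest candidate; because mathematically tied splits do occur (for a
two-delta histogram the class entropies are symmetric around the gap), the
argmax uses a relative tolerance of 1e-9 so the tie-break is well defined
under floating-point rounding. Candidate thresholds are only those with at
least one occupied bin on each side — a guard that matters because
cumulative probabilities can round into (0, 1) even for an empty class.

* `threshold_otsu` — maximises between-class variance ω0·ω1·(µ0−µ1)².
* `threshold_max_entropy` — maximises the summed Shannon entropies of the
  two normalised class histograms (Kapur).
* `threshold_renyi` — per-order Rényi-entropy maxima for orders
  (0.5, 1, 2), combined by the published three-threshold weighting rule
  (thresholds within 5 bins pool their weight on the middle value; the
  final threshold blends the sorted candidates with cumulative-probability
  weights). Orders (1, 1, 1) reduce exactly to the Kapur method.
* `threshold_default_isodata` — iterative intermeans,
  `t ← floor((µ_≤t + µ_>t)/2)` from the histogram midpoint to its fixed
  point.

Every method is tested against an exhaustive search of its stated
criterion on randomly generated histograms.

## The synthetic world

`generate_stack()` renders, at a chosen voxel calibration (default the
two-photon 0.144 × 0.144 × 0.988 µm):

* **Vessels** — correlated random-walk tubes (radius 2 µm, a cortical
  capillary) biased along the longest axis; paths reflect at the lateral
  volume walls so a vessel always traverses the field of view.
* **Somata** — axis-aligned ellipsoids with volumes drawn uniformly from a
  stated range (200–1100 µm³ regime), volume-preserving random axis
  distortions, and a minimum mutual distance; thin 1-voxel processes
  radiate from each soma.
* **Endfeet** — a perivascular sleeve straddling the lumen boundary
  (0.4 µm inward ≈ the lateral optical resolution, 0.8 µm outward), over a
  band whose length realises the requested fraction of vessel voxels
  co-covered by glia. This mirrors real data, where the dextran-filled
  lumen and the abluminal endfoot sheet overlap within the point-spread
  function rather than the endfoot penetrating the lumen.
* **AQP4** — a 1-voxel shell just outside a band of the vessel surface
  covering the requested surface fraction.
* **Channels** — two-level rendering (background 1200, glial foreground
  3100, vessel foreground 2100 in 16-bit native units) plus crosstalk
  `c · vessel` (default c = 0.3) added to the glial channel, and additive
  Gaussian noise. SNR is defined as (foreground − background)/noise_sd.
  Channel gains are deliberately unequal, as they are at acquisition where
  each detector is set independently; 16-bit rendering keeps the
  background noise clear of the zero clip (at 8 bit and SNR 5 roughly a
  third of background voxels would clip to 0, creating an artifactual
  histogram mode that defeats every global threshold).

Ground truth (masks, per-soma volumes, contact percentages) is stored with
the stack and is recomputable from the masks by exactly the definitions
the pipelines use — a self-consistency that the tests assert.

**What the generator does not emulate:** PSF-accurate optics (structures
are hard-edged before noise), Poisson photon statistics (noise is
Gaussian and stationary), motion/breathing artefacts, photobleaching,
vessel calibre variation, and truly ramified glial morphology. Passing the
recovery suites therefore demonstrates that the pipeline machinery is
unbiased under controlled geometry and noise — not that the absolute
numbers from any particular microscope are accurate.

### Validation conditions

The parameter-recovery suites run on 128 × 256 × 256-voxel stacks at the
two-photon calibration, ten stacks per suite:

* soma volumetry: 8 somata per stack in the 200–1100 µm³ regime, SNR 8 —
  representative of the photon-rich soma interiors of EGFP/ECFP reporters;
  at SNR 5 the stationary-Gaussian noise model places ~0.4 % pepper holes
  inside somata, which the 253-voxel opening element amplifies into
  artefactual erosion that real images do not show. Tolerance: mean soma
  volume within ±10 % of truth.
* contact ratio: coverages 0.05–0.30, SNR 5, crosstalk 0.3. Tolerance:
  ±20 % relative of mask truth. The residual bias is a systematic slight
  under-estimate (the detected endfoot sleeve is marginally shallower than
  the true inward penetration).
* AQP4 surface contact: surface fractions 0.05–0.40 at confocal SNR 15
  (immunostained sections imaged with averaging are far cleaner than
  intravital two-photon data). Tolerance: ±20 % relative.

A separate suite verifies the purpose of the crosstalk subtraction: with a
glial channel containing only 0.3 × vessel bleed plus noise, the pipeline
reports essentially zero contact with subtraction enabled and near-total
false contact without it.

## Statistics

`build_report()` reproduces the study-level workflow: per-image values are
averaged per subject; each condition is screened with Shapiro–Wilk; the
omnibus test is a repeated-measures one-way ANOVA for paired (intravital)
designs — balanced designs only, no sphericity correction by default, with
the convention that a zero between-condition sum of squares reports
F = 0, p = 1 — or an ordinary one-way ANOVA for independent (confocal)
designs; pairwise follow-ups use Tukey's HSD (paired) or Welch t tests
(independent); and condition means are summarised as percent change versus
the baseline, displayed to one decimal with full precision retained in the
tables. The type-I error of the ANOVA wrapper is verified by null
simulation (2,000 replicates, 5 % ± 2 %).

## Numerical choices and degenerate inputs

* Axis convention (z, y, x) throughout; TIFF pages map to z.
* Calibration precedence: explicit argument > OME metadata > YAML sidecar
  > error. Silent voxel defaults would corrupt every µm³ output.
* Intensities stay in native integer units; nothing is normalised at load.
* Constant channels raise a degenerate-histogram error where a threshold
  is requested directly; inside the contact/AQP4 pipelines they downgrade
  to an empty mask with a warning (an empty glial channel is a legitimate
  0 %-contact observation; an empty vessel channel is an error because the
  ratio is undefined).
* The distance transform is the exact squared-Euclidean transform with
  per-axis spacings; erosion/dilation by the anisotropic ellipsoid are
  computed through it (thresholding the scaled distance at 1), which is
  identical to sweeping the discrete structuring element, with the volume
  border treated as inside for erosion.
* Watershed flooding order is deterministic (priority by distance,
  first-in-first-out among ties), so labellings are reproducible across
  runs and platforms.
* Percent changes require a strictly positive baseline.

## Limitations

* Global thresholds assign *some* foreground to any non-constant channel:
  a channel containing pure noise will segment its upper noise tail. The
  pipelines do not attempt to detect "no signal present".
* Voxel-count surface areas underestimate true areas anisotropically;
  only relative comparisons across groups should be interpreted.
* The soma pipeline assumes the bright somata dominate the glial channel
  after opening; heavy vessel bleed-through is handled by the contact
  pipeline's subtraction but is outside the soma pipeline's contract.
* RM-ANOVA assumes sphericity by default, matching the standard workflow;
  a Greenhouse–Geisser correction is available
  (`anova_oneway(..., sphericity = "greenhouse-geisser")`) but changes the
  degrees of freedom and hence the downstream Tukey comparisons.
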