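---
title: "Myofiber typing from immunofluorescence sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myofiber typing from immunofluorescence sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Skeletal muscle is a mosaic of myofibers whose contractile behaviour is set
by the myosin heavy chain (MyHC) isoform they express: slow type 1, fast
type 2A, and the fastest isoform (2X in human, 2B in mouse), with hybrid
fibers co-expressing two isoforms. Muscle phenotyping therefore asks, for
each biopsy section: how many fibers of each type are present, and how big
are they?

`myotyper` implements a semi-automated analysis of whole-section,
four-channel immunofluorescence images (MyHC1, MyHC2A, MyHC2X/2B, laminin)
that answers this at scale:

1. **Preprocess** — block-average downsampling to a 1–5 µm/px working
   resolution and retrospective shading correction.
2. **Tissue mask** — automatic mask from the laminin channel plus scripted
   polygon edits to exclude folds and artifacts.
3. **Boundary classification** — a trainable random-forest pixel classifier
   turns the masked laminin image into a myofiber-boundary probability map.
4. **Segmentation** — a seeded watershed converts the probability map into
   one region of interest (ROI) per fiber.
5. **Measurement** — per ROI and channel: area, intensity statistics,
   circularity, boundary-strip statistics, distance to the tissue edge.
6. **Quality filters** — three percentile filters remove non-fiber ROIs.
7. **Typing** — mean-shift clustering of the three MyHC intensities,
   cluster pruning and naming, and per-sample composition tables.

Every stage is exercised end to end on synthetic phantoms with per-fiber
ground truth, generated by the package itself.

## The phantom generator

`generate_phantom()` emulates the geometry and staining of a real section,
not its biology:

- **Geometry.** Fibers are the cells of a Voronoi tessellation of random
  seeds inside an elliptical tissue region, relaxed by two Lloyd iterations
  so cells become quasi-hexagonal, as fiber cross-sections are. Optional
  elongated fibers (aspect ≥ 4, grown from line-segment seeds) emulate
  longitudinally cut fibers and exercise the circularity filter.
- **Staining.** Inter-fiber boundaries carry bright laminin over a
  configurable width (default 3 px ≈ 8 µm at the default 2.6 µm/px); fiber
  interiors carry per-fiber mean intensities drawn from type-specific
  log-normal distributions. The defaults put expressed isoforms at a mean
  of 2500 (16-bit scale, log-sd 0.25) and non-expressed ones at 150
  (log-sd 0.35), matching the order of magnitude of the worked-example
  measurement record; hybrids get the 0.5/0.5 convex mixture of the 2A and
  2X means. Gaussian pixel noise (sd 80) is added everywhere.
- **Composition.** Default type proportions are 45/35/15/5%
  (type1/2A/2X/hybrid), a realistic human leg-muscle mixture. The default
  section holds 400 fibers of mean cross-sectional area ≈ 2800 µm² in a
  512×512 px image.
- **Artifacts.** Dirt blobs are bright laminin discs placed off-tissue (at
  least 12 px clear of the border, so each forms its own small object);
  a fold is a quadrilateral where all channels are brightened. `degrade()`
  multiplies every channel by an analytic cosine shading field
  (`1 + a·cos(2πr/H)·cos(2πc/W)`) and adds noise; the applied field is
  returned for oracle use.

What the phantom does **not** model: point-spread functions, spectral
bleed-through, chromatic shifts, staining gradients within fibers, or real
tissue pathology. Passing the phantom suites therefore demonstrates that
the algorithms are implemented correctly and recover known truth under
realistic geometry, intensity and noise — not that any particular real
dataset will segment perfectly. On real data the classifier should be
retrained with sparse annotations and the filter thresholds inspected with
the density plots, as the protocol prescribes.

## Shading correction

Slide scanners leave a smooth multiplicative intensity field across the
section. The profile estimator isolates it by heavy Gaussian smoothing
(default σ = min(H, W)/8 px — shading is low-frequency relative to
fibers), with two refinements:

- the smoothing is **intensity-weighted** (`blur(x²)/blur(x)`, a normalised
  convolution), so dark off-tissue background does not drag the profile
  down near the tissue border — a plain blur of a masked section mostly
  estimates the tissue outline, not the shading;
- the estimate is **refined once** on the corrected image, recovering the
  fraction of the field modulation the blur attenuates.

On a flat image the profile is exactly 1; on a flat image times a known
cosine field it correlates with the field at r > 0.99. Profiles from
several slides are combined per pixel by `median_shading_profile()` and
normalised to mean 1; correction is division, clipped to the 16-bit range.

Because a stained section has genuine low-frequency structure (the density
of bright laminin boundaries varies across tiles), the benchmark for the
corrector is the *shading component*: tile means of the degraded and
corrected phantom relative to the clean phantom. The estimator removes
over 70% of that component's coefficient of variation at amplitude 0.3
(the tests require ≥ 50%); measured on raw tile means the reduction is
bounded by the tissue's intrinsic tile variability and would understate
the correction.

## Tissue mask and masked laminin

The automatic mask blurs the laminin channel (σ = 10 px), applies an Otsu
threshold, fills holes, drops objects under 2000 px², and keeps components
at least 10% of the largest. Laminin is used because it outlines all
fibers regardless of type. Interactive correction is replaced by an
ordered script of polygon edits (`add` / `remove`), rasterised with the
even-odd rule and pixel-center inclusion under half-open coverage — an
unambiguous, testable convention that makes each edit idempotent.

The classifier input is the *feathered* masked laminin image: with
`m = blur(mask, σ = 4)`, the output is
`m·laminin + (1−m)·median(laminin outside the mask)`. Deep inside tissue
(beyond the blur support) the image is untouched; far outside it sits
exactly at the outside median, so the mask edge cannot imprint a spurious
boundary. The per-fiber distance to the tissue edge is the exact Euclidean
distance transform of the mask (image frame counted as background), in µm.

## Boundary classification and segmentation

The pixel classifier mirrors the interactive tools used in such protocols:
8 features per smoothing scale (Gaussian, Laplacian of Gaussian, gradient
magnitude, difference of Gaussians, both structure-tensor and both Hessian
eigenvalues) at σ ∈ {0.7, 1.0, 1.6, 3.5, 5.0} px — chosen to span laminin
boundary widths at 2.6 µm/px — feeding a probability random forest (100
trees, depth ≤ 12, fixed seed, single-threaded, hence deterministic).
Training needs only sparse 'boundary' / 'not boundary' pixel annotations,
on one or several sections; externally produced probability maps (8-bit or
float TIFF) can be substituted at any point.

Segmentation thresholds the smoothed probability at 0.5 to obtain the
boundary ridge, takes 4-connected components of tissue-minus-ridge (area
≥ 9 px²) as seeds, and grows them by an intensity-guided propagation on
the smoothed probability restricted to tissue — a seeded watershed that
closes small laminin gaps which would otherwise merge neighbours. Ridge
pixels remain unassigned: fiber interiors exclude the laminin line, which
is exactly what makes the classification-channel certainty metrics
discriminative (high on the 3-px boundary strip, low inside). On default
phantoms ≥ 97% of truth fibers are recovered one-to-one at IoU ≥ 0.7.

## Measurement

The classification channel (`round(255·p)`) is appended as channel 5, so
segmentation certainty lives in the same table as the intensities. Each
(ROI, channel) record carries: area (pixel count × pixel size², µm²),
interior mean/sd/mode/min/max/median, circularity, boundary-strip mean/sd,
and mean distance to the tissue edge. The strip is the exact Euclidean
dilation by a 3-px disk minus the ROI. Circularity is 4πA/P² capped at 1,
with the perimeter from corner-corrected chain-code tracing of the outer
contour (Kulpa weights 0.948/1.340): a rasterised disk scores ≈ 1 while a
40×4 px rectangle scores ≈ 0.32. The mode is taken over the 16-bit integer
histogram with ties resolved to the smallest value; mean distance is
averaged over interior pixels (not the centroid), matching the column's
meaning as the object's mean distance to the edge.

## Quality filtering

Three percentile filters (type-7 linear interpolation, the convention of
the statistical environment such analyses run in) remove non-fiber ROIs:

| filter      | metric(s)                         | default band |
|-------------|-----------------------------------|--------------|
| certainty   | channel-5 Mean and Mean_boundary  | (5, 95) both |
| CSA         | area, optionally per sample group | (10, 99)     |
| circularity | Circ.                             | > 1st pct    |

All cuts are computed on the **full pooled ROI set** — including ROIs
already failed by another filter — so the flags are independent of
evaluation order. Comparisons are strict at both cuts; in the degenerate
all-ties case nothing is excluded. `StdDev_boundary` is available but
inactive by default, as filtering on the other two metrics already cleans
it up. Thresholds are configuration, not automation: they should be tuned
per dataset by density-plot inspection. The aggregate code (0 / 0.4 / 0.7 /
1) encodes which filter excluded each ROI for the overlay renderer, and a
sample is retained only if its best section keeps ≥ 100 fibers.

## Typing

Per sample, each isoform column of the n×3 MFI matrix is divided by its
uncentered root mean square `sqrt(mean(x²))` — scaling without centering,
so zero stays zero and staining strength cancels across samples — then
log-transformed with a small positive floor (default 1e-4) for zero
safety, pooled, and clustered by Gaussian-kernel mean shift. Pooling after
per-sample scaling is deliberate: compositions are compared across samples
afterwards, which requires shared cluster definitions.

Mean shift moves every point uphill on the kernel density estimate until
the step falls below `1e-6 ×` the data diameter (max 500 iterations);
converged positions within h/2 merge into one mode. Coordinates are
divided by their ranges first (the convention of the clustering
implementation used in the original analyses), which is what makes the
suggested bandwidth window h ∈ [0.01, 0.05] meaningful across datasets;
absolute bandwidths are available via `scale_range = FALSE`. Clusters
below 2% of fibers are pruned to label 0 and excluded from composition
denominators. Between 3 and 8 retained clusters is flagged as the
biologically expected range (warning outside, never an error).

Clusters are named by their dominant isoform mean; a top-two gap under 0.2
log units names a hybrid, and a cluster whose three means all sit below the
10th percentile of the pooled transformed values is tagged `low-MyHC`.
Both margins are configuration with no canonical published value. On
three-type phantoms (n = 1500) some h in the window yields exactly 3
clusters with adjusted Rand index ≈ 1 against truth and composition
recovered within ±0.02 of the nominal 0.6/0.3/0.1 mixture.

## Numerical conventions and degenerate inputs

- 16-bit rasters round-trip bit-for-bit through TIFF; pixel size and
  channel roles travel in a JSON sidecar, and explicit arguments beat the
  sidecar. A missing pixel size is an error, never a silent default.
- Downsampling averages trailing partial blocks over available pixels,
  preserving tissue at the frame.
- An all-zero channel cannot yield a shading profile; profiles are floored
  at 0.05 before division.
- Blank images raise "no tissue found"; an empty measurement table writes a
  header-only file; a section group with one ROI passes the CSA filter
  trivially with a warning.
- All randomness (phantoms, annotation sampling, forest training) is
  seed-parameterised; reruns are bit-identical.

## Problem sizes used by the test and acceptance suites

The suites run phantoms of 250 fibers at 384×384 px for the imaging chain
and 1500 fibers (truth-level intensities) for typing, with one 500-fiber
512×512 px end-to-end run — sizes chosen so the whole suite completes in a
few minutes on one CPU while every stage still sees several hundred
objects.

## Known limitations

- The shading estimator is validated only on phantoms with the analytic
  cosine field; real scanner shading with sharp tile seams may need the
  acquisition software's own reference-based correction.
- The segmentation is contract-compatible with, but not numerically
  identical to, the interactive-macro pipelines it replaces; it is
  validated against phantom truth, not against any particular macro output.
- Hybrid-fiber detection depends on the hybrid margin and bandwidth; very
  small hybrid populations (< 2%) are pruned by design.
- Statistical comparison of compositions between groups is out of scope;
  the composition table is the hand-off point.
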