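---
title: "Feature-based stitching of multi-segment spine MR images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based stitching of multi-segment spine MR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinestitch)
```

## The problem

Whole-spine MR examinations acquire the cervical, thoracic and lumbar
regions as separate sagittal (or coronal) fields of view, each a stack of
co-registered slices, with a band of anatomy shared between neighboring
segments. Composing those segments into one whole-spine image is a 2-D
registration problem constrained to be driven by pixel content alone: the
shared anatomy in the overlap is the only information used, which makes the
method independent of scanner coordinate metadata and applicable to
exported image files.

`spinestitch` solves it with the Scale Invariant Feature Transform (SIFT):
local features are detected in each segment, described by
gradient-orientation histograms, matched across segments by descriptor
distance, and the surviving correspondences vote for the inter-segment
transform. The package also provides the manual alternative (mPTP):
user-clicked point pairs replace the automatic matches, with everything
downstream identical.

## Model and processing stages

### Scale space and DoG

The image (min–max normalized to $[0,1]$) is convolved with Gaussians on
the ladder $\sigma_{o,i} = \sigma_0 k^i 2^o$, $k = 2^{1/s}$. Defaults are
$\sigma_0 = 1.6$, $s = 3$ scales per octave, an assumed input blur of 0.5
px, and as many octaves as keep the coarsest level at least 16 px on a
side. These values are the standard choices for this detector family; the
stitching approach itself does not prescribe them, so they are exposed in
`scale_space_config()`. Blurs are applied incrementally
($\sigma_\text{inc} = \sqrt{\sigma_\text{target}^2 -
\sigma_\text{current}^2}$), each octave is seeded by downsampling the level
with doubled blur, and adjacent levels are subtracted to form the
difference-of-Gaussians (DoG) pyramid.

Numerical choices: convolution kernels are truncated at $5\sigma$ and
renormalized — truncation mass below $10^{-6}$, so the Gaussian semigroup
property holds to $10^{-6}$ per pixel, which the test suite asserts;
boundaries use half-sample symmetric reflection, which preserves both
constants and the image mean exactly. The input is not upsampled 2×
before the first octave: spine matrices (420–576 px per side) carry enough
resolution that sub-pixel localization alone reaches the accuracy the
stitching stage needs.

### Keypoint detection

Discrete DoG samples that are strictly larger or strictly smaller than all
26 neighbors (8 in-plane, 9 in each adjacent scale) become candidates.
Strictness matters: with non-strict comparison, flat regions would tie and
flood the candidate list, so ties are rejected and constant images yield no
keypoints. Each candidate is refined by the second-order Taylor expansion
of the DoG in $(x, y, \sigma)$; when a refined offset component exceeds 0.5
the fit is re-centered on the nearest sample (up to 5 iterations — the
one-shot solve is only valid inside one sample cell). A candidate is kept
if the interpolated extremum value satisfies $|D(\hat{X})| \ge 0.03$ (the
contrast filter is applied to the interpolated value, not the raw sample:
the refined value is what the quadratic model says the extremum actually
is) and if the spatial-Hessian curvature ratio satisfies
$\mathrm{Tr}(H)^2/\mathrm{Det}(H) \le (\gamma+1)^2/\gamma$ with
$\gamma = 10$, rejecting edge-straddling points whose position along the
edge is unstable. The determinant is the true $D_{xx}D_{yy} - D_{xy}^2$;
the eigenvalue identities behind the ratio test only hold for that form.

### Orientation and descriptor

Gradients on the Gaussian level nearest the keypoint scale use full
central differences ($L(x{+}1,y)-L(x{-}1,y)$, no halving) and the
two-argument arctangent mapped to $[0, 2\pi)$ — a one-argument arctangent
would fold opposite gradient directions together. A 36-bin orientation
histogram is accumulated over a window of radius $3 \times 1.5\sigma$
(we read the "3 σ window" of the method's description as three times the
1.5 σ weighting scale, and document that reading), each sample weighted by
its magnitude times a Gaussian of $1.5\sigma$. The highest peak and every
local peak at $\ge 80\%$ of it emit one oriented keypoint each; peak
positions are refined by parabolic interpolation because 10° bins are too
coarse for sub-pixel stitching.

The descriptor samples a 16×16 grid spaced by the keypoint scale, rotated
to the keypoint orientation, and distributes Gaussian-weighted gradient
magnitudes trilinearly into 4×4 spatial cells × 8 orientation bins = 128
values, which are normalized to unit length, clipped at 0.2 and
renormalized (gradients cancel additive intensity changes; the two
normalizations cancel multiplicative ones and tame single-edge bursts).
One deliberate deviation: the descriptor's Gaussian weighting uses half
the window width ($8\sigma$), not $1.5\sigma$. With a literal $1.5\sigma$
weight the outer 12 of the 16 spatial histograms receive essentially zero
mass — the descriptor collapses to its central cells — and measured match
inlier rates on phantom splits drop below 50 %, which defeats the median
transform estimator. Half the window width is the reference choice for
this descriptor layout and restores the intended use of all 16 cells.

### Matching and transform estimation

Descriptors are matched by Euclidean distance with exact all-pairs search
(ties broken toward the lower index for determinism). Raw
nearest-neighbor matching mismatches freely on repetitive anatomy —
vertebrae resemble one another — so two standard filters are on by
default and can be disabled to reproduce bare nearest-distance matching:
Lowe's ratio test (nearest/second-nearest $\le 0.8$) and mutual
nearest-neighbor consistency. The translation between segments is the
component-wise median of the matched displacement vectors, exact for
consistent pairs and robust to just under half the matches being wrong; a
least-squares similarity fit (rotation + isotropic scale, SVD/Procrustes)
is available via `model = "similarity"` for gantry-angle or
field-of-view-scale differences. Spine segments acquired on one scanner
differ essentially by table translation, hence translation is the
default.

### Compositing and the central-slice rule

`stitch_pair()` renders both images onto the bounding-box canvas with
bilinear resampling (exact at integer offsets). Overlap pixels are
feather-blended — each source weighted by its distance to its own segment
edge, weights normalized to sum to one — which suppresses visible seams
from residual intensity differences between segments (e.g. coil
sensitivity); `average` and `overwrite` modes exist for comparison. When
the reference image is itself a growing mosaic, its coverage mask is
threaded through so canvas padding never blends into, or masquerades as,
image data. Segments are stitched sequentially (C+T, then (C-T)+L), and
for multi-slice stacks the transform estimated on the central slice —
index $\lfloor (N-1)/2 \rfloor$ 0-based, i.e. the lower middle for even
$N$, a deterministic reading of "the most central slice" — is applied
unchanged to every slice. Coordinates are 1-based with $x$ the column and
$y$ the row, matching R matrix indexing.

### Agreement evaluation

`nmse()` uses $\sum(\text{ref}-\text{test})^2 / \sum \text{ref}^2$ — the
most common normalization; since the metric's name alone does not pin the
denominator, the choice is stated here and in the function documentation.
`pearson_agreement()` returns the product-moment $r$, its two-sided
p-value and $R^2$ (the squared correlation of the paired observations).
`bland_altman()` uses test − reference differences, the sample SD
($n-1$), limits at mean ± 1.96 SD, and reports the fraction of
differences outside the limits. Comparisons should be restricted to the
intersection of valid-data masks (the `coverage` field of stitch results):
background padding agrees trivially and would inflate every statistic.

## The synthetic phantom: what it emulates and what it does not

`make_phantom()` draws a sagittal-spine-like scene: bright vertebral
bodies separated by darker discs along a sinusoidally curved column, a
cord band, and soft tissue. Three design points make it a fair stand-in
for feature-based registration:

- **Craniocaudal size gradient** (vertebral blocks grow 0.65→1.35 of the
  mean height) and **per-vertebra marrow-signal variation** (±12 %
  uniform), as in real spines. A strictly periodic phantom of identical
  vertebrae makes descriptor matching ill-posed — every level's
  descriptor has a near-twin one vertebra over — which no real spine
  exhibits.
- **A smooth two-scale soft-tissue field** (unit-variance Gaussian random
  fields blurred at σ = 2 and 6 px, combined at amplitude 0.18 over a
  0.30 baseline): real FSE images show mid-gray, textured soft tissue
  everywhere, and that texture is what gives the overlap band enough
  distinctive features to match. Fine per-pixel jitter (SD 0.02) adds
  high-frequency texture.
- **Known ground truth**: `split_overlapping()` cuts head-to-foot bands
  with an exact shared-row overlap (default 56 px of a 700-px phantom,
  roughly the overlap fraction of clinical protocols), optional integer
  lateral jitter, per-segment gain, and seeded per-pixel Gaussian noise
  applied after cutting — so the true transforms stay known to machine
  precision, and reassembly at unit gain / zero noise reproduces the
  phantom exactly.

What the phantom does **not** emulate: MR physics (relaxation-weighted
contrast, bias fields, ghosting, motion), anatomy in the third dimension,
and deformable misalignment between acquisitions. Passing tests therefore
demonstrate the pipeline's geometric and statistical correctness under
realistic texture and noise, not clinical robustness on patient data.

All generators are pure functions of their configs and seeds (`with_seed()`
scopes the RNG and restores session state), so every experiment in the
tests and the acceptance script is bit-reproducible.

## Test problem sizes

The suites run the full pipeline on the default 700×256 phantom: ten
seeded noisy splits (overlap 56 px, noise SD 0.01) plus one noise-free
split for the end-to-end recovery checks, eight seeded splits at the
harder setting (overlap 40 px, noise SD 0.02, lateral jitter ±3 px) for
the robustness property, and 64×64 pyramids for the exhaustive
brute-force extrema comparison. These sizes keep the complete suite at a
few minutes on one CPU while exercising every code path at full default
resolution.

## Known limitations

- No outlier-consensus step (e.g. RANSAC) beyond the ratio/mutual filters
  and the median estimator; with fewer than ~50 % correct matches the
  translation vote can fail. Severely featureless overlaps (uniform
  tissue) reduce the usable match count.
- No inter-segment intensity gain correction: segments are assumed on one
  normalized scale; feathering hides moderate gain steps but does not
  remove them from quantitative readings.
- Rigid (translation/similarity) models only; no deformable registration.
- DICOM files are not read directly (no DICOM reader is available in
  plain R without additional system dependencies); convert series to
  PNG/TIFF first. Slice order then follows lexicographic filenames.
- 2-D only: slices are stitched independently with a shared transform;
  no volumetric feature detection.
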