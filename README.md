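# spinestitch

SIFT-based stitching of multi-segment spine MR images in R.

Whole-spine MRI cannot usually be acquired in a single field of view: the
cervical, thoracic and lumbar (C-T-L) regions are scanned as separate,
partially overlapping segments. Radiologists reading the whole column need
those segments composed into one image. `spinestitch` implements that
composition from pixel features alone — no scanner geometry metadata — using
the Scale Invariant Feature Transform (SIFT), and quantifies how well a
stitched result agrees with a reference image.

The package is aimed at medical-image-analysis researchers who want a
self-contained, fully testable reference implementation: every stage from
scale-space construction to Bland–Altman agreement plots is exposed as an R
function, and a synthetic spine-phantom generator provides inputs with known
ground truth so the whole pipeline can be validated without scanner data.

## Method

For an image `I(x, y)` with intensities normalized to [0, 1]:

1. **Scale space.** `L(x, y, σ) = G(x, y, σ) * I(x, y)` with Gaussian
   kernels `G` on a scale ladder `σ_o,i = σ0 · k^i · 2^o`, `k = 2^(1/s)`
   (defaults `σ0 = 1.6`, `s = 3`). Difference-of-Gaussians levels
   `D(x, y, σ) = L(x, y, kσ) − L(x, y, σ)` approximate the
   scale-normalized Laplacian.
2. **Keypoints.** Discrete extrema of `D` over their 26 scale-space
   neighbors are refined by a second-order Taylor expansion
   (`X̂ = −(∂²D/∂X²)⁻¹ ∂D/∂X`); candidates with interpolated `|D(X̂)| <
   0.03` are discarded as low contrast, and edge-like points are rejected
   when `Tr(H)²/Det(H) > (γ+1)²/γ` for the 2-D spatial Hessian `H`
   (default `γ = 10`).
3. **Orientation and descriptor.** Gradient magnitude
   `m = √(ΔLx² + ΔLy²)` and orientation `θ = atan2(ΔLy, ΔLx)` feed a
   36-bin histogram over a Gaussian-weighted window (1.5 σ); the highest
   peak and any local peak within 80 % of it define keypoint orientations.
   Each oriented keypoint gets a 4×4 grid of 8-bin orientation histograms —
   a 128-element descriptor, normalized, clipped at 0.2, renormalized.
4. **Matching and stitching.** Descriptors are matched by Euclidean
   distance (ratio test 0.8 + mutual-nearest filter). The inter-segment
   translation is the component-wise median of matched displacement
   vectors (a least-squares similarity fit is available). Segments are
   composed sequentially — C+T, then (C-T)+L — with feather blending; for
   multi-slice stacks the transform estimated on the central slice is
   applied to every slice.
5. **Evaluation.** Normalized mean square error
   `Σ(ref − test)²/Σ ref²`, Pearson r with R², and Bland–Altman mean
   difference ± 1.96 SD limits of agreement.

Point correspondences can come from SIFT (aPTP, automated point-to-point)
or from user-supplied pairs (mPTP, manual), mirroring the two modes a
clinical operator would use.

## Worked example

```r
library(spinestitch)

phantom <- make_phantom(phantom_config(seed = 42))        # 700 x 256 spine
ss <- split_overlapping(phantom, n_segments = 3,
                        overlap_px = 56, noise_sd = 0.01, seed = 42)
res <- stitch_sequence(ss$segments, mode = "aptp")
recovered_offsets(res)
#>             dx       dy
#> 1 -0.005959405 214.9792
#> 2  0.015933805 213.9804
ss$true_offsets[, c("dx", "dy")]                          # truth: (0, 215), (0, 214)
```

The automated mode recovered both inter-segment translations to within
0.02 px of the ground truth. Agreement between the aPTP canvas and the
reference stitch built from the exact transforms:

```r
t1 <- res$segment_transforms[[1]]
gt <- stitch_with_true_offsets(ss)
rows <- seq_len(nrow(gt$canvas)) + round(t1$dy)
cols <- seq_len(ncol(gt$canvas)) + round(t1$dx)
agreement_report(gt$canvas, res$slices[[1]]$canvas[rows, cols],
                 mask = res$slices[[1]]$coverage[rows, cols])
#> Agreement (n = 178571):
#>   NMSE      1.711e-05  (sum sq. error / sum sq. reference)
#>   Pearson r 1.0000  (p = 0), R^2 = 0.9999
#>   Bland-Altman -1.24e-06 +/- 0.001888, limits (-0.003702, 0.003699)
```

NMSE of order 1e-5 and r ≈ 1 mean the feature-driven stitch is essentially
indistinguishable from the exact-transform reference; the Bland–Altman
limits span ±0.004 intensity units on a [0, 1] scale.

## Command line

A thin Rscript front end exposes the pipeline as subcommands:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/spinestitch", package = "spinestitch"))')
Rscript $CLI simulate --out sim/ --seed 7 --segments 3 --overlap 56 --noise 0.01
Rscript $CLI stitch sim/segment_1 sim/segment_2 sim/segment_3 --out stitched/
Rscript $CLI evaluate ref/ test/ --report report.json --plots plots/
```

`detect` and `match` subcommands export keypoints and matches as JSON;
`--config file.yaml` merges a YAML config under the command-line flags, and
the effective configuration is echoed next to each output.

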