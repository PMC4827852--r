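Package: spinestitch
Title: SIFT-Based Stitching of Multi-Segment Spine MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Composes cervical, thoracic and lumbar spine magnetic resonance
    image segments into a single whole-spine view. Implements the Scale
    Invariant Feature Transform (SIFT) end to end -- Gaussian scale space,
    difference-of-Gaussians extrema, sub-pixel keypoint localization with
    contrast and edge-response filtering, gradient-orientation assignment,
    128-element descriptors and Euclidean-distance matching -- and uses the
    matched correspondences to estimate inter-segment transforms, either
    automatically (aPTP) or from user-supplied point pairs (mPTP). Segments
    are stitched sequentially with feather blending, and for multi-slice
    stacks the transform estimated on the central slice is propagated to all
    slices. Agreement between a reference and a test stitched image is
    quantified by normalized mean square error, Pearson correlation,
    coefficient of determination and Bland-Altman limits of agreement. A
    seeded synthetic spine phantom generator provides segment sets with known
    ground-truth offsets so the whole pipeline is testable without scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    jpeg,
    tiff,
    stats,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
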