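test_that("translation estimation is exact on consistent pairs and robust", {
  mk_pairs <- function(n, dx, dy) {
    a <- data.frame(x = runif(n, 10, 100), y = runif(n, 10, 100))
    point_pair_set(a, data.frame(x = a$x - dx, y = a$y - dy),
                   source = "automatic")
  }
  set.seed(21)
  t1 <- estimate_transform(mk_pairs(7, 5, 120))
  expect_equal(c(t1$dx, t1$dy), c(5, 120))
  # one pair suffices for the translation model
  t2 <- estimate_transform(point_pair_set(data.frame(x = 10, y = 200),
                                          data.frame(x = 7, y = 90)))
  expect_equal(c(t2$dx, t2$dy), c(3, 110))
  # median shrugs off one gross outlier among 9 consistent pairs
  p <- mk_pairs(9, 0, 100)
  p$points_b$x[5] <- p$points_a$x[5] - 50
  p$points_b$y[5] <- p$points_a$y[5] + 30
  t3 <- estimate_transform(p)
  expect_equal(c(t3$dx, t3$dy), c(0, 100))
})

test_that("similarity estimation recovers a known rotation and scale", {
  set.seed(22)
  b <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100))
  rot <- 8 * pi / 180; s <- 1.03; dx <- 12.5; dy <- -40
  a <- data.frame(x = s * (cos(rot) * b$x - sin(rot) * b$y) + dx,
                  y = s * (sin(rot) * b$x + cos(rot) * b$y) + dy)
  tr <- estimate_transform(point_pair_set(a, b), model = "similarity")
  expect_equal(tr$rotation, rot, tolerance = 1e-6)
  expect_equal(tr$scale, s, tolerance = 1e-6)
  expect_equal(c(tr$dx, tr$dy), c(dx, dy), tolerance = 1e-6)
  expect_lt(max(attr(tr, "residuals")), 1e-9)
  expect_error(estimate_transform(point_pair_set(a[1, ], b[1, ]),
                                  model = "similarity"), "at least 2")
})

test_that("transforms compose and invert consistently", {
  t1 <- spine_transform(dx = 3, dy = -7, rotation = 0.1, scale = 1.02,
                        model = "similarity")
  p <- apply_spine_transform(t1, c(5, 80), c(12, -3))
  back <- apply_spine_transform(invert_spine_transform(t1), p$x, p$y)
  expect_equal(back$x, c(5, 80), tolerance = 1e-12)
  expect_equal(back$y, c(12, -3), tolerance = 1e-12)
})

test_that("stitching two halves of one image reproduces it", {
  ph <- make_phantom(phantom_config(height = 256, width = 128,
                                    n_vertebrae = 5))
  a <- ph[1:156, ]                 # rows 1..156
  b <- ph[101:256, ]               # rows 101..256; 56-row overlap
  tr <- spine_transform(dx = 0, dy = 100)
  for (blend in c("feather", "average", "overwrite")) {
    res <- stitch_pair(a, b, tr, blend = blend)
    expect_equal(dim(res$canvas), dim(ph))
    expect_lt(nmse(ph, res$canvas), 1e-6)
  }
  # identical images, zero translation: canvas equals the input exactly
  for (blend in c("feather", "average", "overwrite")) {
    res0 <- stitch_pair(a, a, spine_transform(0, 0), blend = blend)
    expect_equal(res0$canvas, a, tolerance = 1e-12)
    expect_true(all(res0$overlap_mask))
  }
  # overlap mask marks exactly the doubly covered band
  res <- stitch_pair(a, b, tr)
  expect_equal(which(apply(res$overlap_mask, 1, any)), 101:156)
  # feather weights sum to one wherever data exists
  w <- res$weights$a + res$weights$b
  expect_lt(max(abs(w[res$coverage] - 1)), 1e-9)
  # a transform pushing b away leaves untouched corners at background 0
  far <- stitch_pair(a, b, spine_transform(dx = 120, dy = 200))
  expect_equal(far$canvas[nrow(far$canvas), 1], 0)
  expect_false(far$coverage[nrow(far$canvas), 1])
  expect_error(stitch_pair(a, b, spine_transform(NaN, 0)), "finite|NaN")
})

test_that("aPTP and mPTP stitch a split phantom to the same canvas", {
  ph <- make_phantom(phantom_config())
  ss <- split_overlapping(ph, n_segments = 2, overlap_px = 56,
                          noise_sd = 0.01, seed = 5)
  a <- ss$segments[[1]]$planes[[1]]
  b <- ss$segments[[2]]$planes[[1]]
  mm <- match_images(a, b)
  res_a <- stitch_sequence(ss$segments, mode = "aptp")
  res_m <- stitch_sequence(ss$segments, mode = "mptp",
                           pairs_list = list(mm$pairs))
  # same correspondences -> pixel-identical canvas
  expect_identical(res_a$slices[[1]]$canvas, res_m$slices[[1]]$canvas)
  off <- recovered_offsets(res_a)
  expect_lt(max(abs(off$dy - ss$true_offsets$dy)), 0.5)
  expect_lt(max(abs(off$dx - ss$true_offsets$dx)), 0.5)
})

test_that("three-segment sequential stitch recovers the phantom", {
  ph <- make_phantom(phantom_config())
  ss <- split_overlapping(ph, overlap_px = 56, noise_sd = 0.01, seed = 2)
  res <- stitch_sequence(ss$segments, mode = "aptp")
  expect_length(res$segment_transforms, 3L)
  expect_lt(sequence_canvas_nmse(res, ph), 1e-3)
  # single segment passes through unchanged
  res1 <- stitch_sequence(ss$segments[1])
  expect_identical(res1$slices[[1]]$canvas, ss$segments[[1]]$planes[[1]])
  # mPTP without pairs is a usage error; mismatched slice counts error
  expect_error(stitch_sequence(ss$segments, mode = "mptp"), "point-pair")
  bad <- ss$segments
  bad[[2]] <- slice_stack(rep(bad[[2]]$planes, 2))
  expect_error(stitch_sequence(bad), "slice counts")
})

test_that("the central-slice transform propagates to every slice", {
  expect_equal(central_slice_index(6), 3L)  # lower middle of an even stack
  expect_equal(central_slice_index(5), 3L)
  expect_equal(central_slice_index(1), 1L)

  cfg <- phantom_config(height = 256, width = 128, n_vertebrae = 5)
  st <- make_phantom(cfg, n_slices = 6, slice_jitter_sd = 0.01)
  a <- slice_stack(lapply(st$planes, function(p) p[1:156, ]))
  b <- slice_stack(lapply(st$planes, function(p) p[101:256, ]))
  tr <- spine_transform(dx = 0, dy = 100)
  out <- propagate_to_slices(a, b, tr)
  expect_length(out, 6L)
  for (s in seq_len(6))
    expect_lt(nmse(st$planes[[s]], out[[s]]$canvas), 1e-6)
  # identical slices give identical per-slice results
  a2 <- slice_stack(rep(a$planes[3], 4))
  b2 <- slice_stack(rep(b$planes[3], 4))
  out2 <- propagate_to_slices(a2, b2, tr)
  expect_identical(out2[[1]]$canvas, out2[[4]]$canvas)
  expect_error(propagate_to_slices(a, slice_stack(b$planes[1:3]), tr),
               "unequal")
})

test_that("aPTP recovers random split offsets within half a pixel", {
  ph <- make_phantom(phantom_config())
  for (seed in 1:8) {
    ss <- split_overlapping(ph, overlap_px = 40, jitter_px = 3,
                            noise_sd = 0.02, seed = seed)
    res <- stitch_sequence(ss$segments, mode = "aptp")
    err <- abs(as.matrix(recovered_offsets(res)) -
                 as.matrix(ss$true_offsets[, c("dx", "dy")]))
    expect_lt(max(err), 0.5)
  }
})
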