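# Binarization, labelling, transform, peaks, features, splitting.

test_that("fraction-of-max binarization matches its worked examples", {
  px <- matrix(0, 8, 8)
  px[3, 4] <- 10000; px[5, 6] <- 49.9; px[2, 2] <- 50
  img <- toy_image(px)
  mask <- binarize(img, threshold_fraction = 0.005)   # cutoff = 50.0
  expect_true(mask[3, 4]); expect_true(mask[2, 2])
  expect_false(mask[5, 6])
  # pixel-by-pixel oracle
  expect_identical(mask, px >= 0.005 * max(px))
  # all-zero image -> empty mask, not everything
  expect_false(any(binarize(toy_image(matrix(0, 8, 8)))))
})

test_that("binarization is invariant to global intensity rescaling", {
  withr::with_seed(2, { px <- matrix(rexp(400, 1 / 50), 20, 20) })
  m1 <- binarize(toy_image(px), threshold_fraction = 0.05)
  m2 <- binarize(toy_image(px * 7.3), threshold_fraction = 0.05)
  expect_identical(m1, m2)
})

test_that("adaptive binarization lifts sparse spots off a flat background", {
  withr::with_seed(3, { px <- matrix(rnorm(2500, 10, 0.5), 50, 50) })
  px[10, 10] <- 40; px[30, 42] <- 35
  mask <- binarize(toy_image(pmax(px, 0)), mode = "adaptive",
                   window_px = 11)
  expect_true(mask[10, 10]); expect_true(mask[30, 42])
  expect_lt(sum(mask), 10)
})

test_that("initial segment labelling is 8-connected and area-filtered", {
  mask <- matrix(FALSE, 10, 10)
  mask[2:4, 2:4] <- TRUE           # block A, area 9
  mask[7:9, 7:9] <- TRUE           # block B, area 9
  img <- toy_image(matrix(1, 10, 10))
  segs <- label_initial_segments(mask, img, min_area_px = 4)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$area_px, c(9L, 9L))
  expect_equal(segs$diameter_nm, rep(2 * sqrt(9 * 400 / pi), 2))

  # diagonal touch merges into one segment
  diag_mask <- matrix(FALSE, 6, 6)
  diag_mask[2, 2] <- TRUE; diag_mask[3, 3] <- TRUE
  diag_mask[2, 3] <- TRUE; diag_mask[4, 4] <- TRUE
  segs2 <- label_initial_segments(diag_mask, toy_image(matrix(1, 6, 6)),
                                  min_area_px = 1)
  expect_identical(nrow(segs2), 1L)
  expect_identical(segs2$area_px, 4L)

  # min-area filter
  small <- matrix(FALSE, 6, 6); small[2, 2] <- TRUE
  expect_identical(
    nrow(label_initial_segments(small, toy_image(matrix(1, 6, 6)),
                                min_area_px = 4)), 0L)
})

test_that("labelling agrees with a flood-fill oracle on random masks", {
  for (seed in 1:3) {
    mask <- withr::with_seed(seed, matrix(runif(900) < 0.35, 30, 30))
    segs <- label_initial_segments(mask, toy_image(matrix(1, 30, 30)),
                                   min_area_px = 1)
    oracle <- flood_fill_labels(mask)
    expect_identical(nrow(segs), max(oracle))
    # identical pixel partitions up to relabelling
    ours <- sort(vapply(segs$pixels, function(p)
      paste(sort(paste(p[, 1], p[, 2])), collapse = ";"), character(1)))
    theirs <- sort(vapply(seq_len(max(oracle)), function(k) {
      idx <- which(oracle == k, arr.ind = TRUE)
      paste(sort(paste(idx[, 1], idx[, 2])), collapse = ";")
    }, character(1)))
    expect_identical(ours, theirs)
  }
})

test_that("segment boundary polygon has the segment's pixel area", {
  mask <- matrix(FALSE, 8, 8); mask[3:5, 2:6] <- TRUE
  segs <- label_initial_segments(mask, toy_image(matrix(1, 8, 8)),
                                 min_area_px = 1)
  ring <- segs$polygon[[1]]
  expect_equal(abs(evquant:::shoelace_area(ring)), 15 * 400)
})

test_that("Laplacian of the cube root matches finite-difference oracles", {
  # constant patch -> zero transform
  img <- toy_image(matrix(7, 9, 9))
  seg <- tibble(label = 1L, pixels = list(rect_pixels(1, 9, 1, 9)))
  p <- laplacian_cubicroot(img, seg[1, ])
  expect_equal(max(abs(p$values)), 0)

  # i = (x^2 + y^2 + c)^3 has cube root x^2 + y^2 + c, whose 5-point
  # Laplacian is exactly 4 at unit spacing
  g <- expand.grid(r = 1:15, c = 1:15)
  quad <- matrix(((g$r - 8)^2 + (g$c - 8)^2 + 5)^3, 15, 15)
  p2 <- laplacian_cubicroot(toy_image(quad),
                            tibble(label = 1L,
                                   pixels = list(rect_pixels(1, 15, 1, 15)))[1, ])
  expect_equal(p2$values[4:12, 4:12], matrix(4, 9, 9))

  # homogeneity: scaling intensity by 8 scales the transform by 2
  p8 <- laplacian_cubicroot(toy_image(quad * 8),
                            tibble(label = 1L,
                                   pixels = list(rect_pixels(1, 15, 1, 15)))[1, ])
  expect_equal(p8$values, 2 * p2$values)
})

test_that("peak detection resolves separated Gaussians and flat patches", {
  mk_patch <- function(centres, sigma = 3, amp = 100, n = 41) {
    px <- matrix(0, n, n)
    g <- expand.grid(r = seq_len(n), c = seq_len(n))
    for (cc in centres) {
      px <- px + matrix(amp * exp(-((g$r - cc[1])^2 + (g$c - cc[2])^2) /
                                    (2 * sigma^2)), n, n)
    }
    img <- toy_image(px)
    seg <- tibble(label = 1L, pixels = list(rect_pixels(1, n, 1, n)))
    laplacian_cubicroot(img, seg[1, ])
  }
  # single blob -> one peak at the centre pixel
  one <- detect_peaks(mk_patch(list(c(21, 21))), prominence = 0.2)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$row, one$col), c(21L, 21L))

  # two equal blobs 6 sigma apart -> two peaks at the programmed centres;
  # oracle: exhaustive local-maximum scan of the negated transform
  patch <- mk_patch(list(c(21, 12), c(21, 30)))
  two <- detect_peaks(patch, prominence = 0.2)
  expect_identical(nrow(two), 2L)
  expect_setequal(paste(two$row, two$col), c("21 12", "21 30"))
  s <- -patch$values
  scan <- which(s == max(s), arr.ind = TRUE)
  expect_true(all(paste(scan[, 1], scan[, 2]) %in% paste(two$row, two$col)))

  # flat patch -> no peaks
  flat <- laplacian_cubicroot(
    toy_image(matrix(5, 11, 11)),
    tibble(label = 1L, pixels = list(rect_pixels(1, 11, 1, 11)))[1, ])
  expect_identical(nrow(detect_peaks(flat)), 0L)
})

test_that("variation eligibility uses the foreground CV", {
  img_const <- toy_image(matrix(100, 5, 5))
  seg <- tibble(label = 1L, pixels = list(rect_pixels(1, 5, 1, 5)))
  expect_false(variation_eligible(seg[1, ], img_const, cv_cutoff = 0.2))

  # two-level checkerboard: closed-form CV = sd/mean of {a, b} pattern
  a <- 50; b <- 150
  px <- matrix(a, 6, 6); px[(row(px) + col(px)) %% 2 == 0] <- b
  seg6 <- tibble(label = 1L, pixels = list(rect_pixels(1, 6, 1, 6)))
  v <- px[seg6$pixels[[1]]]
  cv_closed <- sd(v) / mean(v)
  expect_true(variation_eligible(seg6[1, ], toy_image(px),
                                 cv_cutoff = cv_closed - 0.01))
  expect_false(variation_eligible(seg6[1, ], toy_image(px),
                                  cv_cutoff = cv_closed + 0.01))
  # zero cutoff passes any non-constant segment
  expect_true(variation_eligible(seg6[1, ], toy_image(px), cv_cutoff = 0))
})

test_that("segment features match geometric oracles", {
  # 5x5 square: area 25 px, perimeter 20 pixel edges, solidity 1
  mask <- matrix(FALSE, 9, 9); mask[3:7, 3:7] <- TRUE
  img <- toy_image(matrix(10, 9, 9))
  seg <- label_initial_segments(mask, img, 1)
  f <- extract_features(seg[1, ], img)
  expect_identical(f$area_px, 25L)
  expect_identical(f$perimeter_px, 20)
  expect_equal(f$solidity, 1)
  expect_equal(f$axis_ratio, 1, tolerance = 1e-8)
  expect_equal(f$eccentricity, 0, tolerance = 1e-8)

  # rasterized disc: eccentricity ~ 0, solidity ~ 1
  g <- expand.grid(r = 1:41, c = 1:41)
  disc <- matrix((g$r - 21)^2 + (g$c - 21)^2 <= 15^2, 41, 41)
  segd <- label_initial_segments(disc, toy_image(matrix(1, 41, 41)), 1)
  fd <- extract_features(segd[1, ], toy_image(matrix(1, 41, 41)))
  expect_lt(fd$eccentricity, 0.1)
  expect_gt(fd$solidity, 0.9)  # rasterization stair-steps cost a few percent

  # 2:1 ellipse: axis ratio ~ 2 (moments oracle on the rasterization)
  ell <- matrix((g$r - 21)^2 / 8^2 + (g$c - 21)^2 / 16^2 <= 1, 41, 41)
  sege <- label_initial_segments(ell, toy_image(matrix(1, 41, 41)), 1)
  fe <- extract_features(sege[1, ], toy_image(matrix(1, 41, 41)))
  expect_equal(fe$axis_ratio, 2, tolerance = 0.06)

  # degenerate single pixel
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  sego <- label_initial_segments(one, toy_image(matrix(1, 5, 5)), 1)
  fo <- extract_features(sego[1, ], toy_image(matrix(1, 5, 5)))
  expect_identical(fo$eccentricity, 0)
  expect_identical(fo$axis_ratio, 1)
})

test_that("intensity integrals are background-subtracted and clamped", {
  px <- matrix(10, 6, 6); px[2:3, 2:6] <- 110
  img <- toy_image(px)
  seg <- tibble(label = 1L, pixels = list(rect_pixels(2, 3, 2, 6)),
                roi_id = "r")
  out <- segment_intensity_integral(seg[1, ], img, background = 10)
  expect_identical(out$J, 10 * 100)        # 10 px at (110 - 10)
  expect_equal(out$normalized_integral, 1000 / 110)

  # background above all intensities -> J = 0
  expect_identical(
    segment_intensity_integral(seg[1, ], img, background = 200)$J, 0)

  # elementwise-sum oracle on a random patch
  withr::with_seed(4, { rp <- matrix(runif(36, 0, 50), 6, 6) })
  rimg <- toy_image(rp)
  rseg <- tibble(label = 1L, pixels = list(rect_pixels(1, 6, 1, 6)))
  expect_equal(segment_intensity_integral(rseg[1, ], rimg, 7)$J,
               sum(pmax(rp - 7, 0)))
})

test_that("weighted grids scale point mass with transformed intensity", {
  seg <- tibble(label = 1L, pixels = list(rect_pixels(1, 2, 1, 2)))
  patch <- list(values = matrix(c(1, 0, 0, 0), 2, 2),
                mask = matrix(TRUE, 2, 2), bbox = c(row0 = 1L, col0 = 1L))
  gp <- weighted_grid(seg[1, ], patch, pixel_size_nm = 20,
                      points_per_unit = 9)
  counts <- table(gp$pixel)
  expect_identical(as.integer(counts[["1"]]), 9L)   # w = 1 pixel
  expect_identical(as.integer(counts[["2"]]), 1L)   # w = 0 floor
  expect_identical(nrow(gp), 12L)

  # uniform patch -> equal points per pixel; arithmetic oracle for totals
  patch_u <- list(values = matrix(2, 2, 2), mask = matrix(TRUE, 2, 2),
                  bbox = c(row0 = 1L, col0 = 1L))
  gu <- weighted_grid(seg[1, ], patch_u, 20, points_per_unit = 4)
  expect_identical(as.integer(table(gu$pixel)), rep(4L, 4))
  w <- evquant:::rescale_unit(patch_u$values[cbind(c(1, 2, 1, 2),
                                                   c(1, 1, 2, 2))])
  expect_identical(nrow(gu), as.integer(sum(pmax(1, round(4 * w)))))

  # points stay inside their pixel
  expect_true(all(gp$x_nm >= 0 & gp$x_nm <= 40 & gp$y_nm >= 0 &
                    gp$y_nm <= 40))
})

test_that("k-means splitting separates disjoint blobs like components", {
  # one mask containing two disjoint 3x3 blocks treated as one segment
  pix <- rbind(rect_pixels(2, 4, 2, 4), rect_pixels(12, 14, 12, 14))
  px <- matrix(1, 16, 16); px[pix] <- 100
  img <- toy_image(px)
  seg <- tibble(label = 1L, stage = "initial", area_px = nrow(pix),
                diameter_nm = 1, x_nm = 0, y_nm = 0,
                pixels = list(pix), polygon = list(NULL), roi_id = "r")
  patch <- laplacian_cubicroot(img, seg[1, ])
  gp <- weighted_grid(seg[1, ], patch, 20)
  out <- split_segment_kmeans(seg[1, ], gp, 2, img, seed = 11)
  expect_identical(nrow(out), 2L)
  parts <- lapply(out$pixels, function(p) sort(paste(p[, 1], p[, 2])))
  oracle <- list(sort(paste(rect_pixels(2, 4, 2, 4)[, 1],
                            rect_pixels(2, 4, 2, 4)[, 2])),
                 sort(paste(rect_pixels(12, 14, 12, 14)[, 1],
                            rect_pixels(12, 14, 12, 14)[, 2])))
  expect_setequal(vapply(parts, paste, character(1), collapse = ";"),
                  vapply(oracle, paste, character(1), collapse = ";"))

  # determinism under the same seed
  out2 <- split_segment_kmeans(seg[1, ], gp, 2, img, seed = 11)
  expect_identical(out$pixels, out2$pixels)

  # N = 1 returns the segment unchanged; N > points errors
  expect_identical(split_segment_kmeans(seg[1, ], gp, 1, img), seg[1, ])
  expect_error(split_segment_kmeans(seg[1, ], gp[1:2, ], 5, img),
               "fewer grid points")
})

test_that("final segments partition their parent and conserve area and J", {
  roi <- annotated_roi(205, merged_fraction = 0.4, roi_um = 6)
  finals <- finalize_segments(roi$initial, roi$image, analysis_config(),
                              classifier = NULL)
  for (parent in unique(finals$parent_label)) {
    childs <- finals[finals$parent_label == parent, ]
    ppix <- roi$initial$pixels[[which(roi$initial$label == parent)]]
    cpix <- do.call(rbind, childs$pixels)
    expect_identical(sum(childs$area_px), nrow(ppix))
    expect_setequal(paste(cpix[, 1], cpix[, 2]),
                    paste(ppix[, 1], ppix[, 2]))
  }
  # J is additive over the split (per-pixel clamp)
  pj <- vapply(unique(finals$parent_label), function(parent) {
    idx <- which(roi$initial$label == parent)
    segment_intensity_integral(roi$initial[idx, ], roi$image,
                               roi$background)$J
  }, numeric(1))
  cj <- vapply(unique(finals$parent_label), function(parent)
    sum(finals$J[finals$parent_label == parent]), numeric(1))
  expect_equal(cj, pj, tolerance = 1e-10)
})

test_that("the pipeline recovers well-separated EVs one final segment each", {
  cfg <- simulation_config(roi_width_um = 5, roi_height_um = 5,
                           ev_density_per_um2 = 0.2)
  truth <- simulate_ground_truth(cfg, seed = 41)
  img <- render_srrf_image(truth, cfg, seed = 42)
  segs <- segment_pipeline(img, analysis_config())
  expect_identical(nrow(segs), nrow(truth))
  expect_identical(nrow(segs), length(unique(segs$parent_label)))

  # empty image -> empty result
  empty <- srrf_image(matrix(0, 50, 50), 20)
  expect_identical(nrow(segment_pipeline(empty, analysis_config())), 0L)
})

test_that("pipeline output is deterministic for a fixed config", {
  cfg <- simulation_config(roi_width_um = 5, roi_height_um = 5,
                           merged_fraction = 0.4)
  truth <- simulate_ground_truth(cfg, seed = 51)
  img <- render_srrf_image(truth, cfg, seed = 52)
  a <- segment_pipeline(img, analysis_config())
  b <- segment_pipeline(img, analysis_config())
  expect_identical(a, b)
})
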