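# Shared fixtures and independent oracles, all built in code.

library(dplyr)

# An srrf_image whose pixels are given directly (pixel size 20 nm).
toy_image <- function(px, pixel_size_nm = 20, roi_id = "roi1") {
  srrf_image(px, pixel_size_nm = pixel_size_nm, roi_id = roi_id)
}

# Rectangle of pixels as an (row, col) index matrix.
rect_pixels <- function(r0, r1, c0, c1) {
  as.matrix(expand.grid(row = r0:r1, col = c0:c1))
}

# Segments tibble built from explicit pixel sets (for overlap tests).
segments_from_pixels <- function(pixel_list, roi_id = "roi1") {
  tibble(
    label = seq_along(pixel_list), stage = "final",
    area_px = vapply(pixel_list, nrow, integer(1)),
    diameter_nm = NA_real_, x_nm = NA_real_, y_nm = NA_real_,
    pixels = pixel_list, polygon = vector("list", length(pixel_list)),
    roi_id = roi_id
  )
}

# Clusters tibble carrying pre-rasterized pixel sets.
clusters_from_pixels <- function(pixel_list) {
  tibble(cluster_id = seq_along(pixel_list), pixels = pixel_list)
}

# Monte-Carlo nearest-site estimate of Voronoi cell areas inside a
# rectangle (the independent oracle for voronoi_densities). One jittered
# sample per stratum of a regular grid: still n_samples nearest-site
# draws, but the variance comes only from boundary-crossing strata.
mc_cell_areas <- function(x, y, bounds, n_samples = 1e5, seed = 1) {
  g <- floor(sqrt(n_samples))
  withr::with_seed(seed, {
    gx <- (rep(seq_len(g), times = g) - runif(g * g)) / g
    gy <- (rep(seq_len(g), each = g) - runif(g * g)) / g
    sx <- bounds[1] + gx * (bounds[2] - bounds[1])
    sy <- bounds[3] + gy * (bounds[4] - bounds[3])
    nn <- FNN::get.knnx(cbind(x, y), cbind(sx, sy), k = 1)$nn.index[, 1]
    counts <- tabulate(nn, nbins = length(x))
    counts / (g * g) * (bounds[2] - bounds[1]) * (bounds[4] - bounds[3])
  })
}

# Recursive flood fill, the independent oracle for 8-connected labelling.
flood_fill_labels <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask))
        next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      for (dr in -1:1) for (dc in -1:1) {
        if (dr != 0 || dc != 0)
          stack[[length(stack) + 1]] <- c(p[1] + dr, p[2] + dc)
      }
    }
  }
  lab
}

# Synthetic linearly separable feature tables for classifier tests.
separable_features <- function(n_per_class, shift = 8, seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(2 * n_per_class * 11), ncol = 11)
    base[seq_len(n_per_class), 1:3] <- base[seq_len(n_per_class), 1:3] + shift
    colnames(base) <- evquant:::FEATURE_NAMES
    list(features = as_tibble(base),
         true_n = rep(c(2L, 1L), each = n_per_class))
  })
}

# Annotated initial segments + features from one synthetic ROI (shared by
# classifier and acceptance tests).
annotated_roi <- function(seed, merged_fraction = 0.3, roi_um = 10,
                          acfg = analysis_config()) {
  cfg <- simulation_config(roi_width_um = roi_um, roi_height_um = roi_um,
                           merged_fraction = merged_fraction)
  truth <- simulate_ground_truth(cfg, seed = seed)
  img <- render_srrf_image(truth, cfg, seed = seed + 500L)
  mask <- binarize(img, threshold_fraction = acfg$threshold_fraction)
  init <- label_initial_segments(mask, img, acfg$min_segment_area_px)
  ann <- annotate_with_ground_truth(init, truth, img)
  bg <- estimate_background(img, mask)
  feats <- bind_rows(lapply(seq_len(nrow(ann)), function(i)
    extract_features(ann[i, ], img, bg)))
  list(cfg = cfg, truth = truth, image = img, mask = mask,
       initial = init, annotated = ann, features = feats, background = bg)
}

# Classifier trained once on three synthetic ROIs; reused across tests.
shared_classifier <- local({
  clf <- NULL
  function() {
    if (is.null(clf)) {
      rois <- lapply(c(101L, 102L, 103L, 104L, 105L), annotated_roi)
      feats <- bind_rows(lapply(rois, `[[`, "features"))
      truen <- unlist(lapply(rois, function(r) r$annotated$true_n))
      clf <<- train_component_classifier(feats, truen)
    }
    clf
  }
})
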