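# Colocalization of SRRF segments with SMLM clusters (validation arm) and
# between acquisition channels (cargo-positivity arm).
#
# All overlaps are evaluated on the shared ROI pixel raster: segments carry
# their pixel sets natively, and an SMLM cluster's region (the union of its
# member localizations' Voronoi cells) is rasterized exactly by
# nearest-localization site assignment: a pixel centre lies in the union
# iff its nearest localization is a cluster member. The overlap statistic
# is intersection area over the smaller of the two areas, which tolerates
# the two modalities' different effective resolutions (~28 nm SMLM vs
# ~70 nm SRRF).

# Rasterize cluster regions onto the image grid. Returns a tibble
# (pix, cluster_id) of linear pixel indices covered by each cluster.
rasterize_clusters <- function(clusters, locs, image) {
  if (nrow(clusters) == 0)
    return(tibble(pix = integer(), cluster_id = integer()))
  if ("pixels" %in% names(clusters)) {
    # pre-rasterized clusters (tests, rectangle fixtures)
    nr <- nrow(image$pixels)
    return(bind_rows(purrr::map2(
      clusters$pixels, clusters$cluster_id,
      function(p, id) tibble(pix = (p[, 2] - 1L) * nr + p[, 1],
                             cluster_id = id))))
  }
  px_nm <- image$pixel_size_nm
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  member_of <- integer(nrow(locs))
  for (i in seq_len(nrow(clusters)))
    member_of[clusters$loc_indices[[i]]] <- clusters$cluster_id[i]
  out <- purrr::map(seq_len(nrow(clusters)), function(i) {
    ring <- clusters$polygon[[i]]
    pts <- if (!is.null(ring)) ring else
      cbind(locs$x_nm[clusters$loc_indices[[i]]],
            locs$y_nm[clusters$loc_indices[[i]]])
    c0 <- max(1L, floor(min(pts[, 1]) / px_nm) + 1L)
    c1 <- min(nc, floor(max(pts[, 1]) / px_nm) + 1L)
    r0 <- max(1L, floor(min(pts[, 2]) / px_nm) + 1L)
    r1 <- min(nr, floor(max(pts[, 2]) / px_nm) + 1L)
    if (c1 < c0 || r1 < r0) return(NULL)
    grid <- expand.grid(row = r0:r1, col = c0:c1)
    ctr <- pixel_center_nm(grid$row, grid$col, px_nm)
    nn <- FNN::get.knnx(cbind(locs$x_nm, locs$y_nm), ctr, k = 1)
    keep <- member_of[nn$nn.index[, 1]] == clusters$cluster_id[i]
    if (!any(keep)) return(NULL)
    tibble(pix = (grid$col[keep] - 1L) * nr + grid$row[keep],
           cluster_id = clusters$cluster_id[i])
  })
  bind_rows(purrr::compact(out))
}

segment_pixel_table <- function(segments, nr) {
  if (nrow(segments) == 0) return(tibble(pix = integer(), label = integer()))
  bind_rows(purrr::map2(segments$pixels, segments$label, function(p, id)
    tibble(pix = (p[, 2] - 1L) * nr + p[, 1], label = id)))
}

#' Match SRRF segments to SMLM clusters
#'
#' Records a pair (segment, cluster) whenever
#' `area(intersection) / min(area(segment), area(cluster))` reaches
#' `min_overlap_fraction`, resolves a one-to-one assignment greedily by
#' descending overlap (ties to the lower segment label), and categorizes
#' every segment (`one_to_one`, `multi`, `srrf_only`) and cluster
#' (`matched`, `smlm_only`).
#'
#' @param segments final segments tibble from [segment_pipeline()].
#' @param clusters clusters tibble from [cluster_localizations()].
#' @param image the ROI's [srrf_image()] (defines the raster and ROI id).
#' @param locs the localization map behind `clusters` (not needed when the
#'   clusters carry a pre-rasterized `pixels` column).
#' @param min_overlap_fraction overlap rule threshold.
#' @return an object of class `ev_match`: list with `pairs` (segment label,
#'   cluster id, overlap fraction, `assigned` flag), `segment_categories`,
#'   `cluster_categories`.
#' @export
match_segments_to_clusters <- function(segments, clusters, image,
                                       locs = NULL,
                                       min_overlap_fraction = 0.25) {
  if (!is.null(segments$roi_id) && nrow(segments) > 0 &&
      any(segments$roi_id != image$roi_id))
    abort("match_segments_to_clusters: segments belong to a different ROI")
  nr <- nrow(image$pixels)
  seg_tab <- segment_pixel_table(segments, nr)
  clu_tab <- rasterize_clusters(clusters, locs, image)
  seg_area <- dplyr::count(seg_tab, .data$label, name = "area_s")
  clu_area <- dplyr::count(clu_tab, .data$cluster_id, name = "area_c")
  inter <- inner_join(seg_tab, clu_tab, by = "pix",
                      relationship = "many-to-many")
  pairs <- dplyr::count(inter, .data$label, .data$cluster_id,
                        name = "area_int")
  pairs <- left_join(pairs, seg_area, by = "label")
  pairs <- left_join(pairs, clu_area, by = "cluster_id")
  pairs <- mutate(pairs,
                  overlap = .data$area_int / pmin(.data$area_s, .data$area_c))
  pairs <- filter(pairs, .data$overlap >= min_overlap_fraction)
  pairs <- arrange(pairs, desc(.data$overlap), .data$label, .data$cluster_id)
  # greedy one-to-one resolution
  assigned <- logical(nrow(pairs))
  used_s <- integer(0); used_c <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$label[i] %in% used_s) && !(pairs$cluster_id[i] %in% used_c)) {
      assigned[i] <- TRUE
      used_s <- c(used_s, pairs$label[i])
      used_c <- c(used_c, pairs$cluster_id[i])
    }
  }
  pairs$assigned <- assigned
  n_per_seg <- dplyr::count(pairs, .data$label)
  seg_cat <- tibble(label = segments$label) |>
    left_join(n_per_seg, by = "label") |>
    mutate(category = dplyr::case_when(
      is.na(.data$n) ~ "srrf_only",
      .data$n == 1 ~ "one_to_one",
      TRUE ~ "multi"
    )) |> select("label", "category")
  clu_cat <- tibble(cluster_id = clusters$cluster_id) |>
    mutate(category = ifelse(.data$cluster_id %in% pairs$cluster_id,
                             "matched", "smlm_only"))
  structure(
    list(pairs = select(pairs, "label", "cluster_id", "overlap", "assigned"),
         segment_categories = seg_cat, cluster_categories = clu_cat),
    class = "ev_match"
  )
}

#' @export
print.ev_match <- function(x, ...) {
  sc <- table(x$segment_categories$category)
  cc <- table(x$cluster_categories$category)
  cat(sprintf("<ev_match> %d passing pairs (%d one-to-one)\n",
              nrow(x$pairs), sum(x$pairs$assigned)))
  cat("  segments:", paste(names(sc), sc, sep = "=", collapse = ", "), "\n")
  cat("  clusters:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method
glance.ev_match <- function(x, ...) {
  sc <- x$segment_categories$category
  cc <- x$cluster_categories$category
  tibble(
    n_pairs = nrow(x$pairs),
    n_assigned = sum(x$pairs$assigned),
    n_segments = length(sc),
    n_clusters = length(cc),
    one_to_one = sum(sc == "one_to_one"),
    multi = sum(sc == "multi"),
    srrf_only = sum(sc == "srrf_only"),
    smlm_only = sum(cc == "smlm_only"),
    segment_match_fraction = if (length(sc)) mean(sc != "srrf_only") else NA_real_,
    cluster_match_fraction = if (length(cc)) mean(cc == "matched") else NA_real_
  )
}

#' Annotate initial segments with true component counts from SMLM
#'
#' The classifier training annotation: `true_n` is the number of SMLM
#' clusters whose overlap with the segment passes the overlap rule;
#' segments overlapping no cluster are excluded.
#'
#' @inheritParams match_segments_to_clusters
#' @param segments initial segments tibble.
#' @return the segments tibble with a `true_n` column (rows with
#'   `true_n = 0` removed).
#' @export
annotate_true_counts <- function(segments, clusters, image, locs = NULL,
                                 min_overlap_fraction = 0.25) {
  m <- match_segments_to_clusters(segments, clusters, image, locs,
                                  min_overlap_fraction)
  counts <- dplyr::count(m$pairs, .data$label, name = "true_n")
  out <- inner_join(segments, counts, by = "label")
  out$true_n <- as.integer(out$true_n)
  out
}

#' Annotate segments with ground-truth EV counts (synthetic data)
#'
#' For generator-produced images the true component count of a segment is
#' the number of simulated EV centres falling inside its pixel set. Close
#' EV pairs below the SMLM clustering resolution make the SMLM-based
#' annotation undercount exactly the segments the classifier must learn,
#' so synthetic training uses this oracle instead.
#'
#' @param segments segments tibble.
#' @param truth ground-truth EV tibble from [simulate_ground_truth()].
#' @param image the ROI's [srrf_image()].
#' @return segments tibble with a `true_n` column (segments containing no
#'   EV centre are removed).
#' @export
annotate_with_ground_truth <- function(segments, truth, image) {
  if (nrow(segments) == 0) { segments$true_n <- integer(); return(segments) }
  nr <- nrow(image$pixels)
  rc <- nm_to_pixel(truth$x_nm, truth$y_nm, image$pixel_size_nm,
                    dim(image$pixels))
  ev_pix <- (rc[, "col"] - 1L) * nr + rc[, "row"]
  segments$true_n <- vapply(segments$pixels, function(p) {
    sum(ev_pix %in% ((p[, 2] - 1L) * nr + p[, 1]))
  }, integer(1))
  filter(segments, .data$true_n > 0)
}

#' Confusion matrix of true vs predicted component counts
#'
#' @param true_n,predicted_n integer vectors; classes above `max_class` are
#'   pooled into `max_class`.
#' @param max_class largest reported class.
#' @return an object of class `ev_confusion`: list with integer `counts`
#'   (true in rows, predicted in columns) and `row_percent`.
#' @export
confusion <- function(true_n, predicted_n, max_class = 3L) {
  stopifnot(length(true_n) == length(predicted_n), length(true_n) >= 1)
  clamp <- function(v) factor(pmin(as.integer(v), max_class),
                              levels = seq_len(max_class))
  counts <- table(true = clamp(true_n), predicted = clamp(predicted_n))
  rs <- rowSums(counts)
  row_percent <- sweep(counts, 1, ifelse(rs == 0, 1, rs), "/") * 100
  structure(list(counts = unclass(counts),
                 row_percent = unclass(row_percent),
                 n = length(true_n)),
            class = "ev_confusion")
}

#' @export
print.ev_confusion <- function(x, ...) {
  cat(sprintf("<ev_confusion> %d segments; row%% (counts):\n", x$n))
  print(round(x$row_percent, 1))
  invisible(x)
}

#' @exportS3Method
tidy.ev_confusion <- function(x, ...) {
  cnt <- as.data.frame.table(as.table(x$counts), responseName = "count")
  pct <- as.data.frame.table(as.table(x$row_percent), responseName = "percent")
  out <- as_tibble(cnt)
  out$percent <- pct$percent
  out$true <- as.integer(as.character(out$true))
  out$predicted <- as.integer(as.character(out$predicted))
  out
}

#' Cross-channel positivity fraction
#'
#' Fraction of reference-channel EVs (e.g. red, TSPAN-detected) that
#' colocalize with a segment in the other channel (e.g. green, GFP or RNA
#' stain), per the pairwise overlap rule. Both segment tables must live on
#' the same ROI raster.
#'
#' @param reference_segments segments tibble of the reference channel.
#' @param other_segments segments tibble of the other channel.
#' @param image the ROI's [srrf_image()] (either channel; defines raster).
#' @param min_overlap_fraction overlap rule threshold.
#' @return fraction in `[0, 1]`.
#' @export
channel_positivity <- function(reference_segments, other_segments, image,
                               min_overlap_fraction = 0.25) {
  if (nrow(reference_segments) == 0)
    abort("channel_positivity: empty reference set (fraction undefined)")
  if (nrow(other_segments) == 0) return(0)
  nr <- nrow(image$pixels)
  ref_tab <- segment_pixel_table(reference_segments, nr)
  oth_tab <- dplyr::rename(
    segment_pixel_table(other_segments, nr), other = "label")
  ref_area <- dplyr::count(ref_tab, .data$label, name = "area_r")
  oth_area <- dplyr::count(oth_tab, .data$other, name = "area_o")
  inter <- inner_join(ref_tab, oth_tab, by = "pix",
                      relationship = "many-to-many")
  pairs <- dplyr::count(inter, .data$label, .data$other, name = "area_int") |>
    left_join(ref_area, by = "label") |>
    left_join(oth_area, by = "other") |>
    mutate(overlap = .data$area_int / pmin(.data$area_r, .data$area_o)) |>
    filter(.data$overlap >= min_overlap_fraction)
  length(unique(pairs$label)) / nrow(reference_segments)
}
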