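# SRRF image segmentation: binarization, connected-component labelling,
# Laplacian-of-cube-root peak analysis, and intensity-weighted k-means
# splitting of merged segments.
#
# A reconstructed SRRF image shows each surface-captured EV as a
# sub-diffraction spot. Thresholding yields "initial" segments; a segment
# may cover several EVs sitting closer than the SRRF resolution. The
# cube-root transform compresses the dynamic range between bright and dim
# neighbours and the (negated) discrete Laplacian sharpens each underlying
# spot, so multi-EV segments show multiple peaks. Segments with a single
# peak but sufficient internal intensity variation are referred to an
# ordinal classifier (see train_component_classifier); segments with N > 1
# components are split by k-means on an intensity-weighted grid.

#' Binarize an SRRF image
#'
#' @param image an [srrf_image()].
#' @param mode `"fraction_of_max"`: foreground where intensity is at least
#'   `threshold_fraction` times the maximum image intensity (0.50% of
#'   maximum by default). `"adaptive"`: foreground where intensity exceeds
#'   the local mean (boxcar window) by `offset`; used for single-fluorophore
#'   calibration surfaces.
#' @param threshold_fraction fraction of maximum intensity (fraction mode).
#' @param window_px odd boxcar window width in px (adaptive mode).
#' @param offset intensity offset above the local mean (adaptive mode);
#'   `NULL` picks `4 * mad(image)`.
#' @return logical matrix, `TRUE` for foreground. An all-zero image gives an
#'   empty mask in fraction mode.
#' @export
binarize <- function(image, mode = c("fraction_of_max", "adaptive"),
                     threshold_fraction = 0.005, window_px = 31L,
                     offset = NULL) {
  mode <- match.arg(mode)
  px <- image$pixels
  if (mode == "fraction_of_max") {
    stopifnot(threshold_fraction > 0, threshold_fraction < 1)
    m <- max(px)
    if (m == 0) return(matrix(FALSE, nrow(px), ncol(px)))
    px >= threshold_fraction * m
  } else {
    offset <- offset %||% (4 * stats::mad(px))
    px > box_mean(px, window_px) + offset
  }
}

# Boxcar local mean with edge replication, via an integral image.
box_mean <- function(px, window_px) {
  r <- (as.integer(window_px) - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(0, nr + 2 * r, nc + 2 * r)
  pad[(r + 1):(r + nr), (r + 1):(r + nc)] <- px
  # replicate edges
  pad[1:r, ] <- pad[rep(r + 1, r), ]
  pad[(r + nr + 1):(r + nr + r), ] <- pad[rep(r + nr, r), ]
  pad[, 1:r] <- pad[, rep(r + 1, r)]
  pad[, (r + nc + 1):(r + nc + r)] <- pad[, rep(r + nc, r)]
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- rbind(0, cbind(0, t(ii)))
  w <- 2 * r + 1
  i1 <- 1:nr; j1 <- 1:nc
  s <- ii[i1 + w, j1 + w, drop = FALSE] - ii[i1, j1 + w, drop = FALSE] -
       ii[i1 + w, j1, drop = FALSE] + ii[i1, j1, drop = FALSE]
  s / w^2
}

#' Label initial segments in a binary mask
#'
#' 8-connected components of the foreground mask with area at least
#' `min_area_px`, with the outer boundary traced along pixel edges (nm
#' coordinates).
#'
#' @param mask logical matrix from [binarize()].
#' @param image the source [srrf_image()] (for pixel size / ROI metadata).
#' @param min_area_px minimum component area in px.
#' @return segments tibble (stage `"initial"`): `label`, `area_px`,
#'   `diameter_nm`, centroid `x_nm`/`y_nm`, plus list-columns `pixels`
#'   (n x 2 row/col matrices) and `polygon` (nm vertex matrices).
#' @export
label_initial_segments <- function(mask, image, min_area_px = 4L) {
  px_nm <- image$pixel_size_nm
  comps <- connected_components(mask)
  rows <- purrr::keep(comps, ~ nrow(.x) >= min_area_px)
  if (length(rows) == 0) return(empty_segments())
  out <- purrr::imap(rows, function(pix, i) {
    ctr <- pixel_center_nm(pix[, 1], pix[, 2], px_nm)
    tibble(
      label = as.integer(i), stage = "initial",
      area_px = nrow(pix),
      diameter_nm = 2 * sqrt(nrow(pix) * px_nm^2 / pi),
      x_nm = mean(ctr[, 1]), y_nm = mean(ctr[, 2]),
      pixels = list(pix),
      polygon = list(trace_boundary(pix, px_nm))
    )
  })
  bind_rows(out)
}

empty_segments <- function() {
  tibble(label = integer(), stage = character(), area_px = integer(),
         diameter_nm = double(), x_nm = double(), y_nm = double(),
         pixels = list(), polygon = list())
}

# 8-connected components of a logical matrix; returns a list of n x 2
# (row, col) index matrices ordered by first (column-major) pixel.
connected_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  nr <- nrow(mask)
  id <- integer(length(mask)); id[idx] <- seq_along(idx)
  offs <- c(1, nr - 1, nr, nr + 1)  # down, up-right, right, down-right
  edges <- purrr::map(offs, function(o) {
    a <- idx
    b <- idx + o
    rowa <- (a - 1L) %% nr + 1L
    ok <- b >= 1 & b <= length(mask)
    # forbid wrap across matrix columns
    if (o == 1) ok <- ok & rowa < nr
    if (o == nr - 1) ok <- ok & rowa > 1
    if (o == nr + 1) ok <- ok & rowa < nr
    ok[ok] <- mask[b[ok]]
    cbind(id[a[ok]], id[b[ok]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(as.character(seq_along(idx)),
                      igraph::V(g)$name)),
    name = setdiff(as.character(seq_along(idx)), igraph::V(g)$name))
  comp <- igraph::components(g)
  mem <- comp$membership[as.character(seq_along(idx))]
  groups <- split(idx, mem)
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  purrr::map(groups, function(g_idx) {
    cbind(row = (g_idx - 1L) %% nr + 1L, col = (g_idx - 1L) %/% nr + 1L)
  })
}

# Trace the outer boundary of a pixel set along pixel edges, in nm.
# Directed pixel-edge cancellation: interior edges appear twice in opposite
# directions and drop out; the remaining edges chain into rings, of which
# the largest-area one is the outer boundary.
trace_boundary <- function(pix, px_nm) {
  r <- pix[, 1]; c <- pix[, 2]
  # corners in nm; y increases downward (image convention)
  x0 <- (c - 1) * px_nm; x1 <- c * px_nm
  y0 <- (r - 1) * px_nm; y1 <- r * px_nm
  seg <- rbind(
    cbind(x0, y0, x1, y0),  # top
    cbind(x1, y0, x1, y1),  # right
    cbind(x1, y1, x0, y1),  # bottom
    cbind(x0, y1, x0, y0)   # left
  )
  key_f <- paste(seg[, 1], seg[, 2], seg[, 3], seg[, 4])
  key_b <- paste(seg[, 3], seg[, 4], seg[, 1], seg[, 2])
  internal <- key_f %in% key_b
  seg <- seg[!internal, , drop = FALSE]
  rings <- chain_segments(seg, digits = 6)
  if (length(rings) == 0) return(NULL)
  areas <- vapply(rings, function(x) abs(shoelace_area(x)), numeric(1))
  rings[[which.max(areas)]]
}

#' Laplacian of the cube-root-transformed intensity over a segment
#'
#' Computes the discrete Laplacian (5-point stencil, reflect padding) of the
#' elementwise cube root of the intensity, restricted to the segment's
#' bounding box. Peaks of intensity appear as minima of the transform; the
#' cube root compresses the brightness difference between strong and weak
#' components of a merged segment so that dim partners survive peak
#' detection.
#'
#' @param image an [srrf_image()].
#' @param segment one row of a segments tibble.
#' @return list with `values` (matrix over the bounding box), logical
#'   foreground `mask`, and the bounding box `bbox = c(row0, col0)` offset
#'   (top-left pixel, 1-based).
#' @export
laplacian_cubicroot <- function(image, segment) {
  pix <- segment$pixels[[1]]
  r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
  c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
  patch <- image$pixels[r0:r1, c0:c1, drop = FALSE]
  v <- laplacian5(patch^(1 / 3))
  mask <- matrix(FALSE, nrow(patch), ncol(patch))
  mask[cbind(pix[, 1] - r0 + 1L, pix[, 2] - c0 + 1L)] <- TRUE
  list(values = v, mask = mask, bbox = c(row0 = r0, col0 = c0))
}

# 5-point discrete Laplacian with reflect padding.
laplacian5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up    <- m[c(1, seq_len(nr - 1)), , drop = FALSE]
  down  <- m[c(seq_len(nr)[-1], nr), , drop = FALSE]
  left  <- m[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- m[, c(seq_len(nc)[-1], nc), drop = FALSE]
  up + down + left + right - 4 * m
}

#' Detect peaks in a transformed segment patch
#'
#' Finds regional maxima of the negated transform (intensity peaks are
#' Laplacian minima) on the segment foreground, filters them by topographic
#' prominence and by pairwise separation, and returns them sorted by
#' magnitude.
#'
#' @param patch result of [laplacian_cubicroot()].
#' @param prominence minimum prominence as a fraction of the patch's
#'   negated-transform value range (relative, so the pipeline is invariant
#'   to global intensity rescaling).
#' @param min_separation_px minimum pairwise peak distance in px.
#' @return tibble with `row`, `col` (absolute image coordinates), `value`
#'   and `prominence`, strongest first.
#' @export
detect_peaks <- function(patch, prominence = 0.2, min_separation_px = 2L) {
  stopifnot(prominence >= 0)
  s <- -patch$values
  mask <- patch$mask
  nr <- nrow(s); nc <- ncol(s)
  cand <- which(mask)
  if (length(cand) == 0) return(empty_peaks())
  # regional maxima: >= all 8 neighbours (out-of-patch treated as -Inf) and
  # strictly greater than at least one
  spad <- matrix(-Inf, nr + 2, nc + 2)
  spad[2:(nr + 1), 2:(nc + 1)] <- s
  rr <- (cand - 1L) %% nr + 2L
  cc <- (cand - 1L) %/% nr + 2L
  nbr <- sapply(list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                     c(1, -1), c(1, 0), c(1, 1)),
                function(d) spad[cbind(rr + d[1], cc + d[2])])
  if (length(cand) == 1) nbr <- matrix(nbr, nrow = 1)
  v <- s[cand]
  nbr_max <- apply(nbr, 1, max)
  # a peak must dominate its neighbourhood and strictly exceed at least
  # one finite (in-patch) neighbour, so plateaus and constant patches
  # yield no peaks
  n_lower <- rowSums(is.finite(nbr) & nbr < v)
  is_max <- v >= nbr_max & n_lower > 0
  peaks <- cand[is_max]
  if (length(peaks) == 0) return(empty_peaks())
  prom <- peak_prominence(s, mask, peaks)
  rng <- diff(range(s[mask]))
  keep <- if (rng > 0) prom >= prominence * rng else rep(TRUE, length(peaks))
  peaks <- peaks[keep]; prom <- prom[keep]
  if (length(peaks) == 0) return(empty_peaks())
  ord <- order(-s[peaks])
  peaks <- peaks[ord]; prom <- prom[ord]
  # greedy separation filter, strongest first
  pr <- (peaks - 1L) %% nr + 1L
  pc <- (peaks - 1L) %/% nr + 1L
  kept <- integer(0)
  for (i in seq_along(peaks)) {
    if (length(kept) == 0 ||
        all((pr[i] - pr[kept])^2 + (pc[i] - pc[kept])^2 >=
            min_separation_px^2)) {
      kept <- c(kept, i)
    }
  }
  tibble(
    row = pr[kept] + patch$bbox[["row0"]] - 1L,
    col = pc[kept] + patch$bbox[["col0"]] - 1L,
    value = s[peaks[kept]],
    prominence = prom[kept]
  )
}

empty_peaks <- function() {
  tibble(row = integer(), col = integer(), value = double(),
         prominence = double())
}

# Topographic prominence of regional maxima by descending-level union-find
# over the foreground pixels: when the region growing down from a peak first
# meets a region containing a higher peak, the meeting level is its key
# saddle. The globally highest peak gets (peak - lowest foreground level).
peak_prominence <- function(s, mask, peaks) {
  nr <- nrow(s)
  fg <- which(mask)
  ordv <- fg[order(-s[fg])]
  parent <- integer(length(s))          # 0 = unprocessed
  comp_peak <- numeric(length(s))       # highest value in component root
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prom <- stats::setNames(rep(NA_real_, length(peaks)), peaks)
  peak_set <- logical(length(s)); peak_set[peaks] <- TRUE
  peak_of_root <- integer(length(s))    # representative peak index per root
  inmask <- logical(length(s)); inmask[fg] <- TRUE
  for (p in ordv) {
    parent[p] <- p
    comp_peak[p] <- s[p]
    peak_of_root[p] <- if (peak_set[p]) p else 0L
    rp <- (p - 1L) %% nr + 1L; cp <- (p - 1L) %/% nr + 1L
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                   c(1, -1), c(1, 0), c(1, 1))) {
      rn <- rp + d[1]; cn <- cp + d[2]
      if (rn < 1 || rn > nr || cn < 1 || cn > ncol(s)) next
      q <- (cn - 1L) * nr + rn
      if (q > length(s) || !inmask[q] || parent[q] == 0L) next
      rq <- find(q); rpth <- find(p)
      if (rq == rpth) next
      # merge: the component with the lower summit dies at this level
      lo <- if (comp_peak[rq] < comp_peak[rpth]) rq else rpth
      hi <- if (lo == rq) rpth else rq
      dead_peak <- peak_of_root[lo]
      if (dead_peak > 0L && peak_set[dead_peak] &&
          is.na(prom[as.character(dead_peak)]))
        prom[as.character(dead_peak)] <- s[dead_peak] - s[p]
      parent[lo] <- hi
      if (peak_of_root[hi] == 0L) peak_of_root[hi] <- peak_of_root[lo]
    }
  }
  base <- min(s[fg])
  for (i in seq_along(peaks)) {
    if (is.na(prom[i])) prom[i] <- s[peaks[i]] - base
  }
  unname(prom)
}

#' Is a segment eligible for classifier-driven splitting?
#'
#' Initial segments with low internal intensity variation are not considered
#' for further segmentation (over-segmentation guard): eligibility requires
#' the coefficient of variation of the background-subtracted foreground
#' intensities to exceed `cv_cutoff`.
#'
#' @param segment one row of a segments tibble.
#' @param image the source [srrf_image()].
#' @param cv_cutoff coefficient-of-variation cutoff.
#' @param background background intensity estimate.
#' @return `TRUE` if the segment should be passed to the classifier.
#' @export
variation_eligible <- function(segment, image, cv_cutoff = 0.2,
                               background = 0) {
  v <- pmax(image$pixels[segment$pixels[[1]]] - background, 0)
  m <- mean(v)
  if (m <= 0) return(FALSE)
  stats::sd(v) / m > cv_cutoff
}

#' Background-subtracted intensity integral of a segment
#'
#' `J = sum over foreground pixels of max(intensity - background, 0)`; the
#' per-pixel clamp makes J exactly additive over any split of the segment.
#' The normalized integral divides J by the ROI's maximum intensity
#' (dimensionless, illumination-robust); its square root is the input
#' feature of the molecule-content regression.
#'
#' @inheritParams variation_eligible
#' @param background background intensity estimate (>= 0), e.g.
#'   [estimate_background()].
#' @return list with `J` and `normalized_integral`.
#' @export
segment_intensity_integral <- function(segment, image, background = 0) {
  stopifnot(background >= 0)
  J <- sum(pmax(image$pixels[segment$pixels[[1]]] - background, 0))
  mx <- max(image$pixels)
  list(J = J, normalized_integral = if (mx > 0) J / mx else 0)
}

#' Median-of-background intensity estimate for an ROI
#'
#' @param image an [srrf_image()].
#' @param mask foreground mask from [binarize()].
#' @return median intensity of the non-segment pixels.
#' @export
estimate_background <- function(image, mask) {
  bg <- image$pixels[!mask]
  if (length(bg) == 0) 0 else stats::median(bg)
}

#' Intensity-weighted grid of synthetic localizations over a segment
#'
#' For k-means splitting, each foreground pixel receives
#' `max(1, round(points_per_unit * w))` grid points on a regular sub-lattice
#' of the pixel, where `w` is the pixel's transformed-intensity magnitude
#' rescaled to `[0, 1]` over the segment. Total points >= segment area.
#'
#' @param segment one row of a segments tibble.
#' @param patch result of [laplacian_cubicroot()] for that segment.
#' @param pixel_size_nm physical pixel size.
#' @param points_per_unit grid points for a full-weight pixel.
#' @return tibble with `x_nm`, `y_nm` and the source `pixel` index.
#' @export
weighted_grid <- function(segment, patch, pixel_size_nm,
                          points_per_unit = 10) {
  pix <- segment$pixels[[1]]
  prow <- pix[, 1] - patch$bbox[["row0"]] + 1L
  pcol <- pix[, 2] - patch$bbox[["col0"]] + 1L
  w <- rescale_unit(patch$values[cbind(prow, pcol)])
  n_p <- pmax(1L, as.integer(round(points_per_unit * w)))
  out <- purrr::map(seq_len(nrow(pix)), function(i) {
    n <- n_p[i]
    g <- ceiling(sqrt(n))
    off <- (seq_len(g) - 0.5) / g
    sub <- expand.grid(dx = off, dy = off)[seq_len(n), ]
    tibble(
      x_nm = (pix[i, 2] - 1 + sub$dx) * pixel_size_nm,
      y_nm = (pix[i, 1] - 1 + sub$dy) * pixel_size_nm,
      pixel = i
    )
  })
  bind_rows(out)
}

#' Split a merged segment by k-means on grid localizations
#'
#' Runs k-means (k = N, seeded, 10 restarts of k-means++-style sampling via
#' R's default initialisation) on the weighted grid points, then assigns
#' every foreground pixel to the cluster of its nearest centre (ties to the
#' lowest cluster index). Pixel partitions need not be connected.
#'
#' @param segment one row of a segments tibble.
#' @param grid_points tibble from [weighted_grid()].
#' @param n_components number of components N; `N <= 1` returns the segment
#'   unchanged.
#' @param image the source [srrf_image()].
#' @param seed RNG seed for the k-means restarts.
#' @return segments tibble with `n_components` rows (stage `"final"`).
#' @export
split_segment_kmeans <- function(segment, grid_points, n_components, image,
                                 seed = 1L) {
  if (n_components <= 1) return(segment)
  if (nrow(grid_points) < n_components)
    abort("split_segment_kmeans: fewer grid points than components")
  km <- withr::with_seed(as.integer(seed), {
    stats::kmeans(cbind(grid_points$x_nm, grid_points$y_nm),
                  centers = n_components, nstart = 10, iter.max = 50)
  })
  centers <- km$centers[order(km$centers[, 1], km$centers[, 2]), ,
                        drop = FALSE]
  pix <- segment$pixels[[1]]
  ctr <- pixel_center_nm(pix[, 1], pix[, 2], image$pixel_size_nm)
  d2 <- outer(ctr[, 1], centers[, 1], "-")^2 +
        outer(ctr[, 2], centers[, 2], "-")^2
  assign <- apply(d2, 1, which.min)  # which.min takes the lowest index on ties
  parts <- split(seq_len(nrow(pix)), assign)
  out <- purrr::imap(parts, function(sel, part_id) {
    sub <- segment
    sub$pixels <- list(pix[sel, , drop = FALSE])
    sub$area_px <- length(sel)
    sub$diameter_nm <- 2 * sqrt(length(sel) * image$pixel_size_nm^2 / pi)
    sub$x_nm <- mean(ctr[sel, 1]); sub$y_nm <- mean(ctr[sel, 2])
    sub$polygon <- list(trace_boundary(pix[sel, , drop = FALSE],
                                       image$pixel_size_nm))
    sub$stage <- "final"
    sub
  })
  bind_rows(out)
}

#' Extract the 11 classifier features of a segment
#'
#' Morphology, intensity and texture features computed on the
#' background-subtracted patch: area (px), perimeter (pixel edges),
#' equivalent diameter (px), eccentricity, solidity, major/minor axis
#' ratio, maximum intensity, mean intensity, intensity coefficient of
#' variation, intensity integral, and the dispersion (sd) of a 9-bin
#' histogram of oriented gradients pooled over the patch.
#'
#' @inheritParams variation_eligible
#' @param background background intensity estimate.
#' @return a 1-row tibble of 11 numeric features.
#' @export
extract_features <- function(segment, image, background = 0) {
  pix <- segment$pixels[[1]]
  vals <- pmax(image$pixels[pix] - background, 0)
  area <- nrow(pix)
  # perimeter: pixel edges adjacent to background (4-neighbourhood)
  key <- paste(pix[, 1], pix[, 2])
  nbr4 <- sum(paste(pix[, 1] + 1L, pix[, 2]) %in% key) +
          sum(paste(pix[, 1], pix[, 2] + 1L) %in% key)
  perimeter <- 4 * area - 2 * nbr4
  # mask second moments
  if (area >= 2) {
    cv <- stats::cov(pix[, c(2, 1)])  # (col, row) = (x, y)
    ev <- eigen(cv, symmetric = TRUE)$values
    ev <- pmax(ev, 1e-12)
    ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
    axis_ratio <- sqrt(ev[1] / ev[2])
  } else {
    ecc <- 0; axis_ratio <- 1
  }
  # solidity: pixel area over convex hull of pixel corner points
  corners <- rbind(
    cbind(pix[, 2] - 1, pix[, 1] - 1), cbind(pix[, 2], pix[, 1] - 1),
    cbind(pix[, 2], pix[, 1]), cbind(pix[, 2] - 1, pix[, 1])
  )
  ha <- hull_area(corners)
  solidity <- if (ha > 0) min(area / ha, 1) else 1
  m <- mean(vals)
  tibble(
    area_px = area,
    perimeter_px = perimeter,
    equiv_diameter_px = 2 * sqrt(area / pi),
    eccentricity = ecc,
    solidity = solidity,
    axis_ratio = min(axis_ratio, 50),
    max_intensity = max(vals),
    mean_intensity = m,
    cv_intensity = if (m > 0) stats::sd(vals) / m else 0,
    intensity_integral = sum(vals),
    hog_dispersion = hog_dispersion(segment, image, background)
  )
}

# sd of a 9-bin orientation histogram of intensity gradients pooled over
# the segment foreground (magnitude-weighted, normalized to unit sum).
hog_dispersion <- function(segment, image, background) {
  pix <- segment$pixels[[1]]
  r0 <- min(pix[, 1]); c0 <- min(pix[, 2])
  patch <- pmax(image$pixels[r0:max(pix[, 1]), c0:max(pix[, 2]),
                             drop = FALSE] - background, 0)
  nr <- nrow(patch); nc <- ncol(patch)
  gx <- (patch[, c(seq_len(nc)[-1], nc), drop = FALSE] -
         patch[, c(1, seq_len(nc - 1)), drop = FALSE]) / 2
  gy <- (patch[c(seq_len(nr)[-1], nr), , drop = FALSE] -
         patch[c(1, seq_len(nr - 1)), , drop = FALSE]) / 2
  sel <- cbind(pix[, 1] - r0 + 1L, pix[, 2] - c0 + 1L)
  mag <- sqrt(gx[sel]^2 + gy[sel]^2)
  ang <- atan2(gy[sel], gx[sel]) %% pi
  bin <- pmin(floor(ang / (pi / 9)) + 1L, 9L)
  h <- vapply(1:9, function(b) sum(mag[bin == b]), numeric(1))
  tot <- sum(h)
  if (tot == 0) return(0)
  stats::sd(h / tot)
}

#' Segment an SRRF image into single-EV regions
#'
#' Full segmentation pipeline: binarize, label initial segments, transform
#' each segment (Laplacian of the cube root) and count peaks. For segments
#' with multiple peaks the component count N is the peak count (capped at
#' `config$max_components`); for single-peak segments with sufficient
#' intensity variation N comes from the ordinal classifier (when supplied;
#' without a classifier, as in wide-field-only operation, N = 1); segments
#' with N > 1 are split by intensity-weighted k-means. Returns final
#' segments with intensity integrals filled in.
#'
#' @param image an [srrf_image()].
#' @param config an [analysis_config()].
#' @param classifier optional trained [train_component_classifier()] model.
#' @return segments tibble (stage `"final"`) with columns `label`,
#'   `parent_label`, `n_peaks`, `n_components`, `area_px`, `diameter_nm`,
#'   `x_nm`, `y_nm`, `J`, `normalized_integral`, `roi_id`, and list-columns
#'   `pixels`, `polygon`.
#' @export
segment_pipeline <- function(image, config = analysis_config(),
                             classifier = NULL) {
  mask <- binarize(image, mode = config$binarize_mode,
                   threshold_fraction = config$threshold_fraction,
                   window_px = config$adaptive_window_px,
                   offset = config$adaptive_offset)
  initial <- label_initial_segments(mask, image,
                                    min_area_px = config$min_segment_area_px)
  finalize_segments(initial, image, config, classifier)
}

#' Resolve initial segments into final single-EV segments
#'
#' The post-binarization half of [segment_pipeline()]; exposed separately so
#' that initial segments can be annotated (for classifier training) and
#' resolved in one flow.
#'
#' @param initial segments tibble from [label_initial_segments()].
#' @inheritParams segment_pipeline
#' @export
finalize_segments <- function(initial, image, config = analysis_config(),
                              classifier = NULL) {
  if (nrow(initial) == 0) {
    out <- empty_segments()
    out$parent_label <- integer(); out$n_peaks <- integer()
    out$n_components <- integer(); out$J <- double()
    out$normalized_integral <- double(); out$roi_id <- character()
    return(out)
  }
  mask <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
  for (i in seq_len(nrow(initial))) mask[initial$pixels[[i]]] <- TRUE
  background <- estimate_background(image, mask)

  pieces <- purrr::map(seq_len(nrow(initial)), function(i) {
    seg <- initial[i, ]
    patch <- laplacian_cubicroot(image, seg)
    peaks <- detect_peaks(patch, prominence = config$peak_prominence,
                          min_separation_px = config$peak_min_separation_px)
    np <- nrow(peaks)
    n_comp <- if (np > 1) {
      min(np, config$max_components)
    } else if (!is.null(classifier) &&
               variation_eligible(seg, image, config$cv_cutoff, background)) {
      predict_component_count(classifier,
                              extract_features(seg, image, background))
    } else {
      1L
    }
    finals <- if (n_comp > 1) {
      gp <- weighted_grid(seg, patch, image$pixel_size_nm,
                          config$grid_points_per_unit)
      split_segment_kmeans(seg, gp, n_comp, image,
                           seed = config$kmeans_seed + seg$label)
    } else {
      seg$stage <- "final"
      seg
    }
    finals$parent_label <- seg$label
    finals$n_peaks <- np
    finals$n_components <- as.integer(n_comp)
    finals
  })
  out <- bind_rows(pieces)
  ints <- purrr::map(seq_len(nrow(out)), function(i)
    segment_intensity_integral(out[i, ], image, background))
  out$J <- vapply(ints, `[[`, numeric(1), "J")
  out$normalized_integral <- vapply(ints, `[[`, numeric(1),
                                    "normalized_integral")
  out$roi_id <- image$roi_id
  out$label <- seq_len(nrow(out))
  out
}
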