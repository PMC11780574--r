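# Voronoi tessellation clustering of SMLM localization maps.
#
# EVs appear in SMLM data as dense clouds of localizations. Each
# localization's local density is estimated as the inverse of its Voronoi
# cell area (cells clipped to the ROI rectangle so border cells stay
# finite). Localizations denser than `density_factor` times the global
# ROI density (n / ROI area, the uniform expectation) form cluster cores:
# foreground points whose Voronoi cells share an edge are merged. The
# outermost localizations of a dense cloud have outward-reaching cells
# and fail the density cut, so each core then recruits boundary
# localizations adjacent (Delaunay) to at least two of its members.
# Molecule counts use all member localizations (molecules =
# localizations / alpha); area and polygon use the core cells only, so a
# border cell reaching into empty space never inflates the geometry. A
# cluster is a detected EV when it carries at least `min_molecules`
# molecules.

#' Per-localization Voronoi densities
#'
#' @param locs tibble with `x_nm`, `y_nm` columns (a localization map).
#' @param bounds ROI bounding rectangle `c(xmin, xmax, ymin, ymax)` in nm;
#'   defaults to the tight bounding box of the points.
#' @return numeric vector of local densities (nm^-2), one per input point,
#'   in input order: `density_i = 1 / area(Voronoi cell of point i)`.
#' @export
voronoi_densities <- function(locs, bounds = NULL) {
  tess <- voronoi_tessellation(locs, bounds)
  tess$density
}

# Full tessellation bundle shared by densities and clustering.
# Returns list(dd, density, areas, bounds, jittered x/y).
voronoi_tessellation <- function(locs, bounds = NULL) {
  x <- locs$x_nm; y <- locs$y_nm
  n <- length(x)
  if (n < 4) abort("voronoi tessellation needs at least 4 points")
  if (is.null(bounds)) bounds <- c(range(x), range(y))
  # coincident localizations are jittered deterministically by ~1e-3 nm so
  # the tessellation stays non-degenerate (three orders below localization
  # precision; no effect on any downstream quantity)
  key <- paste(x, y)
  dup <- duplicated(key)
  if (any(dup)) {
    k <- ave(seq_len(n), key, FUN = seq_along) - 1L
    x <- x + k * 1e-3
    y <- y + k * 1.37e-3
  }
  if (abs(shoelace_area(cbind(x, y)[grDevices::chull(cbind(x, y)), , drop = FALSE])) < 1e-9)
    abort("voronoi tessellation: degenerate geometry (all points collinear)")
  dd <- deldir::deldir(x, y, rw = bounds, suppressMsge = TRUE)
  # deldir preserves input order in $summary for non-duplicated input
  areas <- dd$summary$dir.area
  if (length(areas) != n)
    abort("voronoi tessellation: point set degenerated (unexpected duplicates)")
  list(dd = dd, density = 1 / areas, areas = areas, bounds = bounds,
       x = x, y = y)
}

#' Cluster SMLM localizations into detected EVs
#'
#' @inheritParams voronoi_densities
#' @param density_factor core threshold: a point joins a cluster core when
#'   its Voronoi density reaches this multiple of the global ROI density
#'   n / area(bounds); cores then recruit their boundary localizations
#'   (points adjacent to at least two core members).
#' @param min_molecules minimum molecule count (localizations / alpha) for a
#'   cluster to be reported as a detected EV (default 2.5).
#' @param alpha mean localizations per fluorescent reporter.
#' @param polygons compute outer-ring polygons of the clusters (list-column
#'   `polygon`); switch off for large maps where only counts are needed.
#' @return tibble with one row per detected cluster: `cluster_id`, `n_locs`
#'   and `molecules` over all member localizations (core + recruited
#'   boundary), `area_nm2` (sum of the core cells' areas), `diameter_nm`
#'   (equivalent-circle), `x_nm`, `y_nm` (centroid), plus list-columns
#'   `loc_indices` (indices into `locs`) and `polygon` (core outer ring).
#' @export
cluster_localizations <- function(locs, bounds = NULL, density_factor = 2,
                                  min_molecules = 2.5, alpha = 10,
                                  polygons = TRUE) {
  stopifnot_scalar_pos(density_factor, "density_factor")
  stopifnot_scalar_pos(alpha, "alpha")
  empty <- tibble(
    cluster_id = integer(), n_locs = integer(), molecules = double(),
    area_nm2 = double(), diameter_nm = double(), x_nm = double(),
    y_nm = double(), loc_indices = list(), polygon = list()
  )
  if (nrow(locs) < 4) return(empty)
  tess <- voronoi_tessellation(locs, bounds)
  rect <- tess$bounds
  global_density <- nrow(locs) / ((rect[2] - rect[1]) * (rect[4] - rect[3]))
  fg <- which(tess$density >= density_factor * global_density)
  if (length(fg) == 0) return(empty)

  # merge foreground points whose Voronoi cells share an edge: these are
  # exactly the Delaunay neighbours (deldir reports them in $delsgs).
  # Adjacency alone can bridge distant clusters through thin "sliver"
  # cells, so merging additionally requires the generating points to sit
  # closer than the spacing a point pair at the threshold density would
  # have (edge length <= 1 / sqrt(threshold density)).
  ds <- tess$dd$delsgs
  edge_cut <- 1 / sqrt(density_factor * global_density)
  short <- (ds$x1 - ds$x2)^2 + (ds$y1 - ds$y2)^2 <= edge_cut^2
  ds <- ds[short, , drop = FALSE]
  keep <- ds$ind1 %in% fg & ds$ind2 %in% fg
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ds$ind1[keep]),
               to = as.character(ds$ind2[keep])),
    directed = FALSE,
    vertices = data.frame(name = as.character(fg))
  )
  comp <- igraph::components(g)
  member_of <- split(as.integer(igraph::V(g)$name), comp$membership)

  # recruit boundary localizations: non-core points Delaunay-adjacent to
  # >= 2 members of the same core (the dense cloud's own periphery, whose
  # outward cells failed the density cut); assigned to the core with the
  # most adjacent members, ties to the lower component id
  comp_of <- integer(nrow(locs))
  for (ci in seq_along(member_of)) comp_of[member_of[[ci]]] <- ci
  cand <- tibble(
    p = c(ds$ind1, ds$ind2),
    core = comp_of[c(ds$ind2, ds$ind1)]
  )
  cand <- cand[comp_of[cand$p] == 0L & cand$core > 0L, ]
  attached <- list()
  if (nrow(cand) > 0) {
    tallies <- dplyr::count(cand, .data$p, .data$core)
    tallies <- tallies[tallies$n >= 2, ]
    tallies <- tallies[order(tallies$p, -tallies$n, tallies$core), ]
    tallies <- tallies[!duplicated(tallies$p), ]
    attached <- split(tallies$p, tallies$core)
  }

  rows <- purrr::imap(member_of, function(core, comp_id) {
    members <- sort(c(core, attached[[comp_id]]))
    m <- length(members) / alpha
    if (m < min_molecules) return(NULL)
    area <- sum(tess$areas[core])
    tibble(
      n_locs = length(members), molecules = m, area_nm2 = area,
      diameter_nm = cluster_diameter(area),
      x_nm = mean(tess$x[members]), y_nm = mean(tess$y[members]),
      loc_indices = list(members),
      polygon = list(if (polygons)
        cluster_outer_ring(tess$dd, core, tess$x, tess$y) else NULL)
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) return(empty)
  out <- bind_rows(rows)
  # deterministic ordering independent of component enumeration
  out <- arrange(out, .data$y_nm, .data$x_nm)
  mutate(out, cluster_id = row_number(), .before = 1)
}

# Outer boundary ring of the union of the member points' Voronoi cells.
# Uses the tessellation edge list: an edge belongs to the union boundary iff
# exactly one of its two generating points is a member. Cells truncated by
# the ROI rectangle contribute rectangle-border pieces that are not in the
# edge list; if the boundary then fails to close, fall back to the convex
# hull of the member cells' vertices.
cluster_outer_ring <- function(dd, members, x, y) {
  sgs <- dd$dirsgs
  in1 <- sgs$ind1 %in% members
  in2 <- sgs$ind2 %in% members
  bd <- sgs[xor(in1, in2), c("x1", "y1", "x2", "y2"), drop = FALSE]
  if (nrow(bd) >= 3) {
    rings <- chain_segments(as.matrix(bd))
    if (length(rings) > 0) {
      areas <- vapply(rings, function(r) abs(shoelace_area(r)), numeric(1))
      return(rings[[which.max(areas)]])
    }
  }
  # fallback: hull of all vertices of member cells (incl. rectangle corners)
  both <- sgs[in1 | in2, , drop = FALSE]
  pts <- unique(rbind(as.matrix(both[, c("x1", "y1")]),
                      as.matrix(both[, c("x2", "y2")])))
  if (nrow(pts) < 3) return(cbind(x[members], y[members]))
  pts[grDevices::chull(pts), , drop = FALSE]
}

#' Equivalent-circle diameter of a cluster area
#'
#' @param area_nm2 cluster area in nm^2 (scalar or vector).
#' @return diameter in nm, `2 * sqrt(area / pi)`.
#' @export
cluster_diameter <- function(area_nm2) {
  if (any(area_nm2 <= 0)) abort("cluster_diameter: area must be > 0")
  2 * sqrt(area_nm2 / pi)
}

#' EV surface density of an ROI
#'
#' @param n_detected number of detected EVs (or a clusters/segments tibble,
#'   in which case its row count is used).
#' @param roi_area_um2 ROI area in um^2.
#' @return detected EVs per um^2.
#' @export
surface_density <- function(n_detected, roi_area_um2) {
  stopifnot_scalar_pos(roi_area_um2, "roi_area_um2")
  if (is.data.frame(n_detected)) n_detected <- nrow(n_detected)
  n_detected / roi_area_um2
}
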