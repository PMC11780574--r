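# On-disk artifacts and the shared coordinate convention.
#
# One geometric convention is used throughout the package: 0-based pixel
# indices with the origin at the image top-left, physical coordinates in nm,
# and the centre of pixel (row, col) at x = (col + 0.5) * pixel_size_nm,
# y = (row + 0.5) * pixel_size_nm. In R's 1-based matrix indexing that is
# x = (col - 0.5) * pixel_size_nm and likewise for y.

EV_CHANNELS <- c("red_640", "red_630", "green_488", "green_475")

#' Construct an SRRF image object
#'
#' A light wrapper around a numeric intensity matrix carrying the physical
#' pixel size, channel tag and ROI identity. Intensities must be finite and
#' non-negative.
#'
#' @param pixels numeric matrix of intensities, `[row, col]`, row 1 at top.
#' @param pixel_size_nm physical pixel edge length in nm.
#' @param channel one of `"red_640"`, `"red_630"`, `"green_488"`, `"green_475"`.
#' @param roi_id ROI identifier string.
#' @param roi_area_um2 ROI area in um^2; defaults to the image extent.
#' @return an object of class `srrf_image`.
#' @export
srrf_image <- function(pixels, pixel_size_nm, channel = "red_640",
                       roi_id = "roi1", roi_area_um2 = NULL) {
  stopifnot(is.matrix(pixels))
  if (any(!is.finite(pixels)) || any(pixels < 0))
    abort("srrf_image: intensities must be finite and >= 0")
  stopifnot_scalar_pos(pixel_size_nm, "pixel_size_nm")
  channel <- match.arg(channel, EV_CHANNELS)
  extent_um2 <- nrow(pixels) * ncol(pixels) * pixel_size_nm^2 / 1e6
  roi_area_um2 <- roi_area_um2 %||% extent_um2
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm, channel = channel,
         roi_id = roi_id, roi_area_um2 = roi_area_um2),
    class = "srrf_image"
  )
}

#' @export
print.srrf_image <- function(x, ...) {
  cat(sprintf("<srrf_image> %d x %d px @ %.3g nm/px, channel %s, ROI %s (%.1f um^2)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$channel,
              x$roi_id, x$roi_area_um2))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.srrf_image <- function(x) dim(x$pixels)

#' Physical bounds of an image, nm
#' @param image an `srrf_image`.
#' @return numeric vector `c(xmin, xmax, ymin, ymax)` in nm.
#' @export
image_bounds_nm <- function(image) {
  c(0, ncol(image$pixels) * image$pixel_size_nm,
    0, nrow(image$pixels) * image$pixel_size_nm)
}

#' Pixel centre coordinates in nm
#' @keywords internal
pixel_center_nm <- function(row, col, pixel_size_nm) {
  cbind(x = (col - 0.5) * pixel_size_nm, y = (row - 0.5) * pixel_size_nm)
}

#' Map nm coordinates to containing pixel indices (1-based row/col)
#' @keywords internal
nm_to_pixel <- function(x, y, pixel_size_nm, dims) {
  col <- pmin(pmax(floor(x / pixel_size_nm) + 1L, 1L), dims[2])
  row <- pmin(pmax(floor(y / pixel_size_nm) + 1L, 1L), dims[1])
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Load a reconstructed SRRF image from a grayscale TIFF
#'
#' @inheritParams srrf_image
#' @param path path to a single-plane grayscale TIFF.
#' @return an [srrf_image()].
#' @export
load_srrf_image <- function(path, pixel_size_nm, channel = "red_640",
                            roi_id = NULL) {
  px <- read_tiff_gray(path)
  srrf_image(px, pixel_size_nm = pixel_size_nm, channel = channel,
             roi_id = roi_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Save an SRRF image as a 32-bit float grayscale TIFF
#' @param image an [srrf_image()].
#' @param path output path.
#' @param bits sample depth (32 float, 16 or 8 unsigned).
#' @export
save_srrf_image <- function(image, path, bits = 32) {
  write_tiff_gray(image$pixels, path, bits = bits)
}

#' Load an SMLM localization table
#'
#' Reads a comma-separated localization export with a named header. The
#' columns `x`, `y` (nm), `frame` and `photons` are matched by name
#' (case-insensitively; `x [nm]` / `x_nm` spellings accepted), so column
#' order does not matter and extra columns are ignored.
#'
#' @param path CSV path.
#' @param channel acquisition channel tag.
#' @param roi_id ROI identifier.
#' @return a tibble with columns `x_nm`, `y_nm`, `frame`, `photons`,
#'   `channel`, `roi_id`; zero rows for a header-only file.
#' @export
load_localizations <- function(path, channel = "red_640", roi_id = "roi1") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  norm <- gsub("[^a-z]", "", tolower(names(df)))
  pick <- function(cands, what) {
    hit <- which(norm %in% cands)
    if (length(hit) == 0)
      abort(paste0("localization table is missing required column: ", what))
    df[[hit[1]]]
  }
  x <- pick(c("x", "xnm"), "x")
  y <- pick(c("y", "ynm"), "y")
  frame <- pick(c("frame", "frameindex"), "frame")
  photons <- pick(c("photons", "photoncount", "intensityphotons"), "photons")
  for (v in list(x = x, y = y)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad) > 0)
      abort(paste0("non-numeric coordinate in localization table at data row ",
                   bad[1]))
  }
  tibble(
    x_nm = as.numeric(x), y_nm = as.numeric(y),
    frame = as.integer(frame), photons = as.numeric(photons),
    channel = channel, roi_id = roi_id
  )
}

#' Write an SMLM localization table
#' @param locs tibble as returned by [load_localizations()].
#' @param path CSV path.
#' @export
write_localizations <- function(locs, path) {
  readr::write_csv(locs[, c("x_nm", "y_nm", "frame", "photons")], path)
  invisible(path)
}

EV_TABLE_COLS <- c("roi_id", "x_nm", "y_nm", "diameter_nm", "tspan_count",
                   "method", "positive_green", "positive_rna")

#' Write a quantified-EV table
#'
#' One row per EV: ROI id, centroid (nm), calibrated diameter, detected
#' TSPAN molecule count, provenance method tag
#' (`smlm` / `srrf_regression` / `srrf_sami` / `srrf_sensitivity`) and
#' cross-channel positivity flags.
#'
#' @param records tibble of EV records.
#' @param path CSV path.
#' @export
write_ev_table <- function(records, path) {
  if (nrow(records) == 0) {
    records <- tibble(
      roi_id = character(), x_nm = double(), y_nm = double(),
      diameter_nm = double(), tspan_count = double(), method = character(),
      positive_green = logical(), positive_rna = logical()
    )
  }
  for (col in EV_TABLE_COLS) if (is.null(records[[col]])) records[[col]] <- NA
  readr::write_csv(records[, EV_TABLE_COLS], path)
  invisible(path)
}

#' Read a quantified-EV table written by [write_ev_table()]
#' @param path CSV path.
#' @export
read_ev_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    roi_id = readr::col_character(),
                    method = readr::col_character(),
                    positive_green = readr::col_logical(),
                    positive_rna = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}

#' Analysis configuration
#'
#' Houses every tunable of the quantification pipeline: binarization mode and
#' threshold, segment size and intensity-variation cutoffs, peak-detection
#' parameters, k-means seed, Voronoi clustering factor, the minimum molecule
#' count defining an SMLM cluster (default 2.5), the localizations-per-
#' fluorophore constant alpha, and the colocalization overlap rule.
#'
#' @param binarize_mode `"fraction_of_max"` (threshold at a fraction of the
#'   maximum image intensity) or `"adaptive"` (local-mean window).
#' @param threshold_fraction fraction of the maximum image intensity used as
#'   the binarization cutoff; default 0.005 (0.50% of maximum).
#' @param adaptive_window_px odd window width for adaptive binarization;
#'   must be much wider than the PSF so a spot cannot inflate its own
#'   local threshold.
#' @param adaptive_offset intensity offset above the local mean required for
#'   foreground in adaptive mode; `NULL` picks 4x the image MAD at call time.
#' @param min_segment_area_px minimum initial-segment area, px.
#' @param peak_prominence relative prominence cutoff (fraction of the
#'   transformed patch's value range) for peak detection.
#' @param peak_min_separation_px minimum pairwise peak separation, px.
#' @param cv_cutoff intensity coefficient-of-variation cutoff below which an
#'   initial segment is not considered for classifier-driven splitting.
#' @param max_components cap on the component count taken from peak counting.
#' @param grid_points_per_unit grid localizations per unit transformed
#'   intensity per pixel for k-means splitting.
#' @param kmeans_seed base seed for the k-means splitting restarts.
#' @param density_factor Voronoi foreground threshold as a multiple of the
#'   global ROI localization density.
#' @param min_molecules minimum detected molecules defining an SMLM cluster.
#' @param alpha mean SMLM localizations per fluorescent reporter.
#' @param min_overlap_fraction colocalization rule: intersection over the
#'   smaller area must reach this fraction.
#' @return an object of class `ev_analysis_config` (a named list).
#' @export
analysis_config <- function(binarize_mode = c("fraction_of_max", "adaptive"),
                            threshold_fraction = 0.005,
                            adaptive_window_px = 31L,
                            adaptive_offset = NULL,
                            min_segment_area_px = 4L,
                            peak_prominence = 0.2,
                            peak_min_separation_px = 2L,
                            cv_cutoff = 0.2,
                            max_components = 5L,
                            grid_points_per_unit = 10,
                            kmeans_seed = 1L,
                            density_factor = 2,
                            min_molecules = 2.5,
                            alpha = 10,
                            min_overlap_fraction = 0.25) {
  cfg <- list(
    binarize_mode = match.arg(binarize_mode),
    threshold_fraction = threshold_fraction,
    adaptive_window_px = as.integer(adaptive_window_px),
    adaptive_offset = adaptive_offset,
    min_segment_area_px = as.integer(min_segment_area_px),
    peak_prominence = peak_prominence,
    peak_min_separation_px = as.integer(peak_min_separation_px),
    cv_cutoff = cv_cutoff,
    max_components = as.integer(max_components),
    grid_points_per_unit = grid_points_per_unit,
    kmeans_seed = as.integer(kmeans_seed),
    density_factor = density_factor,
    min_molecules = min_molecules,
    alpha = alpha,
    min_overlap_fraction = min_overlap_fraction
  )
  validate_analysis_config(cfg)
  structure(cfg, class = "ev_analysis_config")
}

validate_analysis_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("analysis_config: ", msg))
  chk(cfg$threshold_fraction > 0 && cfg$threshold_fraction < 1,
      "threshold_fraction must be in (0, 1)")
  chk(cfg$min_segment_area_px >= 1, "min_segment_area_px must be >= 1")
  chk(cfg$peak_prominence >= 0, "peak_prominence must be >= 0")
  chk(cfg$cv_cutoff >= 0, "cv_cutoff must be >= 0")
  chk(cfg$density_factor > 0, "density_factor must be > 0")
  chk(cfg$min_molecules >= 0, "min_molecules must be >= 0")
  chk(cfg$alpha > 0, "alpha must be > 0")
  chk(cfg$min_overlap_fraction > 0 && cfg$min_overlap_fraction <= 1,
      "min_overlap_fraction must be in (0, 1]")
  invisible(cfg)
}

#' Write / read an analysis configuration as YAML
#' @param cfg an [analysis_config()] object.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw[!vapply(raw, is.null, logical(1))])
}
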