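# Per-ROI summaries and distribution exports. The ROI is the unit of
# replication: all group statistics are means of per-ROI means, reported
# as mean +- SEM across ROIs.

#' Summarize EV records per ROI
#'
#' @param ev_records EV-record tibble (one row per quantified EV).
#' @param roi_area_um2 ROI area in um^2 (single value or named vector by
#'   ROI id).
#' @return tibble with one row per ROI: `n_evs`, `surface_density_per_um2`,
#'   `mean_diameter_nm`, `mean_tspan_count`, and `positivity_fraction`
#'   (mean of `positive_green` where present).
#' @export
summarize_rois <- function(ev_records, roi_area_um2) {
  if (nrow(ev_records) == 0) {
    return(tibble(roi_id = character(), n_evs = integer(),
                  surface_density_per_um2 = double(),
                  mean_diameter_nm = double(), mean_tspan_count = double(),
                  positivity_fraction = double()))
  }
  area_of <- function(roi) {
    if (!is.null(names(roi_area_um2))) unname(roi_area_um2[roi])
    else roi_area_um2
  }
  has_green <- "positive_green" %in% names(ev_records)
  ev_records |>
    group_by(.data$roi_id) |>
    summarise(
      n_evs = n(),
      surface_density_per_um2 = n() / area_of(dplyr::cur_group()$roi_id),
      mean_diameter_nm = mean(.data$diameter_nm),
      mean_tspan_count = mean(.data$tspan_count),
      positivity_fraction = if (has_green) mean(.data$positive_green)
        else NA_real_,
      .groups = "drop"
    )
}

#' Grand summary across ROIs (mean +- SEM of per-ROI means)
#'
#' @param roi_summaries tibble from [summarize_rois()].
#' @return tibble with one row per metric: `mean`, `sem`, `n_rois`.
#' @export
grand_summary <- function(roi_summaries) {
  metrics <- c("surface_density_per_um2", "mean_diameter_nm",
               "mean_tspan_count", "positivity_fraction")
  out <- purrr::map(metrics, function(m) {
    v <- roi_summaries[[m]]
    v <- v[is.finite(v)]
    tibble(metric = m,
           mean = if (length(v)) mean(v) else NA_real_,
           sem = if (length(v) > 1) sem(v) else NA_real_,
           n_rois = length(v))
  })
  bind_rows(out)
}

#' Export a binned distribution of an EV metric
#'
#' @param ev_records EV-record tibble.
#' @param metric column to bin (`"diameter_nm"` or `"tspan_count"`).
#' @param bin_edges increasing numeric vector of bin edges; values outside
#'   the range are counted in the outermost bins so the counts always sum
#'   to the record count.
#' @return tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
histogram_export <- function(ev_records, metric, bin_edges) {
  if (!metric %in% names(ev_records))
    abort(paste0("histogram_export: unknown metric `", metric, "`"))
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  v <- ev_records[[metric]]
  v <- pmin(pmax(v, bin_edges[1]), bin_edges[length(bin_edges)])
  b <- if (length(v)) {
    table(cut(v, bin_edges, include.lowest = TRUE, right = FALSE,
              labels = FALSE))
  } else NULL
  counts <- integer(length(bin_edges) - 1)
  if (!is.null(b)) counts[as.integer(names(b))] <- as.integer(b)
  tibble(bin_lo = head(bin_edges, -1), bin_hi = tail(bin_edges, -1),
         count = counts)
}
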