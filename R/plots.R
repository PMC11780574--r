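# ggplot2 displays of the main result types.

#' Plot segment and cluster outlines over an SRRF image
#'
#' @param image an [srrf_image()].
#' @param segments optional segments tibble (outlines drawn in blue).
#' @param clusters optional clusters tibble (outlines drawn in red).
#' @param trim_quantile upper display quantile for the intensity scale.
#' @return a ggplot object (x/y in nm, y increasing downwards as in the
#'   image).
#' @export
plot_roi <- function(image, segments = NULL, clusters = NULL,
                     trim_quantile = 0.999) {
  px <- image$pixels
  df <- expand.grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$x <- (df$col - 0.5) * image$pixel_size_nm
  df$y <- (df$row - 0.5) * image$pixel_size_nm
  df$intensity <- pmin(px[cbind(df$row, df$col)],
                       stats::quantile(px, trim_quantile))
  ring_df <- function(tab, what) {
    polys <- purrr::compact(tab$polygon)
    bind_rows(purrr::imap(polys, function(p, i)
      tibble(x = p[, 1], y = p[, 2], id = paste0(what, i), what = what)))
  }
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "I") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    g <- g + ggplot2::geom_path(
      data = ring_df(segments, "segment"),
      ggplot2::aes(group = .data$id), colour = "deepskyblue", linewidth = 0.3)
  }
  if (!is.null(clusters) && nrow(clusters) > 0) {
    g <- g + ggplot2::geom_path(
      data = ring_df(clusters, "cluster"),
      ggplot2::aes(group = .data$id), colour = "red", linewidth = 0.3)
  }
  g
}

#' @exportS3Method ggplot2::autoplot
autoplot.ev_linear_cal <- function(object, data = NULL, ...) {
  g <- ggplot2::ggplot()
  if (!is.null(data)) {
    g <- g + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$x, y = .data$y),
      alpha = 0.3, size = 0.6)
    xr <- range(if (object$transform == "sqrt") sqrt(data$x) else data$x)
  } else xr <- c(0, 1)
  line <- tibble(tx = seq(xr[1], xr[2], length.out = 50))
  line$y <- object$intercept + object$slope * line$tx
  g + ggplot2::geom_line(data = line,
                         ggplot2::aes(x = .data$tx, y = .data$y),
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = if (object$transform == "sqrt") "sqrt(input)" else "input",
      y = object$target,
      title = sprintf("linear calibration, r = %.3f (n = %d)", object$r,
                      object$n_points)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ev_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$percent)) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%\n(%d)", .data$percent, .data$count))) +
    ggplot2::scale_y_reverse(breaks = unique(df$true)) +
    ggplot2::scale_x_continuous(breaks = unique(df$predicted)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted component count",
                  y = "true component count") +
    ggplot2::theme_minimal()
}

#' Histogram of an EV metric per quantification method
#'
#' @param ev_records EV-record tibble (may mix `method` provenances).
#' @param metric `"diameter_nm"` or `"tspan_count"`.
#' @param binwidth histogram bin width.
#' @export
plot_ev_distribution <- function(ev_records, metric = "diameter_nm",
                                 binwidth = NULL) {
  ggplot2::ggplot(ev_records,
                  ggplot2::aes(x = .data[[metric]], fill = .data$method)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.5, bins = if (is.null(binwidth)) 30
                            else NULL) +
    ggplot2::labs(x = metric, y = "EVs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
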