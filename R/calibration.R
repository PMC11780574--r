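# Calibration of SRRF segment geometry and intensity into physical EV
# diameter and detected TSPAN molecule counts.
#
# Three schemes, mirroring how correlative data, single-fluorophore
# surfaces, and reference EVs are each used:
#   * regression  - ordinary least squares of the SMLM-measured quantity on
#     the SRRF segment quantity (diameter on diameter; molecule count on
#     the square root of the normalized intensity integral);
#   * sami        - molecule counts as M_EV = J / <J_1>, dividing a
#     segment's absolute intensity integral by the mean single-fluorophore
#     integral measured on sparse antibody surfaces;
#   * sensitivity - per-ROI mean SRRF metrics divided by a dimensionless
#     sensitivity (mean over ROIs of SRRF metric / reference-EV value),
#     validated by k-fold cross-validation over ROIs.

#' Fit a linear calibration
#'
#' Ordinary least squares of `y` on `T(x)` with intercept, where the input
#' transform `T` is identity or square root (content calibrations perform
#' better with a square-root input feature). `r` is the Pearson correlation
#' of `(T(x), y)`.
#'
#' @param x predictor (SRRF-measured quantity).
#' @param y response (SMLM-measured quantity).
#' @param transform `"identity"` or `"sqrt"` applied to `x` before the fit.
#' @param target what the calibration predicts: `"diameter"` or
#'   `"content"`; controls which segment column [apply_calibration()] feeds
#'   through it.
#' @return an object of class `ev_linear_cal`.
#' @export
fit_linear <- function(x, y, transform = c("identity", "sqrt"),
                       target = c("diameter", "content")) {
  transform <- match.arg(transform)
  target <- match.arg(target)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("fit_linear: need at least 3 points")
  tx <- if (transform == "sqrt") sqrt(x) else x
  if (stats::sd(tx) == 0)
    abort("fit_linear: zero variance in the (transformed) predictor")
  fit <- stats::lm(y ~ tx)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = stats::cor(tx, y), n_points = length(x),
         transform = transform, target = target),
    class = "ev_linear_cal"
  )
}

#' @export
predict.ev_linear_cal <- function(object, x, ...) {
  tx <- if (object$transform == "sqrt") sqrt(x) else x
  object$intercept + object$slope * tx
}

#' @export
print.ev_linear_cal <- function(x, ...) {
  cat(sprintf(
    "<ev_linear_cal> %s: y = %.4g + %.4g * %s(x), r = %.3f, n = %d\n",
    x$target, x$intercept, x$slope,
    if (x$transform == "sqrt") "sqrt" else "", x$r, x$n_points))
  invisible(x)
}

#' @exportS3Method
tidy.ev_linear_cal <- function(x, ...) {
  tibble(term = c("(Intercept)", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method
glance.ev_linear_cal <- function(x, ...) {
  tibble(r = x$r, r.squared = x$r^2, n = x$n_points,
         transform = x$transform, target = x$target)
}

#' Single-fluorophore intensity calibration from sparse antibody surfaces
#'
#' On a surface so sparse that every diffraction-limited spot is a single
#' fluorescent reporter, the mean background-subtracted segment intensity
#' integral estimates the per-fluorophore integral `<J_1>`. Averaging is
#' per ROI first, then across ROIs.
#'
#' @param segments segments tibble with columns `roi_id` and `J` (one row
#'   per detected single-fluorophore spot; typically from
#'   [segment_pipeline()] with adaptive binarization).
#' @return an object of class `ev_sami_cal` with the grand mean `mean_j1`,
#'   a `per_roi` tibble, and `n_rois`.
#' @export
sami_calibrate <- function(segments) {
  if (nrow(segments) == 0)
    abort("sami_calibrate: no single-fluorophore segments supplied")
  per_roi <- segments |>
    group_by(.data$roi_id) |>
    summarise(mean_j1 = mean(.data$J), n_spots = n(), .groups = "drop")
  structure(
    list(mean_j1 = mean(per_roi$mean_j1), per_roi = per_roi,
         n_rois = nrow(per_roi)),
    class = "ev_sami_cal"
  )
}

#' @export
print.ev_sami_cal <- function(x, ...) {
  cat(sprintf("<ev_sami_cal> <J_1> = %.4g over %d ROI(s), %d spots\n",
              x$mean_j1, x$n_rois, sum(x$per_roi$n_spots)))
  invisible(x)
}

#' @exportS3Method
glance.ev_sami_cal <- function(x, ...) {
  tibble(mean_j1 = x$mean_j1, n_rois = x$n_rois,
         n_spots = sum(x$per_roi$n_spots))
}

#' Molecules per EV from the single-fluorophore calibration
#'
#' `M_EV = J / <J_1>`: the ratio of a segment's absolute intensity integral
#' to the mean single-fluorophore integral. Exactly scale-free: rescaling
#' all intensities by a constant leaves every `M_EV` unchanged.
#'
#' @param J segment intensity integral(s).
#' @param sami an [sami_calibrate()] object.
#' @return molecule count(s).
#' @export
tspan_from_sami <- function(J, sami) {
  if (sami$mean_j1 <= 0) abort("tspan_from_sami: <J_1> must be > 0")
  J / sami$mean_j1
}

#' Reference-EV sensitivity calibration
#'
#' Divides the mean SRRF diameter per ROI by the reference mean EV size and
#' the mean square-root intensity integral per ROI by the reference mean
#' molecule content; the sensitivities (dimensionless slopes) are the means
#' of the per-ROI ratios. Applying the calibration divides an SRRF metric
#' by its sensitivity.
#'
#' @param roi_means tibble with one row per ROI: `mean_diameter_nm` and/or
#'   `mean_sqrt_integral` columns.
#' @param reference_diameter_nm reference mean EV diameter (nm).
#' @param reference_content reference mean molecule count per EV.
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return an object of class `ev_sensitivity_cal`.
#' @export
sensitivity_calibrate <- function(roi_means, reference_diameter_nm,
                                  reference_content = NULL,
                                  method = c("mean_of_ratios",
                                             "ratio_of_means")) {
  method <- match.arg(method)
  stopifnot_scalar_pos(reference_diameter_nm, "reference_diameter_nm")
  agg <- function(v, ref) {
    if (method == "mean_of_ratios") mean(v / ref) else mean(v) / ref
  }
  size_sens <- agg(roi_means$mean_diameter_nm, reference_diameter_nm)
  content_sens <- if (!is.null(reference_content) &&
                      !is.null(roi_means$mean_sqrt_integral)) {
    stopifnot_scalar_pos(reference_content, "reference_content")
    agg(roi_means$mean_sqrt_integral, reference_content)
  } else NA_real_
  structure(
    list(size_sensitivity = size_sens, content_sensitivity = content_sens,
         reference_diameter_nm = reference_diameter_nm,
         reference_content = reference_content, method = method,
         n_rois = nrow(roi_means)),
    class = "ev_sensitivity_cal"
  )
}

#' @export
print.ev_sensitivity_cal <- function(x, ...) {
  cat(sprintf(
    "<ev_sensitivity_cal> size %.4f (ref %.4g nm)%s; %s over %d ROIs\n",
    x$size_sensitivity, x$reference_diameter_nm,
    if (is.na(x$content_sensitivity)) ""
    else sprintf(", content %.4f (ref %.4g molecules)",
                 x$content_sensitivity, x$reference_content),
    x$method, x$n_rois))
  invisible(x)
}

#' @exportS3Method
glance.ev_sensitivity_cal <- function(x, ...) {
  tibble(size_sensitivity = x$size_sensitivity,
         content_sensitivity = x$content_sensitivity,
         reference_diameter_nm = x$reference_diameter_nm,
         reference_content = x$reference_content %||% NA_real_,
         method = x$method, n_rois = x$n_rois)
}

#' k-fold cross-validation of the sensitivity calibration
#'
#' Randomly partitions the ROIs into `k` near-equal folds (seeded), fits
#' the sensitivity on the other `k - 1` folds and applies it to the
#' held-out fold, reporting per-fold calibrated mean diameter and content.
#'
#' @param roi_means as in [sensitivity_calibrate()].
#' @param k number of folds (>= 2, <= number of ROIs).
#' @param seed RNG seed for the fold assignment.
#' @inheritParams sensitivity_calibrate
#' @return list with `folds` (tibble: fold id per ROI row) and `summary`
#'   (tibble per fold: `n_rois`, `calibrated_mean_diameter_nm`,
#'   `calibrated_mean_content`).
#' @export
crossvalidate_sensitivity <- function(roi_means, k = 5L, seed = 1L,
                                      reference_diameter_nm,
                                      reference_content = NULL,
                                      method = "mean_of_ratios") {
  n <- nrow(roi_means)
  k <- as.integer(k)
  if (k < 2) abort("crossvalidate_sensitivity: k must be >= 2")
  if (k > n) abort("crossvalidate_sensitivity: k exceeds the number of ROIs")
  # near-equal fold sizes: n %% k folds get one extra ROI
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- withr::with_seed(as.integer(seed),
                           sample(rep(seq_len(k), times = sizes)))
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- roi_means[fold != f, , drop = FALSE]
    test <- roi_means[fold == f, , drop = FALSE]
    sens <- sensitivity_calibrate(train, reference_diameter_nm,
                                  reference_content, method)
    tibble(
      fold = f, n_rois = nrow(test),
      calibrated_mean_diameter_nm =
        mean(test$mean_diameter_nm) / sens$size_sensitivity,
      calibrated_mean_content = if (is.na(sens$content_sensitivity))
        NA_real_ else mean(test$mean_sqrt_integral) / sens$content_sensitivity
    )
  })
  list(folds = tibble(roi = seq_len(n), fold = fold),
       summary = bind_rows(per_fold))
}

#' Convert final segments into quantified EV records
#'
#' Applies a size calibration and/or a content calibration to every final
#' segment, producing one EV record per segment. The provenance tag follows
#' the content model (`srrf_sami` for single-fluorophore, `srrf_sensitivity`
#' for reference-EV sensitivity, otherwise `srrf_regression`).
#'
#' @param segments final segments tibble from [segment_pipeline()].
#' @param size [fit_linear()] (target `"diameter"`, fed the segment
#'   diameter), [sensitivity_calibrate()], or `NULL` (raw segment diameter).
#' @param content [fit_linear()] (target `"content"`, fed the normalized
#'   intensity integral through its sqrt transform),
#'   [sami_calibrate()] (fed the absolute integral J),
#'   [sensitivity_calibrate()], or `NULL`.
#' @return EV-record tibble: `roi_id`, `x_nm`, `y_nm`, `diameter_nm`,
#'   `tspan_count`, `method`.
#' @export
apply_calibration <- function(segments, size = NULL, content = NULL) {
  if (nrow(segments) == 0) {
    return(tibble(roi_id = character(), x_nm = double(), y_nm = double(),
                  diameter_nm = double(), tspan_count = double(),
                  method = character()))
  }
  diameter <- if (is.null(size)) {
    segments$diameter_nm
  } else if (inherits(size, "ev_linear_cal")) {
    predict(size, segments$diameter_nm)
  } else if (inherits(size, "ev_sensitivity_cal")) {
    segments$diameter_nm / size$size_sensitivity
  } else abort("apply_calibration: unsupported size model")
  tspan <- if (is.null(content)) {
    NA_real_
  } else if (inherits(content, "ev_linear_cal")) {
    predict(content, segments$normalized_integral)
  } else if (inherits(content, "ev_sami_cal")) {
    tspan_from_sami(segments$J, content)
  } else if (inherits(content, "ev_sensitivity_cal")) {
    sqrt(segments$normalized_integral) / content$content_sensitivity
  } else abort("apply_calibration: unsupported content model")
  method <- if (inherits(content, "ev_sami_cal")) "srrf_sami"
            else if (inherits(content, "ev_sensitivity_cal") ||
                     inherits(size, "ev_sensitivity_cal")) "srrf_sensitivity"
            else "srrf_regression"
  tibble(
    roi_id = segments$roi_id %||% "roi1",
    x_nm = segments$x_nm, y_nm = segments$y_nm,
    diameter_nm = pmax(diameter, 0),
    tspan_count = pmax(tspan, 0),
    method = method
  )
}

#' EV records straight from SMLM clusters
#'
#' @param clusters clusters tibble from [cluster_localizations()].
#' @param roi_id ROI identifier.
#' @return EV-record tibble with method `"smlm"`.
#' @export
smlm_ev_records <- function(clusters, roi_id = "roi1") {
  tibble(
    roi_id = roi_id,
    x_nm = clusters$x_nm, y_nm = clusters$y_nm,
    diameter_nm = clusters$diameter_nm,
    tspan_count = clusters$molecules,
    method = "smlm"
  )
}
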