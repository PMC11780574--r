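# Ordinal classification of initial-segment component counts.
#
# A single-peak initial segment may still cover 1, 2 or 3 EVs. Component
# counts are ordered, so the ordinal problem is decomposed into two
# cumulative binary questions (Frank-Hall scheme): "more than one
# component?" and "more than two?". Each is answered by a soft-margin
# support vector machine with a Gaussian kernel on the 11 standardized
# segment features; the exact dual quadratic program is solved with
# quadprog, which makes training deterministic given the data.

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# Soft-margin SVM dual:
#   max  sum(a) - 1/2 a' (yy' * K) a   s.t. y'a = 0, 0 <= a <= C
svm_fit_qp <- function(X, y, C = 10, gamma = 1 / ncol(X)) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8  # PD jitter for the QP solver
  A <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, bvec, meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  sv <- which(a > 1e-6)
  coefs <- a[sv] * y[sv]
  # bias from margin support vectors (0 < a < C); fall back to all SVs
  margin <- sv[a[sv] < C - 1e-6]
  if (length(margin) == 0) margin <- sv
  f0 <- K[margin, sv, drop = FALSE] %*% coefs
  b <- mean(y[margin] - f0)
  list(sv_x = X[sv, , drop = FALSE], coefs = coefs, b = b, gamma = gamma,
       C = C, n_sv = length(sv))
}

svm_decision <- function(model, X) {
  drop(rbf_kernel(X, model$sv_x, model$gamma) %*% model$coefs + model$b)
}

FEATURE_NAMES <- c("area_px", "perimeter_px", "equiv_diameter_px",
                   "eccentricity", "solidity", "axis_ratio",
                   "max_intensity", "mean_intensity", "cv_intensity",
                   "intensity_integral", "hog_dispersion")

#' Train the ordinal component-count classifier
#'
#' @param features data frame of segment features ([extract_features()]
#'   rows; the 11 canonical columns are used).
#' @param true_n integer vector of true component counts (from SMLM or
#'   generator annotation); values above 3 are pooled into class 3.
#' @param C soft-margin cost.
#' @param gamma Gaussian kernel width on standardized features; default
#'   1 / (number of features).
#' @return an object of class `ev_component_classifier`.
#' @export
train_component_classifier <- function(features, true_n, C = 10,
                                       gamma = NULL) {
  X <- as.matrix(features[, FEATURE_NAMES])
  stopifnot(nrow(X) == length(true_n))
  true_n <- pmin(pmax(as.integer(true_n), 1L), 3L)
  if (length(unique(true_n)) < 2)
    abort(paste0("training set contains a single class (N = ", true_n[1],
                 "); widen the training data to cover several component",
                 " counts"))
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  sigma[sigma == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  gamma <- gamma %||% (1 / ncol(Z))
  m1 <- svm_fit_qp(Z, ifelse(true_n > 1, 1, -1), C = C, gamma = gamma)
  m2 <- if (any(true_n > 2))
    svm_fit_qp(Z, ifelse(true_n > 2, 1, -1), C = C, gamma = gamma)
  else NULL
  structure(
    list(mu = mu, sigma = sigma, gt1 = m1, gt2 = m2, C = C, gamma = gamma,
         n_train = nrow(Z), class_counts = table(true_n)),
    class = "ev_component_classifier"
  )
}

#' Predict segment component counts (1, 2 or 3)
#'
#' Ordinal decode of the two cumulative binary decisions:
#' `N = 1 + [f1 > 0] + [f1 > 0 and f2 > 0]`, which is monotone by
#' construction (a positive "more than two" answer can never yield N = 1).
#'
#' @param classifier a trained [train_component_classifier()] model.
#' @param features data frame of segment features (one row per segment).
#' @return integer vector of predicted component counts.
#' @export
predict_component_count <- function(classifier, features) {
  X <- as.matrix(features[, FEATURE_NAMES])
  Z <- sweep(sweep(X, 2, classifier$mu), 2, classifier$sigma, "/")
  f1 <- svm_decision(classifier$gt1, Z)
  gt1 <- f1 > 0
  if (!is.null(classifier$gt2)) {
    gt2 <- svm_decision(classifier$gt2, Z) > 0
  } else {
    gt2 <- rep(FALSE, nrow(Z))
  }
  as.integer(1L + gt1 + (gt1 & gt2))
}

#' @export
print.ev_component_classifier <- function(x, ...) {
  cat(sprintf(
    "<ev_component_classifier> Gaussian-kernel ordinal SVM (C = %g, gamma = %.3g)\n",
    x$C, x$gamma))
  cat(sprintf("  trained on %d segments; class counts: %s\n", x$n_train,
              paste(names(x$class_counts), as.integer(x$class_counts),
                    sep = ":", collapse = ", ")))
  cat(sprintf("  support vectors: N>1 model %d%s\n", x$gt1$n_sv,
              if (is.null(x$gt2)) " (no N>2 model: no class-3 examples)"
              else sprintf(", N>2 model %d", x$gt2$n_sv)))
  invisible(x)
}

#' @exportS3Method
glance.ev_component_classifier <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_classes = length(x$class_counts),
    C = x$C, gamma = x$gamma,
    n_sv_gt1 = x$gt1$n_sv,
    n_sv_gt2 = if (is.null(x$gt2)) NA_integer_ else x$gt2$n_sv
  )
}
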