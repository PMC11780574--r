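# Linear, single-fluorophore, and sensitivity calibrations.

test_that("exact linear relations are fitted exactly", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_linear(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r, 1)
  expect_equal(predict(fit, 10), 20)

  fit_sqrt <- fit_linear(x, sqrt(x), transform = "sqrt")
  expect_equal(fit_sqrt$slope, 1)
  expect_equal(fit_sqrt$intercept, 0, tolerance = 1e-12)
  expect_equal(fit_sqrt$r, 1)

  expect_error(fit_linear(1:2, 1:2), "at least 3")
  expect_error(fit_linear(rep(2, 5), 1:5), "zero variance")
  expect_identical(tidy(fit)$estimate, c(0, 2))
  expect_identical(glance(fit_sqrt)$transform, "sqrt")
})

test_that("noisy fits recover the programmed slope within OLS theory", {
  withr::with_seed(71, {
    x <- runif(1000, 50, 250)
    y <- 1.8 * x + rnorm(1000, 0, 20)
  })
  fit <- fit_linear(x, y)
  # OLS sampling theory: se(slope) = sigma / (sd(x) sqrt(n))
  se <- 20 / (sd(x) * sqrt(1000))
  expect_lt(abs(fit$slope - 1.8), 3 * se)
  expect_gt(fit$r, 0.95)
})

test_that("single-fluorophore calibration averages per ROI then across", {
  segs <- tibble(roi_id = "a", J = c(9, 10, 11))
  expect_equal(sami_calibrate(segs)$mean_j1, 10)

  two <- tibble(roi_id = c("a", "a", "b"), J = c(6, 10, 12))
  expect_equal(sami_calibrate(two)$mean_j1, mean(c(8, 12)))
  expect_error(sami_calibrate(two[0, ]), "no single-fluorophore")

  expect_equal(tspan_from_sami(210, sami_calibrate(segs)), 21)
  expect_equal(tspan_from_sami(0, sami_calibrate(segs)), 0)
  expect_equal(tspan_from_sami(2 * 210, sami_calibrate(segs)), 42)
})

test_that("the full single-fluorophore pathway recovers programmed integrals", {
  cfg <- simulation_config(roi_width_um = 8, roi_height_um = 8,
                           sami_integral_cv = 0.15)
  sami <- render_sami_surface(50, cfg, seed = 81)
  segs <- segment_pipeline(
    sami$image,
    analysis_config(binarize_mode = "adaptive", min_segment_area_px = 4))
  expect_gt(nrow(segs), 45)          # near-complete spot recovery
  cal <- sami_calibrate(segs)
  sem3 <- 3 * sd(sami$truth$integral) / sqrt(nrow(segs))
  expect_lt(abs(cal$mean_j1 - mean(sami$truth$integral)), sem3)
})

test_that("molecule counts from <J_1> are exactly scale-free", {
  cfg <- simulation_config(roi_width_um = 8, roi_height_um = 8)
  sami <- render_sami_surface(30, cfg, seed = 82)
  acfg <- analysis_config(binarize_mode = "adaptive")
  segs1 <- segment_pipeline(sami$image, acfg)
  scaled <- srrf_image(sami$image$pixels * 37, cfg$pixel_size_nm,
                       "red_640", "sami1")
  segs2 <- segment_pipeline(scaled, acfg)
  m1 <- tspan_from_sami(segs1$J, sami_calibrate(segs1))
  m2 <- tspan_from_sami(segs2$J, sami_calibrate(segs2))
  expect_equal(m2, m1, tolerance = 1e-10)
})

test_that("sensitivity calibration matches its worked example", {
  roi_means <- tibble(mean_diameter_nm = 120)
  sens <- sensitivity_calibrate(roi_means, reference_diameter_nm = 106)
  expect_equal(sens$size_sensitivity, 120 / 106)
  expect_equal(120 / sens$size_sensitivity, 106)

  ident <- sensitivity_calibrate(tibble(mean_diameter_nm = 106), 106)
  expect_equal(ident$size_sensitivity, 1)

  # programmed scale factor recovered within 2%
  withr::with_seed(83, {
    true_means <- runif(20, 90, 130)
    roi_tab <- tibble(
      mean_diameter_nm = 1.25 * true_means * rnorm(20, 1, 0.005),
      mean_sqrt_integral = 0.9 * 21 * rnorm(20, 1, 0.005)
    )
  })
  sens2 <- sensitivity_calibrate(roi_tab,
                                 reference_diameter_nm = mean(true_means),
                                 reference_content = 21)
  # mean-of-ratios vs programmed 1.25 differs by the ratio spread
  expect_equal(sens2$size_sensitivity,
               mean(roi_tab$mean_diameter_nm / mean(true_means)),
               tolerance = 1e-12)
  expect_lt(abs(sens2$content_sensitivity - 0.9), 0.02 * 0.9)
})

test_that("cross-validation partitions ROIs as specified", {
  roi_tab <- tibble(mean_diameter_nm = rep(120, 33),
                    mean_sqrt_integral = rep(25, 33))
  cv <- crossvalidate_sensitivity(roi_tab, k = 5, seed = 2,
                                  reference_diameter_nm = 106,
                                  reference_content = 21)
  expect_identical(sort(as.integer(table(cv$folds$fold)), decreasing = TRUE),
                   c(7L, 7L, 7L, 6L, 6L))
  expect_identical(nrow(cv$folds), 33L)
  # noiseless inputs: every fold's calibrated means equal the references
  expect_equal(cv$summary$calibrated_mean_diameter_nm, rep(106, 5))
  expect_equal(cv$summary$calibrated_mean_content, rep(21, 5))

  # reproducible under the seed, exact partition
  cv2 <- crossvalidate_sensitivity(roi_tab, k = 5, seed = 2,
                                   reference_diameter_nm = 106)
  expect_identical(cv$folds, cv2$folds)

  # leave-one-out runs
  loo <- crossvalidate_sensitivity(roi_tab[1:6, ], k = 6, seed = 1,
                                   reference_diameter_nm = 106)
  expect_identical(nrow(loo$summary), 6L)
  expect_error(crossvalidate_sensitivity(roi_tab[1:3, ], k = 5, seed = 1,
                                         reference_diameter_nm = 106),
               "k exceeds")
})

test_that("apply_calibration produces EV records per method tag", {
  segs <- tibble(
    label = 1:3, roi_id = "r1", x_nm = c(1, 2, 3), y_nm = c(4, 5, 6),
    diameter_nm = c(100, 150, 200), J = c(1000, 2000, 3000),
    normalized_integral = c(0.1, 0.2, 0.3)
  )
  # identity regression returns inputs unchanged
  ident <- fit_linear(c(1, 2, 3), c(1, 2, 3))
  out <- apply_calibration(segs, size = ident)
  expect_equal(out$diameter_nm, segs$diameter_nm)
  expect_identical(out$method, rep("srrf_regression", 3))

  sami <- sami_calibrate(tibble(roi_id = "s", J = c(90, 110)))
  out2 <- apply_calibration(segs, content = sami)
  expect_equal(out2$tspan_count, segs$J / 100)
  expect_identical(out2$method, rep("srrf_sami", 3))

  sens <- sensitivity_calibrate(tibble(mean_diameter_nm = 212,
                                       mean_sqrt_integral = 2),
                                reference_diameter_nm = 106,
                                reference_content = 1)
  out3 <- apply_calibration(segs, size = sens, content = sens)
  expect_equal(out3$diameter_nm, segs$diameter_nm / 2)
  expect_equal(out3$tspan_count, sqrt(segs$normalized_integral) / 2)
  expect_identical(out3$method, rep("srrf_sensitivity", 3))

  expect_identical(nrow(apply_calibration(segs[0, ], size = ident)), 0L)
})

test_that("regression calibration round trips through the generator relation", {
  # generator-style relation: SRRF diameter = a * true + noise; fitting in
  # the generative direction recovers the programmed slope within OLS
  # sampling theory
  withr::with_seed(84, {
    true_d <- rlnorm(1000, log(100), 0.35)
    srrf_d <- 1.4 * true_d + rnorm(1000, 0, 8)
  })
  fwd <- fit_linear(true_d, srrf_d)
  se_fwd <- summary(lm(srrf_d ~ true_d))$coefficients[2, 2]
  expect_lt(abs(fwd$slope - 1.4), 3 * se_fwd)

  # the applied calibration maps SRRF readings back onto the true scale:
  # OLS passes through the means, so mean recovery is exact in expectation
  cal <- fit_linear(srrf_d, true_d)
  segs <- tibble(roi_id = "r", x_nm = 0, y_nm = 0, diameter_nm = srrf_d,
                 J = 1, normalized_integral = 1)
  rec <- apply_calibration(segs, size = cal)
  expect_equal(mean(rec$diameter_nm), mean(true_d), tolerance = 1e-8)
})
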