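# Synthetic single-EV datasets: ground-truth populations rendered as SRRF
# images, matched SMLM localization maps, and single-fluorophore
# calibration surfaces.
#
# The generator emulates TSPAN-stained EVs captured on a coverslip:
# sub-diffraction particles of variable diameter carrying a
# size-dependent number of labelled molecules, imaged through a Gaussian
# PSF with constant background and Gaussian read noise; SMLM sees each
# fluorophore as a Poisson-distributed burst of localizations jittered by
# the localization precision. Every output is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' Defaults encode the stated experimental world: ~0.5 detected EVs/um^2,
#' lognormal diameters averaging ~106 nm (the reference-EV mean) over a
#' ~50-250 nm range, molecule content with mean 21 at 106 nm scaling with
#' membrane area (M ~ Poisson(21 (d/106)^2)), a 30 nm PSF sigma (~70 nm
#' SRRF resolution), 7.5 nm localization precision and alpha = 10
#' localizations per fluorophore. ROIs default to 12 x 12 um so that full
#' tessellations stay desk-sized; the experiment-scale 1,678 um^2 ROI is a
#' config away.
#'
#' @param roi_width_um,roi_height_um ROI extent, um.
#' @param ev_density_per_um2 expected detected-EV surface density.
#' @param diameter_meanlog,diameter_sdlog lognormal diameter parameters (nm).
#' @param content_scale mean molecule count at the anchor diameter.
#' @param content_d0_nm anchor diameter for the content model.
#' @param psf_sigma_nm Gaussian PSF sigma of the SRRF image.
#' @param intensity_per_molecule rendered intensity integral per molecule
#'   (arbitrary units).
#' @param background constant background intensity.
#' @param read_noise_sd Gaussian read-noise sd.
#' @param pixel_size_nm SRRF pixel size.
#' @param alpha mean localizations per fluorophore.
#' @param loc_precision_nm localization precision sigma.
#' @param poisson_blinking draw Poisson(alpha) localizations per
#'   fluorophore; `FALSE` emits exactly `round(alpha)` (deterministic mode).
#' @param colabel_gfp_fraction,colabel_rna_fraction co-labelling
#'   probabilities of the green/RNA cargo channels.
#' @param green_integral rendered intensity integral of a co-labelled EV in
#'   the green channel.
#' @param merged_fraction fraction of EVs placed as close pairs to exercise
#'   segment splitting.
#' @param pair_separation_psf centre separation of close pairs, in PSF
#'   sigmas.
#' @param margin_nm keep-out margin from the ROI border.
#' @param sami_integral_cv lognormal coefficient of variation of the
#'   single-fluorophore integral on calibration surfaces.
#' @return an object of class `ev_sim_config` (named list).
#' @export
simulation_config <- function(roi_width_um = 12, roi_height_um = 12,
                              ev_density_per_um2 = 0.5,
                              diameter_meanlog = log(100),
                              diameter_sdlog = 0.35,
                              content_scale = 21, content_d0_nm = 106,
                              psf_sigma_nm = 30,
                              intensity_per_molecule = 2000,
                              background = 2, read_noise_sd = 0.5,
                              pixel_size_nm = 20,
                              alpha = 10, loc_precision_nm = 7.5,
                              poisson_blinking = TRUE,
                              colabel_gfp_fraction = 0,
                              colabel_rna_fraction = 0,
                              green_integral = 30000,
                              merged_fraction = 0,
                              pair_separation_psf = 2.5,
                              margin_nm = 500,
                              sami_integral_cv = 0.2) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(roi_width_um > 0, roi_height_um > 0, ev_density_per_um2 >= 0,
              psf_sigma_nm > 0, pixel_size_nm > 0, alpha > 0,
              loc_precision_nm >= 0, merged_fraction >= 0,
              merged_fraction <= 1, colabel_gfp_fraction >= 0,
              colabel_gfp_fraction <= 1)
  })
  structure(cfg, class = "ev_sim_config")
}

roi_bounds <- function(cfg) {
  c(0, cfg$roi_width_um * 1000, 0, cfg$roi_height_um * 1000)
}

#' Simulate a ground-truth EV population
#'
#' Draws `Poisson(density x area)` EVs uniformly over the ROI (inside the
#' border margin); a configured fraction is placed as close pairs at
#' `pair_separation_psf` PSF sigmas to exercise merged-segment splitting.
#' Diameters are lognormal; molecule counts follow
#' `M ~ Poisson(content_scale (d / d0)^2)`; cargo co-labels are Bernoulli.
#'
#' @param cfg an [simulation_config()].
#' @param seed RNG seed.
#' @param roi_id ROI identifier.
#' @return tibble: `ev_id`, `x_nm`, `y_nm`, `diameter_nm`, `m_true`,
#'   `gfp`, `rna`, `pair_id` (NA for singles), `roi_id`.
#' @export
simulate_ground_truth <- function(cfg = simulation_config(), seed = 1L,
                                  roi_id = "roi1") {
  withr::with_seed(as.integer(seed), {
    b <- roi_bounds(cfg)
    area_um2 <- cfg$roi_width_um * cfg$roi_height_um
    n <- stats::rpois(1, cfg$ev_density_per_um2 * area_um2)
    if (n == 0) {
      return(tibble(ev_id = integer(), x_nm = double(), y_nm = double(),
                    diameter_nm = double(), m_true = integer(),
                    gfp = logical(), rna = logical(), pair_id = integer(),
                    roi_id = character()))
    }
    n_pairs <- round(n * cfg$merged_fraction / 2)
    n_single <- n - 2 * n_pairs
    m <- cfg$margin_nm
    rx <- function(k) stats::runif(k, b[1] + m, b[2] - m)
    ry <- function(k) stats::runif(k, b[3] + m, b[4] - m)
    xs <- rx(n_single + n_pairs)
    ys <- ry(n_single + n_pairs)
    x <- xs[seq_len(n_single)]
    y <- ys[seq_len(n_single)]
    pair_id <- rep(NA_integer_, n_single)
    if (n_pairs > 0) {
      ax <- xs[n_single + seq_len(n_pairs)]
      ay <- ys[n_single + seq_len(n_pairs)]
      sep <- cfg$pair_separation_psf * cfg$psf_sigma_nm
      theta <- stats::runif(n_pairs, 0, 2 * pi)
      bx <- pmin(pmax(ax + sep * cos(theta), b[1] + m), b[2] - m)
      by <- pmin(pmax(ay + sep * sin(theta), b[3] + m), b[4] - m)
      x <- c(x, as.vector(rbind(ax, bx)))
      y <- c(y, as.vector(rbind(ay, by)))
      pair_id <- c(pair_id, rep(seq_len(n_pairs), each = 2))
    }
    d <- stats::rlnorm(n, cfg$diameter_meanlog, cfg$diameter_sdlog)
    m_true <- stats::rpois(n, cfg$content_scale * (d / cfg$content_d0_nm)^2)
    tibble(
      ev_id = seq_len(n), x_nm = x, y_nm = y, diameter_nm = d,
      m_true = as.integer(m_true),
      gfp = stats::runif(n) < cfg$colabel_gfp_fraction,
      rna = stats::runif(n) < cfg$colabel_rna_fraction,
      pair_id = pair_id, roi_id = roi_id
    )
  })
}

# Add one isotropic Gaussian spot (total integral `integral`, sigma nm) to
# an intensity matrix, evaluated over a +-4 sigma window.
add_gaussian_spot <- function(px, x_nm, y_nm, integral, sigma_nm,
                              pixel_size_nm) {
  nr <- nrow(px); nc <- ncol(px)
  s_px <- sigma_nm / pixel_size_nm
  cx <- x_nm / pixel_size_nm + 0.5  # centre in pixel units (1-based centres)
  cy <- y_nm / pixel_size_nm + 0.5
  r0 <- max(1L, floor(cy - 4 * s_px)); r1 <- min(nr, ceiling(cy + 4 * s_px))
  c0 <- max(1L, floor(cx - 4 * s_px)); c1 <- min(nc, ceiling(cx + 4 * s_px))
  if (r0 > r1 || c0 > c1) return(px)
  amp <- integral / (2 * pi * s_px^2)
  gy <- exp(-((r0:r1 - cy)^2) / (2 * s_px^2))
  gx <- exp(-((c0:c1 - cx)^2) / (2 * s_px^2))
  px[r0:r1, c0:c1] <- px[r0:r1, c0:c1] + amp * (gy %o% gx)
  px
}

# Effective spot width: PSF broadened by the particle's physical extent.
sigma_eff_nm <- function(diameter_nm, psf_sigma_nm) {
  sqrt(psf_sigma_nm^2 + (diameter_nm / 4)^2)
}

#' Render a ground-truth population as an SRRF image
#'
#' Each EV becomes an isotropic Gaussian of sigma
#' `sqrt(psf_sigma^2 + (d/4)^2)` (PSF broadened by particle extent) whose
#' total integral is `m_true x intensity_per_molecule`, over a constant
#' background with seeded Gaussian read noise. In the green channels only
#' co-labelled EVs are rendered, each with integral `green_integral`.
#'
#' @param evs ground-truth tibble from [simulate_ground_truth()].
#' @param cfg the [simulation_config()].
#' @param seed RNG seed (read noise).
#' @param channel rendered channel; `red_*` renders TSPAN content,
#'   `green_*` renders the co-labelled subpopulation.
#' @return an [srrf_image()].
#' @export
render_srrf_image <- function(evs, cfg = simulation_config(), seed = 1L,
                              channel = "red_640") {
  b <- roi_bounds(cfg)
  nc <- round((b[2] - b[1]) / cfg$pixel_size_nm)
  nr <- round((b[4] - b[3]) / cfg$pixel_size_nm)
  green <- grepl("^green", channel)
  px <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(nr * nc, cfg$background, cfg$read_noise_sd), nr, nc)
  })
  sel <- if (green) which(evs$gfp | evs$rna) else seq_len(nrow(evs))
  for (i in sel) {
    integral <- if (green) cfg$green_integral
                else evs$m_true[i] * cfg$intensity_per_molecule
    px <- add_gaussian_spot(px, evs$x_nm[i], evs$y_nm[i], integral,
                            sigma_eff_nm(evs$diameter_nm[i],
                                         cfg$psf_sigma_nm),
                            cfg$pixel_size_nm)
  }
  srrf_image(pmax(px, 0), pixel_size_nm = cfg$pixel_size_nm,
             channel = channel, roi_id = evs$roi_id[1] %||% "roi1")
}

#' Simulate an SMLM localization map for a ground-truth population
#'
#' Each EV carries `m_true` fluorophores uniform on a disc of its diameter;
#' each fluorophore emits `Poisson(alpha)` localizations (or exactly
#' `round(alpha)` with `poisson_blinking = FALSE`), jittered by the
#' localization precision, with sequential frame indices and lognormal
#' photon counts.
#'
#' @inheritParams render_srrf_image
#' @param roi_id ROI identifier.
#' @return localization tibble (`x_nm`, `y_nm`, `frame`, `photons`,
#'   `channel`, `roi_id`, plus the source `ev_id` truth column).
#' @export
simulate_localizations <- function(evs, cfg = simulation_config(),
                                   seed = 1L, roi_id = NULL) {
  roi_id <- roi_id %||% (evs$roi_id[1] %||% "roi1")
  b <- roi_bounds(cfg)
  withr::with_seed(as.integer(seed), {
    per_ev <- purrr::map(seq_len(nrow(evs)), function(i) {
      m <- evs$m_true[i]
      if (m == 0) return(NULL)
      r <- evs$diameter_nm[i] / 2
      rr <- r * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      fx <- evs$x_nm[i] + rr * cos(th)
      fy <- evs$y_nm[i] + rr * sin(th)
      k <- if (cfg$poisson_blinking) stats::rpois(m, cfg$alpha)
           else rep(round(cfg$alpha), m)
      if (sum(k) == 0) return(NULL)
      tibble(
        x_nm = rep(fx, k) + stats::rnorm(sum(k), 0, cfg$loc_precision_nm),
        y_nm = rep(fy, k) + stats::rnorm(sum(k), 0, cfg$loc_precision_nm),
        photons = stats::rlnorm(sum(k), log(1000), 0.3),
        ev_id = evs$ev_id[i]
      )
    })
    out <- bind_rows(purrr::compact(per_ev))
    if (nrow(out) == 0) {
      return(tibble(x_nm = double(), y_nm = double(), frame = integer(),
                    photons = double(), channel = character(),
                    roi_id = character(), ev_id = integer()))
    }
    out$x_nm <- pmin(pmax(out$x_nm, b[1]), b[2])
    out$y_nm <- pmin(pmax(out$y_nm, b[3]), b[4])
    out$frame <- seq_len(nrow(out))
    out$channel <- "red_640"
    out$roi_id <- roi_id
    out[, c("x_nm", "y_nm", "frame", "photons", "channel", "roi_id",
            "ev_id")]
  })
}

#' Render a single-fluorophore calibration surface
#'
#' Sparse covalently attached reporters: `n_fluorophores` isolated spots
#' with pairwise spacing at least 5 PSF sigmas, each a PSF-sized Gaussian
#' of known integral (lognormal spread `sami_integral_cv` around
#' `intensity_per_molecule`), plus a matched localization map with one
#' Poisson(alpha) burst per reporter.
#'
#' @param n_fluorophores number of isolated reporters.
#' @param cfg the [simulation_config()].
#' @param seed RNG seed.
#' @param roi_id ROI identifier.
#' @return list with `image` ([srrf_image()]), `locs` (localization
#'   tibble), and `truth` (tibble with per-spot positions and true
#'   integrals).
#' @export
render_sami_surface <- function(n_fluorophores, cfg = simulation_config(),
                                seed = 1L, roi_id = "sami1") {
  b <- roi_bounds(cfg)
  spacing <- 5 * cfg$psf_sigma_nm
  usable <- (b[2] - b[1] - 2 * cfg$margin_nm) *
            (b[4] - b[3] - 2 * cfg$margin_nm)
  if (n_fluorophores * pi * spacing^2 > 0.5 * usable)
    abort("render_sami_surface: too many fluorophores for the spacing constraint at this ROI size")
  withr::with_seed(as.integer(seed), {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_fluorophores) {
      if ((tries <- tries + 1L) > 200 * n_fluorophores)
        abort("render_sami_surface: could not place fluorophores with the required spacing")
      px <- stats::runif(1, b[1] + cfg$margin_nm, b[2] - cfg$margin_nm)
      py <- stats::runif(1, b[3] + cfg$margin_nm, b[4] - cfg$margin_nm)
      if (length(xs) == 0 ||
          all((xs - px)^2 + (ys - py)^2 >= spacing^2)) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    sdlog <- sqrt(log(1 + cfg$sami_integral_cv^2))
    J1 <- stats::rlnorm(n_fluorophores,
                        log(cfg$intensity_per_molecule) - sdlog^2 / 2, sdlog)
    nc <- round((b[2] - b[1]) / cfg$pixel_size_nm)
    nr <- round((b[4] - b[3]) / cfg$pixel_size_nm)
    px <- matrix(stats::rnorm(nr * nc, cfg$background, cfg$read_noise_sd),
                 nr, nc)
    for (i in seq_len(n_fluorophores)) {
      px <- add_gaussian_spot(px, xs[i], ys[i], J1[i], cfg$psf_sigma_nm,
                              cfg$pixel_size_nm)
    }
    k <- if (cfg$poisson_blinking) stats::rpois(n_fluorophores, cfg$alpha)
         else rep(round(cfg$alpha), n_fluorophores)
    locs <- tibble(
      x_nm = rep(xs, k) + stats::rnorm(sum(k), 0, cfg$loc_precision_nm),
      y_nm = rep(ys, k) + stats::rnorm(sum(k), 0, cfg$loc_precision_nm),
      frame = seq_len(sum(k)),
      photons = stats::rlnorm(sum(k), log(1000), 0.3),
      channel = "red_640", roi_id = roi_id
    )
    list(
      image = srrf_image(pmax(px, 0), cfg$pixel_size_nm, "red_640", roi_id),
      locs = locs,
      truth = tibble(spot_id = seq_len(n_fluorophores), x_nm = xs,
                     y_nm = ys, integral = J1, n_locs = k)
    )
  })
}
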