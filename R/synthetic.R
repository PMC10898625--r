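#' Site style specifications for the synthetic multi-site simulator
#'
#' Creates `n_sites` distinct appearance-style specifications.  Each site is a
#' bundle of per-tissue mean intensities, a contrast exponent (gamma), a
#' multiplicative low-frequency bias-field amplitude and smoothness, additive
#' noise, in-plane blur, and a relative jitter that models natural intra-site
#' appearance variability.  Sites are laid out on a deterministic grid of
#' contrast/noise/blur values (so any two sites differ in several parameters)
#' and then perturbed slightly by the seed.
#'
#' Tissue classes are 0 = background, 1 = CSF-like ring, 2 = GM-like shell,
#' 3 = WM-like core, with strictly increasing mean intensities (T1-like).
#'
#' @param n_sites number of sites (>= 2)
#' @param seed integer seed; the spec list is a pure function of it
#' @param jitter_sd relative intra-site jitter of class means and gamma
#' @return list of `site_style_spec` objects
#' @export
make_site_specs <- function(n_sites, seed, jitter_sd = 0.025) {
  assert_that(is_count(n_sites) && n_sites >= 2,
              "harmonization needs at least 2 sites (got %s)", format(n_sites))
  assert_that(is_count(seed), "seed must be a single integer")
  base_means <- c(0.03, 0.28, 0.55, 0.85)
  scale  <- seq(1.0, 0.78, length.out = n_sites)
  gamma  <- seq(0.65, 1.55, length.out = n_sites)
  noise  <- seq(0.010, 0.030, length.out = n_sites)
  biasA  <- seq(0.04, 0.12, length.out = n_sites)
  biasS  <- seq(8, 14, length.out = n_sites)
  blur   <- seq(0, 1.6, length.out = n_sites)
  with_seed(derive_seed(seed, "site-specs"), {
    lapply(seq_len(n_sites), function(k) {
      m <- pmin(base_means * scale[k] * (1 + rnorm(4, sd = 0.02)), 1)
      m <- sort(m)  # strict ordering of tissue classes
      spec <- list(
        site_id = k - 1L,
        class_means = m,
        gamma = max(0.2, gamma[k] * (1 + rnorm(1, sd = 0.02))),
        bias_amplitude = biasA[k],
        bias_scale = biasS[k],
        noise_sd = noise[k],
        blur_fwhm = blur[k],
        jitter_sd = jitter_sd
      )
      class(spec) <- "site_style_spec"
      spec
    })
  })
}

#' @export
print.site_style_spec <- function(x, ...) {
  cat(sprintf("<site_style_spec #%d> means=%s gamma=%.3f bias=%.2f/%.1fpx noise=%.3f blur=%.2fpx jitter=%.2f\n",
              x$site_id, paste(sprintf("%.3f", x$class_means), collapse = ","),
              x$gamma, x$bias_amplitude, x$bias_scale, x$noise_sd,
              x$blur_fwhm, x$jitter_sd))
  invisible(x)
}

# Analytic nested-ellipse head template: outer CSF-like ring, GM-like shell,
# WM-like core, on a unit coordinate grid.
ellipse_template_labels <- function(px, py) {
  ax <- c(0.86, 0.72, 0.48)  # semi-axes (fraction of half-canvas), outer to inner
  ay <- c(0.80, 0.66, 0.42)
  lab <- matrix(0L, nrow(px), ncol(px))
  for (k in 1:3) {
    inside <- (px / ax[k])^2 + (py / ay[k])^2 <= 1
    lab[inside] <- k
  }
  lab
}

#' Sample a synthetic head anatomy (tissue-class mask)
#'
#' Draws a nested-ellipse head phantom (CSF ring, GM shell, WM core on
#' background) warped by a smooth random coordinate deformation, giving
#' per-subject anatomical variability while keeping ground-truth tissue
#' labels.  The mask is a pure function of `anatomy_seed`.
#'
#' @param anatomy_seed integer seed identifying the subject
#' @param shape 2-element pixel dimensions, each >= 32
#' @param deform deformation amplitude in pixels; 0 gives the analytic template
#' @return integer matrix of labels in \{0, 1, 2, 3\}
#' @export
sample_anatomy <- function(anatomy_seed, shape = c(64, 64), deform = 3) {
  assert_that(length(shape) == 2 && all(shape >= 32),
              "shape must have >= 32 pixels per axis to contain the nested structures")
  h <- shape[1]; w <- shape[2]
  # unit coordinates in [-1, 1]
  ux <- matrix(rep(seq(-1, 1, length.out = h), w), h, w)
  uy <- matrix(rep(seq(-1, 1, length.out = w), each = h), h, w)
  if (deform > 0) {
    with_seed(derive_seed(anatomy_seed, "anatomy"), {
      fx <- smooth_field(shape, scale = h / 8)
      fy <- smooth_field(shape, scale = h / 8)
      ux <- ux + deform * 2 / h * fx
      uy <- uy + deform * 2 / w * fy
    })
  }
  lab <- ellipse_template_labels(ux, uy)
  assert_that(all(0:3 %in% lab),
              "shape too small: not all tissue classes present in the phantom")
  lab
}

#' Render a tissue mask under a site's appearance style
#'
#' Applies the site's intensity transfer (jittered class means raised to the
#' jittered contrast exponent), a multiplicative smooth bias field, Gaussian
#' in-plane blur and additive noise.  With all dispersion parameters zero the
#' image is the deterministic piecewise-constant map
#' `class_means[k]^gamma` over the mask.
#'
#' @param mask integer tissue mask from [sample_anatomy()]
#' @param spec a `site_style_spec`
#' @param sample_seed integer seed for the per-sample random draws
#' @return a `phantom_sample`: list with `image`, `mask`, `site_id`,
#'   `style_draw` (the realized jittered parameters), `anatomy_seed`
#' @export
render_phantom <- function(mask, spec, sample_seed = 0L, anatomy_seed = NA_integer_) {
  assert_that(inherits(spec, "site_style_spec"), "spec must be a site_style_spec")
  assert_that(all(mask %in% 0:3), "mask labels must be in 0..3")
  shape <- dim(mask)
  with_seed(derive_seed(sample_seed, sprintf("render-%d", spec$site_id)), {
    means <- spec$class_means
    gamma <- spec$gamma
    if (spec$jitter_sd > 0) {
      means <- means * (1 + rnorm(length(means), sd = spec$jitter_sd))
      gamma <- max(0.2, gamma * (1 + rnorm(1, sd = spec$jitter_sd)))
    }
    u <- pmin(pmax(means, 0), 1)^gamma
    img <- matrix(u[as.vector(mask) + 1L], shape[1], shape[2])
    if (spec$bias_amplitude > 0) {
      img <- img * (1 + spec$bias_amplitude * smooth_field(shape, spec$bias_scale))
    }
    if (spec$blur_fwhm > 0) img <- blur2d(img, fwhm_to_sigma(spec$blur_fwhm))
    if (spec$noise_sd > 0) img <- img + matrix(rnorm(prod(shape), sd = spec$noise_sd), shape[1], shape[2])
    out <- list(image = img, mask = mask, site_id = spec$site_id,
                anatomy_seed = anatomy_seed,
                style_draw = list(class_means = means, gamma = gamma))
    class(out) <- "phantom_sample"
    out
  })
}

#' Per-tissue-class mean intensity profile
#'
#' The appearance fingerprint used for site-separability checks and for the
#' appearance-transfer evaluation: mean image intensity within each tissue
#' class of the mask.
#'
#' @param image intensity matrix
#' @param mask tissue mask of equal shape
#' @param classes which labels to profile
#' @return numeric vector, one mean per class
#' @export
class_mean_profile <- function(image, mask, classes = 1:3) {
  vapply(classes, function(k) mean(image[mask == k]), numeric(1))
}

#' Generate a full multi-site dataset with a paired traveling-phantom test set
#'
#' Training sets use disjoint anatomy seeds per site (unpaired, as in real
#' multi-site data).  The paired test set renders each of `n_paired_test`
#' held-out anatomies under every site's style — synthetic traveling
#' phantoms — with ground-truth masks retained.  Train and test anatomy seeds
#' are disjoint by construction.
#'
#' @param specs list of `site_style_spec` from [make_site_specs()]
#' @param n_train_per_site training anatomies per site (>= 1)
#' @param n_paired_test paired test anatomies (>= 1)
#' @param seed integer seed; the dataset is a pure function of (specs, seed)
#' @param shape canvas dimensions
#' @return list with `train` (list per site of `phantom_sample`), `paired`
#'   (list per anatomy of per-site `phantom_sample`), `specs`, and the seed
#'   bookkeeping
#' @export
make_dataset <- function(specs, n_train_per_site, n_paired_test, seed,
                         shape = c(64, 64)) {
  assert_that(is_count(n_train_per_site) && n_train_per_site >= 1,
              "n_train_per_site must be >= 1")
  assert_that(is_count(n_paired_test) && n_paired_test >= 1,
              "n_paired_test must be >= 1")
  n_sites <- length(specs)
  n_anat <- n_sites * n_train_per_site + n_paired_test
  aseeds <- with_seed(derive_seed(seed, "anatomy-seeds"),
                      sample.int(2^30, n_anat))  # unique => train/test disjoint
  train_seeds <- matrix(aseeds[seq_len(n_sites * n_train_per_site)],
                        nrow = n_sites)
  test_seeds <- aseeds[(n_sites * n_train_per_site + 1):n_anat]

  train <- lapply(seq_len(n_sites), function(k) {
    lapply(seq_len(n_train_per_site), function(i) {
      m <- sample_anatomy(train_seeds[k, i], shape)
      render_phantom(m, specs[[k]],
                     sample_seed = derive_seed(seed, sprintf("tr-%d-%d", k, i)),
                     anatomy_seed = train_seeds[k, i])
    })
  })
  paired <- lapply(seq_len(n_paired_test), function(i) {
    m <- sample_anatomy(test_seeds[i], shape)
    lapply(seq_len(n_sites), function(k) {
      render_phantom(m, specs[[k]],
                     sample_seed = derive_seed(seed, sprintf("te-%d-%d", k, i)),
                     anatomy_seed = test_seeds[i])
    })
  })
  structure(list(train = train, paired = paired, specs = specs, seed = seed,
                 train_anatomy_seeds = train_seeds,
                 test_anatomy_seeds = test_seeds, shape = shape),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("<site_dataset> %d sites, %d train/site, %d paired test anatomies, canvas %dx%d\n",
              length(x$specs), length(x$train[[1]]), length(x$paired),
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' Simulate coarser effective resolution on the same pixel grid
#'
#' Blurs with the Gaussian whose width matches the resolution change
#' (FWHM = sqrt(factor^2 - 1) pixels), resamples the image onto a grid
#' `factor` times coarser, and bilinearly interpolates back, so the output
#' has the same shape but the detail content of the coarser acquisition.
#'
#' @param image 2-D matrix (or 3-D array, processed slice-wise on axis 3)
#' @param factor resolution degradation factor, > 1 (e.g. 1.25 for 1 mm to 1.25 mm)
#' @return degraded image, same shape as input
#' @export
degrade_resolution <- function(image, factor) {
  assert_that(is.numeric(factor) && length(factor) == 1 && factor > 1,
              "factor must be > 1")
  if (length(dim(image)) == 3) {
    out <- image
    for (k in seq_len(dim(image)[3])) out[, , k] <- degrade_resolution(image[, , k], factor)
    return(out)
  }
  sigma <- fwhm_to_sigma(sqrt(factor^2 - 1))
  x <- blur2d(image, sigma)
  h <- nrow(x); w <- ncol(x)
  # coarse sample positions covering the grid
  ch <- seq(1, h, by = factor)
  cw <- seq(1, w, by = factor)
  coarse <- bilinear_sample(x, ch, cw)
  fine <- bilinear_sample_grid(coarse, ch, cw, h, w)
  fine
}

# Sample x at (rows, cols) positions (outer grid), bilinear.
bilinear_sample <- function(x, rows, cols) {
  h <- nrow(x); w <- ncol(x)
  r0 <- pmin(floor(rows), h - 1); r1 <- r0 + 1; fr <- rows - r0
  c0 <- pmin(floor(cols), w - 1); c1 <- c0 + 1; fc <- cols - c0
  a <- x[r0, c0, drop = FALSE]; b <- x[r1, c0, drop = FALSE]
  d <- x[r0, c1, drop = FALSE]; e <- x[r1, c1, drop = FALSE]
  top <- a * (1 - fr) + b * fr
  bot <- d * (1 - fr) + e * fr
  top * rep(1 - fc, each = length(rows)) + bot * rep(fc, each = length(rows))
}

# Interpolate a coarse grid (sampled at positions ch, cw) back to h x w.
bilinear_sample_grid <- function(coarse, ch, cw, h, w) {
  # positions of each fine pixel in coarse-grid index coordinates
  ri <- stats::approx(ch, seq_along(ch), xout = seq_len(h), rule = 2)$y
  ci <- stats::approx(cw, seq_along(cw), xout = seq_len(w), rule = 2)$y
  bilinear_sample(coarse, ri, ci)
}
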