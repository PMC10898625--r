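# Synthetic multi-site simulator: determinism, content/style factorization,
# paired test construction, resolution degradation.

test_that("site spec generation is deterministic, seed-sensitive and validated", {
  a <- make_site_specs(3, seed = 7)
  b <- make_site_specs(3, seed = 7)
  expect_identical(a, b)

  c_ <- make_site_specs(3, seed = 8)
  diffs <- mapply(function(x, y) !isTRUE(all.equal(x$class_means, y$class_means)) ||
                    x$gamma != y$gamma, a, c_)
  expect_true(any(diffs))

  expect_error(make_site_specs(1, seed = 0), "at least 2")

  # pairwise distinct styles, ordered class means, nonnegative dispersions
  for (i in seq_along(a)) for (j in seq_along(a)) {
    if (i >= j) next
    expect_false(isTRUE(all.equal(unclass(a[[i]])[-1], unclass(a[[j]])[-1])))
  }
  for (s in a) {
    expect_true(all(diff(s$class_means) > 0))
    expect_true(all(c(s$noise_sd, s$bias_amplitude, s$blur_fwhm, s$jitter_sd) >= 0))
    expect_gt(s$gamma, 0)
  }
})

test_that("anatomy sampling is deterministic with all tissue classes present", {
  m1 <- sample_anatomy(42, c(64, 64))
  m2 <- sample_anatomy(42, c(64, 64))
  expect_identical(m1, m2)
  for (seed in c(1, 99, 1234)) {
    m <- sample_anatomy(seed, c(64, 64))
    counts <- table(factor(m, levels = 0:3))
    expect_true(all(counts > 0))
  }
  expect_error(sample_anatomy(1, c(16, 64)), "32")
})

test_that("zero deformation reproduces the analytic nested-ellipse template", {
  sh <- asNamespace("styleharm")
  h <- 48
  ux <- matrix(rep(seq(-1, 1, length.out = h), h), h, h)
  uy <- matrix(rep(seq(-1, 1, length.out = h), each = h), h, h)
  template <- sh$ellipse_template_labels(ux, uy)
  expect_identical(sample_anatomy(5, c(h, h), deform = 0), template)
  expect_identical(sample_anatomy(99, c(h, h), deform = 0), template)
})

test_that("noise-free rendering is the closed-form class transfer", {
  spec <- structure(list(site_id = 0L, class_means = c(0.05, 0.3, 0.6, 0.9),
                         gamma = 1.3, bias_amplitude = 0, bias_scale = 10,
                         noise_sd = 0, blur_fwhm = 0, jitter_sd = 0),
                    class = "site_style_spec")
  mask <- sample_anatomy(4, c(64, 64))
  s <- render_phantom(mask, spec, sample_seed = 1)
  for (k in 0:3) {
    expect_equal(unique(s$image[mask == k]), spec$class_means[k + 1]^1.3,
                 tolerance = 1e-12)
  }
})

test_that("rendering keeps content fixed while styles differ, and is seeded", {
  specs <- make_site_specs(3, seed = 7)
  mask <- sample_anatomy(10, c(64, 64))
  r1 <- render_phantom(mask, specs[[1]], sample_seed = 3)
  r2 <- render_phantom(mask, specs[[3]], sample_seed = 3)
  expect_identical(r1$mask, r2$mask)
  expect_gt(mean(abs(r1$image - r2$image)), 0.01)

  r1b <- render_phantom(mask, specs[[1]], sample_seed = 3)
  expect_identical(r1$image, r1b$image)
  r1c <- render_phantom(mask, specs[[1]], sample_seed = 4)
  expect_false(identical(r1$image, r1c$image))
})

test_that("dataset construction gives the required counts and disjoint seeds", {
  specs <- make_site_specs(3, seed = 7)
  ds <- make_dataset(specs, n_train_per_site = 4, n_paired_test = 2, seed = 1)
  expect_length(ds$train, 3)
  expect_identical(vapply(ds$train, length, integer(1)), rep(4L, 3))
  expect_length(ds$paired, 2)
  expect_identical(vapply(ds$paired, length, integer(1)), rep(3L, 2))

  # paired samples share anatomy; train/test anatomy seeds disjoint
  for (a in ds$paired) {
    expect_identical(a[[1]]$mask, a[[2]]$mask)
    expect_identical(a[[1]]$mask, a[[3]]$mask)
  }
  expect_length(intersect(as.vector(ds$train_anatomy_seeds), ds$test_anatomy_seeds), 0)

  ds2 <- make_dataset(specs, 4, 2, seed = 1)
  expect_identical(ds$train[[2]][[3]]$image, ds2$train[[2]][[3]]$image)
  expect_error(make_dataset(specs, 0, 2, seed = 1), ">= 1")
})

test_that("sites are perfectly separable from per-class intensity profiles", {
  specs <- make_site_specs(3, seed = 7)
  mask <- sample_anatomy(1, c(64, 64))
  n_per <- 100
  profs <- list()
  labs <- integer(0)
  for (k in 1:3) {
    for (i in seq_len(n_per)) {
      r <- render_phantom(mask, specs[[k]], sample_seed = 1000 * k + i)
      profs[[length(profs) + 1]] <- class_mean_profile(r$image, mask)
      labs <- c(labs, k)
    }
  }
  X <- do.call(rbind, profs)
  centroids <- do.call(rbind, lapply(1:3, function(k) colMeans(X[labs == k, ])))
  pred <- apply(X, 1, function(v)
    which.min(colSums((t(centroids) - v)^2)))
  expect_identical(as.integer(pred), labs)
})

test_that("resolution degradation blurs edges without changing the grid", {
  step <- matrix(0, 64, 64)
  step[, 33:64] <- 1
  deg <- degrade_resolution(step, 1.25)
  expect_identical(dim(deg), dim(step))
  expect_gt(edge_transition_width(deg), edge_transition_width(step))
  expect_error(degrade_resolution(step, 1), "> 1")

  # repeated application keeps removing high-frequency energy
  hf_energy <- function(x) {
    f <- Mod(stats::fft(x))^2
    n <- nrow(x)
    idx <- c((n %/% 4):(3 * n %/% 4))
    sum(f[idx, ]) + sum(f[, idx])
  }
  img <- render_phantom(sample_anatomy(3, c(64, 64)),
                        make_site_specs(2, seed = 1)[[1]], sample_seed = 1)$image
  d1 <- degrade_resolution(img, 1.25)
  d2 <- degrade_resolution(d1, 1.25)
  expect_lt(hf_energy(d1), hf_energy(img))
  expect_lt(hf_energy(d2), hf_energy(d1))
})
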