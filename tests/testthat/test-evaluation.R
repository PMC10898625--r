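# Evaluation metrics: closed forms, oracle loops, estimator properties,
# segmentation self-consistency, volumetrics, edge sharpness.

test_that("paired fidelity metrics match their closed forms", {
  withr::with_seed(1, x <- matrix(runif(64 * 64, -1, 1), 64, 64))
  expect_identical(mae(x, x), 0)
  expect_equal(ms_ssim(x, x), 1, tolerance = 1e-9)
  expect_equal(psnr(x, x), 100)

  y0 <- matrix(0, 32, 32)
  expect_equal(psnr(y0, y0 + 0.5, peak = 2), 10 * log10(4 / 0.25), tolerance = 1e-9)

  withr::with_seed(2, y <- matrix(runif(64 * 64, -1, 1), 64, 64))
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i])
  expect_equal(mae(x, y), s / length(x), tolerance = 1e-7)
  expect_error(mae(x, matrix(0, 3, 3)), "shape")
  expect_lt(ms_ssim(x, y), 1)
})

test_that("Dice coefficient handles overlap, disjoint and empty sets", {
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  a[1:4] <- 1L; b[2:7] <- 1L          # |A|=4, |B|=6, overlap {2,3,4} = 3
  expect_equal(dsc(a, b, 1), 0.6)
  expect_identical(dsc(a, a, 1), 1)
  b2 <- matrix(0L, 4, 4); b2[9:12] <- 1L
  expect_identical(dsc(a, b2, 1), 0)
  expect_identical(dsc(a, b, 7), 1)   # class absent from both
})

test_that("the phantom segmenter recovers noiseless masks and ignores scale", {
  spec <- structure(list(site_id = 0L, class_means = c(0.03, 0.3, 0.55, 0.85),
                         gamma = 1, bias_amplitude = 0, bias_scale = 10,
                         noise_sd = 0, blur_fwhm = 0, jitter_sd = 0),
                    class = "site_style_spec")
  mask <- sample_anatomy(8, c(64, 64))
  img <- render_phantom(mask, spec, sample_seed = 1)$image
  seg <- segment_phantom(img)
  for (k in 1:3) expect_gte(dsc(seg, mask, k), 0.99)

  expect_identical(segment_phantom(img * 3.7), seg)
  expect_error(segment_phantom(matrix(1, 16, 16)), "degenerate")
})

test_that("Frechet distance matches Gaussian theory and vanishes on identity", {
  withr::with_seed(3, f <- matrix(rnorm(200 * 8), 200, 8))
  expect_lt(abs(fid(f, f)), 1e-6)

  # 1-D unit Gaussians with mean offset delta: FID -> delta^2
  delta <- 1.5
  n <- 1e4
  withr::with_seed(4, {
    a <- matrix(rnorm(n), ncol = 1)
    b <- matrix(rnorm(n, mean = delta), ncol = 1)
  })
  se <- sqrt(2 * (2 + 4 * delta^2) / n)   # rough large-n sd of the estimate
  expect_lt(abs(fid(a, b) - delta^2), 3 * max(se, 0.05))
})

test_that("kernel distance is unbiased at the null and detects shifts", {
  vals <- numeric(20)
  withr::with_seed(5, {
    for (r in 1:20) {
      a <- matrix(rnorm(100 * 4), 100, 4)
      b <- matrix(rnorm(100 * 4), 100, 4)
      vals[r] <- kid(a, b)
    }
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(20))

  withr::with_seed(6, {
    a <- matrix(rnorm(100 * 4), 100, 4)
    b <- matrix(rnorm(100 * 4, mean = 1), 100, 4)
  })
  expect_gt(kid(a, b), 10 * abs(mean(vals)))
  expect_error(kid(matrix(0, 1, 2), matrix(0, 5, 2)), "at least 2")
})

test_that("the fixed embedding is deterministic and input-sensitive", {
  e1 <- embedding_model(seed = 42)
  e2 <- embedding_model(seed = 42)
  withr::with_seed(7, imgs <- lapply(1:3, function(i) matrix(runif(64 * 64), 64, 64)))
  f1 <- embed_images(e1, imgs)
  expect_identical(f1, embed_images(e2, imgs))
  expect_identical(dim(f1), c(3L, 32L))
  expect_false(identical(f1[1, ], f1[2, ]))
  e3 <- embedding_model(seed = 43)
  expect_false(identical(f1, embed_images(e3, imgs)))
})

test_that("tissue volumes and group comparisons behave as specified", {
  m <- matrix(0L, 20, 20)
  m[1:100] <- 1L
  r <- volumetric_distributions(list(m, m, m, m), groups = c("a", "a", "b", "b"),
                                voxel_volume = 1)
  expect_true(all(r$volumes$volume[r$volumes$class == 1] == 100))
  expect_true(all(vapply(r$tests, function(t) t$p_value, numeric(1)) == 1))

  # permutation invariance of the group summaries
  masks <- withr::with_seed(8, lapply(1:6, function(i) {
    mm <- matrix(0L, 10, 10); mm[sample(100, 30)] <- sample(1:3, 30, TRUE); mm
  }))
  g <- c("a", "a", "a", "b", "b", "b")
  r1 <- volumetric_distributions(masks, g)
  perm <- c(3, 1, 2, 6, 5, 4)
  r2 <- volumetric_distributions(masks[perm], g[perm])
  expect_equal(r1$summary[order(r1$summary$group, r1$summary$class), c("median", "q25", "q75")],
               r2$summary[order(r2$summary$group, r2$summary$class), c("median", "q25", "q75")],
               ignore_attr = TRUE)
  expect_error(volumetric_distributions(list(), character(0)), "non-empty|one group")
})

test_that("edge transition width grows monotonically with blur", {
  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  sh <- asNamespace("styleharm")
  w0 <- edge_transition_width(step)
  w1 <- edge_transition_width(sh$blur2d(step, 1))
  w2 <- edge_transition_width(sh$blur2d(step, 2))
  expect_lt(w0, w1)
  expect_lt(w1, w2)
})
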