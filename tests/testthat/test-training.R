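# Training loop: pair sampling, no-op updates, seeded bitwise determinism,
# checkpoint/restore equivalence, loss-history behaviour.

tiny_train_setup <- function(n_sites = 3, canvas = 32, n_per_site = 4) {
  specs <- make_site_specs(n_sites, seed = 2)
  ds <- make_dataset(specs, n_per_site, 2, seed = 3, shape = c(canvas, canvas))
  mcfg <- model_config(n_sites = n_sites, canvas = canvas, width = 4)
  list(ds = ds, mcfg = mcfg)
}

test_that("site pair sampling is uniform over ordered pairs without self-pairs", {
  set.seed(42)
  draws <- replicate(10000, sample_site_pair(3))
  expect_true(all(draws[1, ] != draws[2, ]))
  key <- paste(draws[1, ], draws[2, ])
  freq <- table(key)
  expect_length(freq, 6)
  p <- 1 / 6
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq / 10000 - p) < 3 * se))

  set.seed(7); a <- sample_site_pair(4)
  set.seed(7); b <- sample_site_pair(4)
  expect_identical(a, b)
  expect_error(sample_site_pair(1), "2 sites")
})

test_that("a zero learning rate step leaves parameters bit-identical", {
  b <- tiny_bundle(canvas = 32, width = 4)
  before <- param_snapshot(b)
  cfg <- train_config(total_steps = 1, batch_size = 2, learning_rate = 0, seed = 1)
  set.seed(3)
  r <- cs_dct_step(b, tiny_input(b, 2, seed = 1), tiny_input(b, 2, seed = 2), 0L, 1L, cfg)
  expect_identical(param_snapshot(b), before)
  expect_true(all(is.finite(unlist(r$report[c("adv", "cont", "ca", "sd", "sty", "cyc", "id", "total")]))))
  expect_error(cs_dct_step(b, tiny_input(b, 2), tiny_input(b, 2), 1L, 1L, cfg),
               "must differ")
})

test_that("identical seeds give bitwise-identical loss reports and parameters", {
  b1 <- tiny_bundle(canvas = 32, width = 4, seed = 9)
  b2 <- tiny_bundle(canvas = 32, width = 4, seed = 9)
  cfg <- train_config(total_steps = 1, batch_size = 2, learning_rate = 1e-3, seed = 1)
  bi <- tiny_input(b1, 2, seed = 4); bj <- tiny_input(b1, 2, seed = 5)
  set.seed(11); r1 <- cs_dct_step(b1, bi, bj, 0L, 1L, cfg)
  set.seed(11); r2 <- cs_dct_step(b2, bi, bj, 0L, 1L, cfg)
  expect_identical(r1$report, r2$report)
  expect_identical(param_snapshot(b1), param_snapshot(b2))
})

test_that("training runs are a pure function of (config, data, seed)", {
  st <- tiny_train_setup()
  cfg <- train_config(total_steps = 20, batch_size = 2, seed = 13)
  m1 <- harmonize_fit(st$ds, cfg, st$mcfg)
  m2 <- harmonize_fit(st$ds, cfg, st$mcfg)
  expect_identical(param_snapshot(m1$bundle), param_snapshot(m2$bundle))
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 20)

  m3 <- harmonize_fit(st$ds, train_config(total_steps = 20, batch_size = 2, seed = 14),
                      st$mcfg)
  expect_false(identical(param_snapshot(m1$bundle), param_snapshot(m3$bundle)))
})

test_that("checkpoint, restore and continue equals the uninterrupted run bitwise", {
  st <- tiny_train_setup()
  ckdir <- tempfile("ck")
  cfg_a <- train_config(total_steps = 16, batch_size = 2, seed = 21,
                        checkpoint_interval = 8, checkpoint_dir = ckdir)
  full <- harmonize_fit(st$ds, cfg_a, st$mcfg)
  ck <- load_checkpoint(file.path(ckdir, "step-000008.rds"))
  resumed <- resume_fit(ck, st$ds, extra_steps = 8)
  expect_identical(param_snapshot(resumed$bundle), param_snapshot(full$bundle))
  expect_equal(resumed$state$step, full$state$step)
})

test_that("zero training steps return the freshly initialized bundle", {
  st <- tiny_train_setup()
  cfg <- train_config(total_steps = 0, seed = 31)
  m <- harmonize_fit(st$ds, cfg, st$mcfg)
  ref <- build_models(st$mcfg, seed = 31)
  expect_identical(param_snapshot(m$bundle), param_snapshot(ref))
  expect_equal(nrow(m$history), 0)
})

test_that("reconstruction losses fall over the smoke training run", {
  m <- get_smoke_model()
  h <- m$history
  early <- mean(h$cyc[1:50] + h$id[1:50])
  late <- mean(h$cyc[(nrow(h) - 49):nrow(h)] + h$id[(nrow(h) - 49):nrow(h)])
  expect_lt(late, early)
})

test_that("the smoke discriminator sits near its equilibrium on held-out fakes", {
  m <- get_smoke_model()
  ds <- get_smoke_dataset()
  sh <- asNamespace("styleharm")
  probs <- c()
  for (a in 1:4) {
    src <- ds$paired[[a]][[1]]
    harm <- harmonize_to_site(m, src, 1L, seed = 100 + a)[[1]]
    x <- sh$prep_slice(as_slice25d(harm$image), m$model_cfg$canvas)$pixels
    probs <- c(probs, discriminate(m$bundle, x, 1L))
  }
  expect_gt(mean(probs), 0.25)
  expect_lt(mean(probs), 0.75)
})
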