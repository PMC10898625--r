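# Loss terms against brute-force elementwise oracles and closed forms.

brute_l1 <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  s <- 0
  for (i in seq_along(av)) s <- s + abs(av[i] - bv[i])
  s / length(av)
}

test_that("L1-based losses equal a brute-force elementwise loop", {
  shapes <- list(c(5, 7), c(3, 4, 2), c(4, 4, 3, 2))
  for (sh in shapes) {
    withr::with_seed(sum(sh), {
      a <- array(rnorm(prod(sh)), sh)
      b <- array(rnorm(prod(sh)), sh)
    })
    expect_equal(content_consistency(a, b), brute_l1(a, b), tolerance = 1e-7)
    expect_equal(style_diversity(a, b), brute_l1(a, b), tolerance = 1e-7)
    expect_equal(identity_loss(a, b), brute_l1(a, b), tolerance = 1e-7)
    expect_equal(style_consistency(as.vector(a), as.vector(b)),
                 brute_l1(a, b), tolerance = 1e-7)
  }
  expect_equal(content_consistency(array(1, c(3, 3)), array(0, c(3, 3))), 1)
  expect_equal(style_consistency(c(0.5, -0.5), c(0, 0)), 0.5)
  expect_identical(content_consistency(c(1, 2), c(1, 2)), 0)
  expect_error(content_consistency(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("adversarial loss matches its closed form and is monotone", {
  expect_equal(adversarial_loss(0.5, 0.5), 2 * log(0.5), tolerance = 1e-6)
  expect_equal(adversarial_loss(1, 0), 0, tolerance = 1e-5)   # perfect limit, clamped
  # increasing in score_real, decreasing in score_fake
  expect_gt(adversarial_loss(0.6, 0.5), adversarial_loss(0.5, 0.5))
  expect_lt(adversarial_loss(0.5, 0.6), adversarial_loss(0.5, 0.5))
  # vectorized means
  expect_equal(adversarial_loss(c(0.5, 0.5), c(0.5, 0.5)), 2 * log(0.5), tolerance = 1e-6)
})

test_that("content alignment is the closed-form Gaussian KL reduction", {
  expect_identical(content_alignment(array(0, c(4, 4, 2))), 0)
  expect_identical(content_alignment(array(1, c(3, 3))), 0.5)
  withr::with_seed(2, c0 <- array(rnorm(60), c(5, 4, 3)))
  expect_equal(content_alignment(2 * c0), 4 * content_alignment(c0), tolerance = 1e-12)
  expect_equal(content_alignment(c0), 0.5 * mean(c0^2))
})

test_that("cycle loss combines intensity and gradient terms correctly", {
  withr::with_seed(3, x <- matrix(rnorm(64), 8, 8))
  expect_identical(cycle_loss(x, x), 0)
  # constant offset: gradient term vanishes
  expect_equal(cycle_loss(x, x + 0.2, lambda_g = 0.1), 0.2, tolerance = 1e-12)
  # ramp vs constant: brute-force both terms
  ramp <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8)
  const <- matrix(0.5, 8, 8)
  sh <- asNamespace("styleharm")
  g1 <- sh$image_gradient(ramp); g2 <- sh$image_gradient(const)
  manual <- brute_l1(ramp, const) + 0.1 * brute_l1(g1, g2)
  expect_equal(cycle_loss(ramp, const, lambda_g = 0.1), manual, tolerance = 1e-6)
})

test_that("total loss reproduces the hand-computed weighted sum", {
  terms <- list(adv = -1.3863, cont = 0.1, ca = 0.5, sd = 0.2, sty = 0.05,
                cyc = 0.3, id = 0.1)
  rep <- total_loss(terms, loss_weights())
  # -1.3863 + 10*0.1 + 0.01*0.5 - 1*0.2 + 10*0.05 + 10*0.3 + 10*0.1
  expect_equal(rep$total, 3.9187, tolerance = 1e-6)
  # literal diversity sign flips the sd contribution
  rep_lit <- total_loss(terms, loss_weights(), sd_literal = TRUE)
  expect_equal(rep_lit$total - rep$total, 2 * 0.2, tolerance = 1e-10)

  # doubling every weight except lambda_adv doubles (total - adv)
  w2 <- loss_weights(lambda_cont = 20, lambda_ca = 0.02, lambda_sd = 2,
                     lambda_sty = 20, lambda_cyc = 20, lambda_id = 20)
  rep2 <- total_loss(terms, w2)
  expect_equal(rep2$total - terms$adv, 2 * (rep$total - terms$adv), tolerance = 1e-10)

  expect_identical(total_loss(list(adv = 0, cont = 0, ca = 0, sd = 0, sty = 0,
                                   cyc = 0, id = 0))$total, 0)
  expect_error(total_loss(list(adv = NaN, cont = 0, ca = 0, sd = 0, sty = 0,
                               cyc = 0, id = 0)), "adv")
})

test_that("style diversity term is symmetric and nonnegative", {
  withr::with_seed(4, {
    a <- array(rnorm(48), c(4, 4, 3))
    b <- array(rnorm(48), c(4, 4, 3))
  })
  expect_equal(style_diversity(a, b), style_diversity(b, a))
  expect_gte(style_diversity(a, b), 0)
  expect_equal(style_diversity(a, a + 0.3), 0.3, tolerance = 1e-12)
})
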