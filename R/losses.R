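# The seven training loss terms and their weighted total.  All norms are
# means over elements (not sums), so weights are comparable across canvas
# sizes; every L1 term here is the exact numeric counterpart of the tape op
# used during training.

#' Default loss weights
#'
#' lambda_adv = 1, lambda_cont = 10, lambda_ca = 0.01, lambda_sd = 1,
#' lambda_sty = 10, lambda_cyc = 10, lambda_g = 0.1, lambda_id = 10.
#'
#' @param ... overrides by name
#' @return a `loss_weights` list
#' @export
loss_weights <- function(...) {
  w <- list(lambda_adv = 1, lambda_cont = 10, lambda_ca = 0.01, lambda_sd = 1,
            lambda_sty = 10, lambda_cyc = 10, lambda_g = 0.1, lambda_id = 10)
  ov <- list(...)
  assert_that(all(names(ov) %in% names(w)), "unknown loss weight name")
  w[names(ov)] <- ov
  assert_that(all(unlist(w) >= 0), "loss weights must be nonnegative")
  structure(w, class = "loss_weights")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stopf("shape mismatch between loss arguments")
}

#' Adversarial loss (probability form)
#'
#' `mean(log score_real) + mean(log(1 - score_fake))`, the value the
#' discriminator ascends.  Scores are clamped to (eps, 1 - eps).
#'
#' @param score_real,score_fake probabilities of being real
#' @param eps clamping constant
#' @export
adversarial_loss <- function(score_real, score_fake, eps = 1e-7) {
  sr <- pmin(pmax(score_real, eps), 1 - eps)
  sf <- pmin(pmax(score_fake, eps), 1 - eps)
  mean(log(sr)) + mean(log(1 - sf))
}

#' Content consistency loss
#'
#' Mean absolute difference between the content code of the source image and
#' the content code re-extracted from the harmonized image.
#' @param c_i,c_tilde_j content feature arrays of equal shape
#' @export
content_consistency <- function(c_i, c_tilde_j) {
  check_same_shape(c_i, c_tilde_j)
  mean(abs(c_i - c_tilde_j))
}

#' Style consistency loss
#'
#' Mean absolute difference between the style used for generation and the
#' style re-extracted from the generated image.
#' @param s_target,s_tilde style vectors of equal length
#' @export
style_consistency <- function(s_target, s_tilde) {
  check_same_shape(s_target, s_tilde)
  mean(abs(s_target - s_tilde))
}

#' Content alignment loss
#'
#' Closed-form KL divergence between unit-covariance Gaussians centred at the
#' content code and at zero, reduced per element: `0.5 * mean(c^2)`.
#' @param c content feature array
#' @export
content_alignment <- function(c) {
  0.5 * mean(c^2)
}

#' Style diversity term
#'
#' Mean absolute difference between two images generated from the same
#' content with styles from distinct latent draws.  The generator maximizes
#' this term (it enters the total with a negative sign), clipped at a ceiling
#' for stability.
#' @param x_tilde,x_tilde_prime generated images of equal shape
#' @export
style_diversity <- function(x_tilde, x_tilde_prime) {
  check_same_shape(x_tilde, x_tilde_prime)
  mean(abs(x_tilde - x_tilde_prime))
}

# Forward finite differences along both spatial axes with edge replication,
# concatenated; the image gradient operator of the cycle loss.
image_gradient <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, length(x), 1)
  d <- dim(x)
  if (length(d) == 2) x <- array(x, c(d, 1, 1)) else if (length(d) == 3) x <- array(x, c(d, 1))
  n1 <- dim(x)[1]; n2 <- dim(x)[2]
  gh <- x[c(seq_len(n1 - 1L) + 1L, n1), , , , drop = FALSE] - x
  gw <- x[, c(seq_len(n2 - 1L) + 1L, n2), , , drop = FALSE] - x
  c(gh, gw)
}

#' Cycle consistency loss
#'
#' Mean absolute intensity difference plus `lambda_g` times the mean absolute
#' difference of forward finite-difference image gradients (both axes,
#' edge-replicated, concatenated).
#' @param x,x_hat source and cycle-reconstructed images of equal shape
#' @param lambda_g weight of the gradient term
#' @export
cycle_loss <- function(x, x_hat, lambda_g = 0.1) {
  check_same_shape(x, x_hat)
  mean(abs(x - x_hat)) + lambda_g * mean(abs(image_gradient(x) - image_gradient(x_hat)))
}

#' Identity loss
#'
#' Mean absolute difference between an image and its reconstruction from its
#' own content and style.
#' @param x,x_bar image and identity reconstruction of equal shape
#' @export
identity_loss <- function(x, x_bar) {
  check_same_shape(x, x_bar)
  mean(abs(x - x_bar))
}

#' Weighted total loss
#'
#' `adv + lambda_cont*cont + lambda_ca*ca - lambda_sd*sd + lambda_sty*sty +
#' lambda_cyc*cyc + lambda_id*id` (the diversity term is maximized, hence
#' subtracted; `sd_literal = TRUE` restores the literal positive sign).  The
#' `cyc` term is assumed to already include its gradient part.
#'
#' @param terms named list with elements adv, cont, ca, sd, sty, cyc, id
#' @param weights a [loss_weights()]
#' @param sd_literal use the literal (minimized) diversity sign?
#' @return a `loss_report`: the terms plus `total`
#' @export
total_loss <- function(terms, weights = loss_weights(), sd_literal = FALSE) {
  need <- c("adv", "cont", "ca", "sd", "sty", "cyc", "id")
  assert_that(all(need %in% names(terms)), "terms must contain %s", paste(need, collapse = ", "))
  vals <- unlist(terms[need])
  bad <- need[!is.finite(vals)]
  if (length(bad))
    stopf("training divergence: non-finite loss term '%s'", bad[1])
  sd_sign <- if (sd_literal) 1 else -1
  total <- weights$lambda_adv * terms$adv + weights$lambda_cont * terms$cont +
    weights$lambda_ca * terms$ca + sd_sign * weights$lambda_sd * terms$sd +
    weights$lambda_sty * terms$sty + weights$lambda_cyc * terms$cyc +
    weights$lambda_id * terms$id
  structure(c(terms[need], list(total = total)), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(paste(sprintf("%s=%.4g", names(x), unlist(x)), collapse = "  "), "\n")
  invisible(x)
}
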