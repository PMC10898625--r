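# The five network roles: a shared content encoder, per-site style encoders
# (shared trunk + site heads), a shared generator with style injected through
# adaptive instance normalization, per-site style generators (MLP trunk +
# site heads) and per-site discriminators (conv trunk + site heads).
# Architectures follow the multi-domain image-to-image translation lineage;
# every dimension is configurable.

#' Model configuration
#'
#' @param n_sites number of sites (>= 2)
#' @param canvas square canvas side; must be divisible by `downsampling`
#' @param d_s style code length
#' @param d_z latent code length
#' @param width base channel width of the content trunk
#' @param downsampling spatial reduction factor of the content map
#' @param content_scale fixed multiplier on the content encoder output; a
#'   scale well above one keeps the training-time perturbation eta ~ N(0, I)
#'   small relative to the code
#' @param out_gain fixed gain inside the generator's output tanh; values
#'   above one let the bounded output approach the [-1, 1] endpoints (where
#'   min-max normalized tissue plateaus sit) at moderate logit magnitudes
#' @param sd_clip ceiling on the style-diversity term in the generator loss
#' @param sty_literal if TRUE, the style consistency loss compares the source
#'   style s_i with the re-extracted target style (the literal printed form)
#'   instead of the generation style s_j
#' @param sd_literal if TRUE, the diversity term is minimized (literal sign)
#'   instead of maximized
#' @return a `model_config` list
#' @export
model_config <- function(n_sites, canvas = 64L, d_s = 8L, d_z = 16L,
                         width = 8L, downsampling = 2L, content_scale = 8,
                         out_gain = 1, sd_clip = 1, sty_literal = FALSE,
                         sd_literal = FALSE) {
  assert_that(is_count(n_sites) && n_sites >= 2, "n_sites must be >= 2")
  if (canvas %% downsampling != 0)
    stopf("canvas (%d) must be divisible by the downsampling factor (%d)", canvas, downsampling)
  structure(list(n_sites = as.integer(n_sites), canvas = as.integer(canvas),
                 d_s = as.integer(d_s), d_z = as.integer(d_z),
                 width = as.integer(width), downsampling = as.integer(downsampling),
                 content_scale = content_scale, out_gain = out_gain,
                 sd_clip = sd_clip, sty_literal = sty_literal,
                 sd_literal = sd_literal),
            class = "model_config")
}

# He-initialized conv kernel / linear weight parameters.
conv_param <- function(kh, kw, cin, cout) {
  new_param(array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                  c(kh, kw, cin, cout)))
}
bias_param <- function(n) new_param(numeric(n))
linear_param <- function(dout, din) {
  new_param(matrix(rnorm(dout * din, sd = sqrt(2 / din)), dout, din))
}

conv_trunk_params <- function(widths, cin) {
  lapply(seq_along(widths), function(i) {
    list(W = conv_param(3, 3, if (i == 1) cin else widths[i - 1], widths[i]),
         b = bias_param(widths[i]))
  })
}

#' Build the model bundle
#'
#' Initializes all five network roles deterministically from the seed and
#' reports per-role parameter counts.
#'
#' @param config a [model_config()]
#' @param seed integer seed for the initialization
#' @return a `model_bundle`
#' @export
build_models <- function(config, seed = 1L) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  w <- config$width
  cc <- 2L * w                       # content channels
  n_sites <- config$n_sites
  n_up <- as.integer(round(log2(config$downsampling)))
  if (2^n_up != config$downsampling)
    stopf("downsampling must be a power of 2 (got %d)", config$downsampling)
  with_seed(derive_seed(seed, "init"), {
    # content encoder: one stride-1 stage then log2(downsampling) stride-2
    # stages (+ an unnormalized residual head)
    trunk_w <- c(w, rep(cc, n_up))
    EC <- list(trunk = lapply(seq_along(trunk_w), function(i)
      list(W = conv_param(3, 3, if (i == 1) 3L else trunk_w[i - 1], trunk_w[i]),
           b = bias_param(trunk_w[i]), stride = if (i == 1) 1L else 2L)),
      res = list(
        list(W = conv_param(3, 3, cc, cc), b = bias_param(cc)),
        list(W = conv_param(3, 3, cc, cc), b = bias_param(cc))))
    # generator: 2 AdaIN residual blocks at content resolution, then one
    # upsampling conv stage (with channel-affine style modulation) per
    # factor-2 of downsampling, then tanh
    up_w <- pmax(4L, as.integer(w / 2^(seq_len(n_up) - 1L)))
    up_in <- c(cc, up_w[-length(up_w)])
    G <- list(
      rb = list(
        list(W = conv_param(3, 3, cc, cc), b = bias_param(cc)),
        list(W = conv_param(3, 3, cc, cc), b = bias_param(cc)),
        list(W = conv_param(3, 3, cc, cc), b = bias_param(cc)),
        list(W = conv_param(3, 3, cc, cc), b = bias_param(cc))),
      up = lapply(seq_len(n_up), function(i)
        list(W = conv_param(3, 3, up_in[i], up_w[i]), b = bias_param(up_w[i]))),
      out = list(W = conv_param(3, 3, up_w[length(up_w)], 3), b = bias_param(3)),
      # style MLP emitting (gain, bias) for 4 AdaIN convs + upsample stages
      sty = local({
        n_mod <- 2L * (4L * cc + sum(up_w))
        list(fc1 = linear_param(64, config$d_s), fb1 = bias_param(64),
             fc2 = linear_param(n_mod, 64), fb2 = bias_param(n_mod))
      }),
      dims = list(cc = cc, up_w = up_w))
    # style encoder: conv trunk (no instance norm: it must see intensity
    # statistics) + per-site linear heads
    es_w <- c(max(4L, w %/% 2L), w, cc, cc)
    ES <- list(trunk = conv_trunk_params(es_w, 3),
               heads = lapply(seq_len(n_sites), function(k)
                 list(W = linear_param(config$d_s, cc), b = bias_param(config$d_s))))
    # style generator: MLP trunk + per-site heads
    GS <- list(fc1 = linear_param(64, config$d_z), fb1 = bias_param(64),
               fc2 = linear_param(64, 64), fb2 = bias_param(64),
               heads = lapply(seq_len(n_sites), function(k)
                 list(W = linear_param(config$d_s, 64), b = bias_param(config$d_s))))
    # discriminator: conv trunk + per-site scalar heads (logits)
    D <- list(trunk = conv_trunk_params(es_w, 3),
              heads = lapply(seq_len(n_sites), function(k)
                list(W = linear_param(1, cc), b = bias_param(1))))
    structure(list(config = config, EC = EC, G = G, ES = ES, GS = GS, D = D),
              class = "model_bundle")
  })
}

# Flatten a nested parameter structure into a list of param environments.
collect_params <- function(x) {
  if (is.environment(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

bundle_param_groups <- function(bundle) {
  list(EC = collect_params(bundle$EC), G = collect_params(bundle$G),
       ES = collect_params(bundle$ES), GS = collect_params(bundle$GS),
       D = collect_params(bundle$D))
}

#' @export
print.model_bundle <- function(x, ...) {
  g <- bundle_param_groups(x)
  counts <- vapply(g, function(ps) sum(vapply(ps, function(p) length(p$value), numeric(1))), numeric(1))
  cat(sprintf("<model_bundle> %d sites, canvas %d, d_s=%d, d_z=%d, width=%d\n",
              x$config$n_sites, x$config$canvas, x$config$d_s, x$config$d_z,
              x$config$width))
  cat("  parameters:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      sprintf("(total %d)\n", sum(counts)))
  invisible(x)
}

# ---- tape-level forward passes -------------------------------------------

check_site <- function(bundle, site) {
  n <- bundle$config$n_sites
  assert_that(is_count(site) && site >= 0 && site < n,
              "site must be an integer in [0, %d)", n)
  as.integer(site) + 1L
}

fwd_EC <- function(tape, bundle, x) {
  h <- x
  for (ly in bundle$EC$trunk) {
    h <- tp_lrelu(tape, tp_instnorm(tape, tp_conv(tape, h, ly$W, ly$b, stride = ly$stride)))
  }
  # residual head without normalization: the code's scale is free to grow,
  # so the training-time perturbation eta ~ N(0, I) stays a perturbation
  # rather than pinning the signal-to-noise ratio at one
  r <- bundle$EC$res
  z <- tp_lrelu(tape, tp_conv(tape, h, r[[1]]$W, r[[1]]$b))
  z <- tp_conv(tape, z, r[[2]]$W, r[[2]]$b)
  tp_scale(tape, tp_add(tape, h, z), bundle$config$content_scale %||% 1)
}

conv_trunk_fwd <- function(tape, layers, x) {
  h <- x
  for (ly in layers) h <- tp_lrelu(tape, tp_conv(tape, h, ly$W, ly$b, stride = 2L))
  h
}

fwd_ES <- function(tape, bundle, x, site1) {
  h <- tp_gap(tape, conv_trunk_fwd(tape, bundle$ES$trunk, x))
  hd <- bundle$ES$heads[[site1]]
  tp_linear(tape, h, hd$W, hd$b)
}

fwd_GS <- function(tape, bundle, z, site1) {
  gs <- bundle$GS
  h <- tp_lrelu(tape, tp_linear(tape, z, gs$fc1, gs$fb1))
  h <- tp_lrelu(tape, tp_linear(tape, h, gs$fc2, gs$fb2))
  hd <- gs$heads[[site1]]
  tp_linear(tape, h, hd$W, hd$b)
}

fwd_D <- function(tape, bundle, x, site1) {
  h <- tp_gap(tape, conv_trunk_fwd(tape, bundle$D$trunk, x))
  hd <- bundle$D$heads[[site1]]
  tp_linear(tape, h, hd$W, hd$b)
}

# Slice consecutive (gain, bias) rows for one modulated stage out of the
# style MLP output (rows = modulation parameters, cols = batch).
mod_slice <- function(tape, mod, from, n) {
  idx_g <- from:(from + n - 1L)
  idx_b <- idx_g + n
  gain <- tp_node(tape, mod$value[idx_g, , drop = FALSE],
                  function(nd) {
                    g <- array(0, dim(mod$value)); g[idx_g, ] <- nd$grad
                    accum_grad(mod, g)
                  })
  bias <- tp_node(tape, mod$value[idx_b, , drop = FALSE],
                  function(nd) {
                    g <- array(0, dim(mod$value)); g[idx_b, ] <- nd$grad
                    accum_grad(mod, g)
                  })
  list(gain = gain, bias = bias, next_from = from + 2L * n)
}

fwd_G <- function(tape, bundle, cnode, snode) {
  G <- bundle$G
  dims <- G$dims
  sty <- G$sty
  h <- tp_lrelu(tape, tp_linear(tape, snode, sty$fc1, sty$fb1))
  mod <- tp_linear(tape, h, sty$fc2, sty$fb2)
  at <- 1L
  adain <- function(x, nch) {
    s <- mod_slice(tape, mod, at, nch)
    at <<- s$next_from
    tp_chanaffine(tape, tp_instnorm(tape, x), s$gain, s$bias)
  }
  cc <- dims$cc
  h <- cnode
  for (rb in 1:2) {
    z <- tp_lrelu(tape, adain(tp_conv(tape, h, G$rb[[2 * rb - 1]]$W, G$rb[[2 * rb - 1]]$b), cc))
    z <- adain(tp_conv(tape, z, G$rb[[2 * rb]]$W, G$rb[[2 * rb]]$b), cc)
    h <- tp_lrelu(tape, tp_add(tape, h, z))
  }
  for (u in seq_along(G$up)) {
    h <- tp_lrelu(tape, adain(tp_conv(tape, tp_upsample2(tape, h), G$up[[u]]$W, G$up[[u]]$b), dims$up_w[u]))
  }
  tp_tanh(tape, tp_scale(tape, tp_conv(tape, h, G$out$W, G$out$b),
                         bundle$config$out_gain %||% 1))
}

# ---- numeric (user-facing) wrappers --------------------------------------

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3) list(x = array(x, c(d, 1)), single = TRUE)
  else if (length(d) == 4) list(x = x, single = FALSE)
  else stopf("expected an HxWx3 slice or an HxWx3xN batch")
}

check_canvas <- function(bundle, x) {
  cv <- bundle$config$canvas
  d <- dim(x)
  if (d[1] != cv || d[2] != cv || d[3] != 3)
    stopf("input is %sx%sx%s; the model expects %dx%dx3", d[1], d[2], d[3], cv, cv)
}

drop_batch <- function(v, single) {
  if (single) array(v, dim(v)[1:3]) else v
}

#' Encode site-invariant content features
#'
#' In training mode the code is perturbed with standard-normal noise
#' (`E^C(x) + eta`); at inference the clean code is returned.
#'
#' @param bundle a [build_models()] bundle
#' @param x canvas-sized HxWx3 slice in [-1, 1], or an HxWx3xN batch
#' @param train_mode add the Gaussian perturbation?
#' @param rng_seed seed for the perturbation draw
#' @return content feature array (Hc x Wc x C (x N))
#' @export
encode_content <- function(bundle, x, train_mode = FALSE, rng_seed = 0L) {
  b <- as_batch(x); check_canvas(bundle, b$x)
  tape <- new_tape()
  out <- fwd_EC(tape, bundle, tp_const(tape, b$x))$value
  if (train_mode) {
    eta <- with_seed(derive_seed(rng_seed, "eta"),
                     array(rnorm(length(out)), dim(out)))
    out <- out + eta
  }
  drop_batch(out, b$single)
}

#' Extract a site-specific style code
#'
#' @param site integer site id in [0, n_sites)
#' @return style matrix (d_s x N), or a length-d_s vector for a single slice
#' @rdname encode_content
#' @export
encode_style <- function(bundle, x, site) {
  s1 <- check_site(bundle, site)
  b <- as_batch(x); check_canvas(bundle, b$x)
  tape <- new_tape()
  v <- fwd_ES(tape, bundle, tp_const(tape, b$x), s1)$value
  if (b$single) drop(v) else v
}

#' Generate a site style code from a latent draw
#'
#' @param z latent vector of length d_z (or d_z x N matrix), standard normal
#' @rdname encode_content
#' @export
generate_style <- function(bundle, z, site) {
  s1 <- check_site(bundle, site)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  assert_that(nrow(z) == bundle$config$d_z, "z must have length d_z = %d", bundle$config$d_z)
  tape <- new_tape()
  v <- fwd_GS(tape, bundle, tp_const(tape, z), s1)$value
  if (ncol(v) == 1) drop(v) else v
}

#' Decode an image from content and style codes
#'
#' @param content content features from [encode_content()]
#' @param style style code from [encode_style()] / [generate_style()]
#' @return canvas-sized HxWx3 image (batch) in [-1, 1]
#' @rdname encode_content
#' @export
decode_image <- function(bundle, content, style) {
  d <- dim(content)
  single <- length(d) == 3
  if (single) content <- array(content, c(d, 1))
  n <- dim(content)[4]
  if (is.null(dim(style))) style <- matrix(style, ncol = n)
  ccd <- bundle$config$canvas / bundle$config$downsampling
  if (dim(content)[1] != ccd || dim(content)[2] != ccd)
    stopf("content map is %dx%d; expected %dx%d", dim(content)[1], dim(content)[2], ccd, ccd)
  assert_that(nrow(style) == bundle$config$d_s, "style must have length d_s = %d", bundle$config$d_s)
  tape <- new_tape()
  v <- fwd_G(tape, bundle, tp_const(tape, content), tp_const(tape, style))$value
  drop_batch(v, single)
}

#' Score images as real for a site branch
#'
#' @return probability-of-real per input (sigmoid-squashed logit)
#' @rdname encode_content
#' @export
discriminate <- function(bundle, x, site) {
  s1 <- check_site(bundle, site)
  b <- as_batch(x); check_canvas(bundle, b$x)
  tape <- new_tape()
  v <- sigmoid(fwd_D(tape, bundle, tp_const(tape, b$x), s1)$value)
  if (b$single) as.numeric(v) else as.numeric(v)
}
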