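# Cycle-translation training: per step, a forward translation of a batch from
# site i into site j (style from the per-site style generator or from
# reference images), a backward translation reconstructing the source, an
# identity reconstruction, and alternating discriminator / generator ADAM
# updates.  Everything is driven by the R RNG, so a (config, data, seed)
# triple reproduces training bitwise.

#' Training configuration
#'
#' @param total_steps number of alternating update steps
#' @param batch_size slices per site per step
#' @param learning_rate ADAM learning rate (default 1e-4)
#' @param seed integer seed driving all training randomness
#' @param weights a [loss_weights()]
#' @param style_source_mix fraction of steps drawing the target style from
#'   reference images (the rest use latent draws through the style generator)
#' @param checkpoint_interval steps between checkpoints (0 = none)
#' @param checkpoint_dir directory for checkpoints
#' @return a `train_config`
#' @export
train_config <- function(total_steps = 1500L, batch_size = 4L,
                         learning_rate = 1e-4, seed = 1L,
                         weights = loss_weights(), style_source_mix = 0.5,
                         checkpoint_interval = 0L, checkpoint_dir = NULL) {
  assert_that(learning_rate >= 0, "learning_rate must be >= 0")
  assert_that(is_count(batch_size) && batch_size >= 1, "batch_size must be >= 1")
  assert_that(style_source_mix >= 0 && style_source_mix <= 1,
              "style_source_mix must be in [0, 1]")
  structure(list(total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 weights = weights, style_source_mix = style_source_mix,
                 checkpoint_interval = as.integer(checkpoint_interval),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

adam_update <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (p in params) {
    g <- p$grad
    p$m[] <- beta1 * p$m + (1 - beta1) * g
    p$v[] <- beta2 * p$v + (1 - beta2) * g * g
    p$value[] <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
    p$grad[] <- 0
  }
  invisible(NULL)
}

#' Sample an ordered pair of distinct sites
#'
#' Uniform over all `n_sites * (n_sites - 1)` ordered pairs, driven by the
#' current RNG state.
#' @param n_sites number of sites (>= 2)
#' @return integer vector (i, j), 0-based site ids, i != j
#' @export
sample_site_pair <- function(n_sites) {
  assert_that(is_count(n_sites) && n_sites >= 2, "need at least 2 sites")
  i <- sample.int(n_sites, 1L)
  j <- sample.int(n_sites - 1L, 1L)
  if (j >= i) j <- j + 1L
  c(i - 1L, j - 1L)
}

#' One CS-DCT training step
#'
#' Forward translation of the site-i batch into site j (latent-path or
#' reference-path style), backward translation reconstructing the source,
#' identity reconstruction, then a discriminator ADAM update (real at branch
#' i, harmonized fake at branch j) followed by a generator-side update with
#' the discriminator frozen.  The per-step random draws (style path, latent
#' codes, content perturbation) come from the current RNG state.
#'
#' @param bundle a [build_models()] bundle (updated in place)
#' @param batch_i canvas x canvas x 3 x N array of site-i slices in [-1, 1]
#' @param batch_j same-shaped array of site-j slices
#' @param site_i,site_j 0-based site ids, distinct
#' @param config a [train_config()]
#' @param state training state (list with `step`); pass the value returned by
#'   the previous call
#' @return list with `report` (a `loss_report` including the discriminator
#'   adversarial value) and `state`
#' @export
cs_dct_step <- function(bundle, batch_i, batch_j, site_i, site_j, config,
                        state = list(step = 0L)) {
  if (site_i == site_j)
    stopf("site_i and site_j must differ (identity translation is handled by the identity loss)")
  s_i1 <- check_site(bundle, site_i)
  s_j1 <- check_site(bundle, site_j)
  cfg <- bundle$config
  wts <- config$weights
  n <- dim(batch_i)[4]

  # shared per-step draws
  use_reference <- runif(1) < config$style_source_mix
  z <- matrix(rnorm(cfg$d_z * n), cfg$d_z, n)
  z2 <- matrix(rnorm(cfg$d_z * n), cfg$d_z, n)
  ccd <- cfg$canvas / cfg$downsampling
  eta <- array(rnorm(ccd * ccd * 2 * cfg$width * n), c(ccd, ccd, 2 * cfg$width, n))

  groups <- bundle_param_groups(bundle)
  gen_params <- c(groups$EC, groups$G, groups$ES, groups$GS)

  # The translation feed-forward uses the perturbed code c_i = E^C(x_i) + eta;
  # the clean code drives the identity decode and the alignment/consistency
  # targets, matching the perturbation-free inference path.
  forward_translation <- function(tape, xi_node) {
    ci_clean <- fwd_EC(tape, bundle, xi_node)
    ci <- tp_add_const(tape, ci_clean, eta)
    sj <- if (use_reference) fwd_ES(tape, bundle, tp_const(tape, batch_j), s_j1)
          else fwd_GS(tape, bundle, tp_const(tape, z), s_j1)
    list(ci = ci, ci_clean = ci_clean, sj = sj, xt = fwd_G(tape, bundle, ci, sj))
  }

  # ---- discriminator phase (generator frozen via stop-gradient) ----
  tapeD <- new_tape()
  xi_nd <- tp_const(tapeD, batch_i)
  fake <- tp_stopgrad(tapeD, forward_translation(tapeD, xi_nd)$xt)
  d_real <- tp_mean_logsig(tapeD, fwd_D(tapeD, bundle, xi_nd, s_i1))
  d_fake <- tp_mean_log1msig(tapeD, fwd_D(tapeD, bundle, fake, s_j1))
  adv_val <- d_real$value + d_fake$value   # the printed adversarial objective
  lossD <- tp_wsum(tapeD, list(d_real, d_fake), c(-1, -1))  # D ascends adv
  tape_backward(tapeD, lossD)
  adam_update(groups$D, config$learning_rate, state$step + 1L)
  zero_grads(gen_params)   # stop-gradient makes these zero already; be safe

  # ---- generator phase (discriminator frozen) ----
  tapeG <- new_tape()
  xi_nd <- tp_const(tapeG, batch_i)
  ft <- forward_translation(tapeG, xi_nd)
  g_adv <- tp_mean_logsig(tapeG, fwd_D(tapeG, bundle, ft$xt, s_j1))  # non-saturating
  ct_j <- fwd_EC(tapeG, bundle, ft$xt)                 # clean re-encoding
  st_j <- fwd_ES(tapeG, bundle, ft$xt, s_j1)
  s_i <- fwd_ES(tapeG, bundle, xi_nd, s_i1)
  x_hat <- fwd_G(tapeG, bundle, ct_j, s_i)
  x_bar <- fwd_G(tapeG, bundle, ft$ci_clean, s_i)

  l_cont <- tp_l1(tapeG, ft$ci_clean, ct_j)
  l_ca <- tp_half_mean_sq(tapeG, ft$ci_clean)
  l_sty <- if (cfg$sty_literal) tp_l1(tapeG, s_i, st_j) else tp_l1(tapeG, ft$sj, st_j)
  l_cyc_pix <- tp_l1(tapeG, xi_nd, x_hat)
  l_cyc_grad <- tp_wsum(tapeG,
                        list(tp_l1(tapeG, tp_fdiff(tapeG, xi_nd, 1), tp_fdiff(tapeG, x_hat, 1)),
                             tp_l1(tapeG, tp_fdiff(tapeG, xi_nd, 2), tp_fdiff(tapeG, x_hat, 2))),
                        c(0.5, 0.5))
  l_id <- tp_l1(tapeG, xi_nd, x_bar)

  if (!use_reference) {
    sj2 <- fwd_GS(tapeG, bundle, tp_const(tapeG, z2), s_j1)
    xt2 <- fwd_G(tapeG, bundle, ft$ci, sj2)
    l_sd <- tp_clip_max(tapeG, tp_l1(tapeG, ft$xt, xt2), cfg$sd_clip)
  } else {
    l_sd <- tp_const(tapeG, 0)
  }
  sd_sign <- if (cfg$sd_literal) 1 else -1
  lossG <- tp_wsum(tapeG,
                   list(g_adv, l_cont, l_ca, l_sd, l_sty, l_cyc_pix, l_cyc_grad, l_id),
                   c(-wts$lambda_adv, wts$lambda_cont, wts$lambda_ca,
                     sd_sign * wts$lambda_sd, wts$lambda_sty,
                     wts$lambda_cyc, wts$lambda_cyc * wts$lambda_g, wts$lambda_id))
  tape_backward(tapeG, lossG)
  adam_update(gen_params, config$learning_rate, state$step + 1L)
  zero_grads(groups$D)     # frozen this phase: discard its gradients

  terms <- list(adv = adv_val, cont = l_cont$value, ca = l_ca$value,
                sd = l_sd$value, sty = l_sty$value,
                cyc = l_cyc_pix$value + wts$lambda_g * l_cyc_grad$value,
                id = l_id$value)
  report <- total_loss(terms, wts, sd_literal = cfg$sd_literal)
  report$g_objective <- lossG$value
  report$path <- if (use_reference) "reference" else "latent"
  list(report = report, state = list(step = state$step + 1L))
}

# Preprocess a phantom sample / slice25d into a canvas-sized [-1,1] array.
slice_to_input <- function(x, canvas) {
  s <- if (inherits(x, "slice25d")) x
       else if (inherits(x, "phantom_sample")) as_slice25d(x$image, site_id = x$site_id)
       else as_slice25d(x)
  prep_slice(s, canvas)$pixels
}

# Stack preprocessed slices into a batch array.
stack_batch <- function(inputs) {
  d <- dim(inputs[[1]])
  out <- array(0, c(d, length(inputs)))
  for (k in seq_along(inputs)) out[, , , k] <- inputs[[k]]
  out
}

#' Fit the harmonization model
#'
#' Trains the five-network bundle with alternating discriminator/generator
#' updates over uniformly sampled ordered site pairs, mixing latent-path and
#' reference-path target styles.  Training data may be a
#' [make_dataset()] object or a list (one element per site) of
#' `phantom_sample`/`slice25d`/matrix slices.
#'
#' @param data training data (see above)
#' @param config a [train_config()]
#' @param model_cfg a [model_config()]; `n_sites` defaults to the data
#' @param init_seed seed for the parameter initialization
#' @param verbose print progress every 100 steps?
#' @return a fitted `styleharm` model: the bundle, configs, and the full loss
#'   history (one `loss_report` row per step)
#' @export
harmonize_fit <- function(data, config = train_config(), model_cfg = NULL,
                          init_seed = NULL, verbose = FALSE) {
  site_lists <- if (inherits(data, "site_dataset")) data$train else data
  n_sites <- length(site_lists)
  assert_that(n_sites >= 2, "need training data for at least 2 sites")
  assert_that(all(vapply(site_lists, length, integer(1)) >= 1),
              "every site needs at least 1 training sample")
  model_cfg <- model_cfg %||% model_config(n_sites = n_sites)
  assert_that(model_cfg$n_sites == n_sites,
              "model_cfg$n_sites (%d) must match the data (%d sites)",
              model_cfg$n_sites, n_sites)
  bundle <- build_models(model_cfg, seed = init_seed %||% config$seed)
  inputs <- lapply(site_lists, function(ss)
    lapply(ss, slice_to_input, canvas = model_cfg$canvas))

  state <- list(step = 0L)
  history <- vector("list", config$total_steps)
  set.seed(derive_seed(config$seed, "train"))
  for (step in seq_len(config$total_steps)) {
    pair <- sample_site_pair(n_sites)
    bi <- stack_batch(sample(inputs[[pair[1] + 1L]], config$batch_size, replace = TRUE))
    bj <- stack_batch(sample(inputs[[pair[2] + 1L]], config$batch_size, replace = TRUE))
    res <- cs_dct_step(bundle, bi, bj, pair[1], pair[2], config, state)
    state <- res$state
    if (!is.finite(res$report$total))
      stopf("training diverged at step %d (non-finite total loss)", step)
    history[[step]] <- c(step = step, site_i = pair[1], site_j = pair[2],
                         res$report[c("adv", "cont", "ca", "sd", "sty", "cyc", "id", "total")])
    if (verbose && step %% 100 == 0)
      message(sprintf("step %d/%d  total=%.3f cyc=%.3f id=%.3f adv=%.3f",
                      step, config$total_steps, res$report$total,
                      res$report$cyc, res$report$id, res$report$adv))
    if (config$checkpoint_interval > 0 && !is.null(config$checkpoint_dir) &&
        step %% config$checkpoint_interval == 0) {
      save_checkpoint(structure(list(bundle = bundle, config = config,
                                     model_cfg = model_cfg, state = state),
                                class = "styleharm"),
                      file.path(config$checkpoint_dir, sprintf("step-%06d.rds", step)))
    }
  }
  hist_df <- if (config$total_steps > 0)
    as.data.frame(do.call(rbind, lapply(history, function(h) unlist(h))))
  else data.frame()
  structure(list(bundle = bundle, config = config, model_cfg = model_cfg,
                 state = state, history = hist_df),
            class = "styleharm")
}

#' Save / restore a training checkpoint
#'
#' Checkpoints capture all parameter values, optimizer moments, the step
#' counter and the RNG state, so a restored run continues bitwise identically
#' to an uninterrupted one.
#'
#' @param model a `styleharm` model (or the in-progress equivalent)
#' @param path .rds file path
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  groups <- bundle_param_groups(model$bundle)
  params <- lapply(groups, function(ps) lapply(ps, function(p)
    list(value = p$value, m = p$m, v = p$v)))
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(params = params, config = model$config,
               model_cfg = model$model_cfg, state = model$state,
               history = model$history, rng = rng), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  bundle <- build_models(ck$model_cfg, seed = 1L)
  groups <- bundle_param_groups(bundle)
  for (g in names(groups)) {
    saved <- ck$params[[g]]
    for (k in seq_along(groups[[g]])) {
      groups[[g]][[k]]$value <- saved[[k]]$value
      groups[[g]][[k]]$m <- saved[[k]]$m
      groups[[g]][[k]]$v <- saved[[k]]$v
      groups[[g]][[k]]$grad[] <- 0
    }
  }
  structure(list(bundle = bundle, config = ck$config, model_cfg = ck$model_cfg,
                 state = ck$state, history = ck$history, rng = ck$rng),
            class = "styleharm")
}

#' Continue training from a restored checkpoint
#'
#' @param model a restored `styleharm` (from [load_checkpoint()])
#' @param data the same training data
#' @param extra_steps steps to run
#' @export
resume_fit <- function(model, data, extra_steps) {
  site_lists <- if (inherits(data, "site_dataset")) data$train else data
  inputs <- lapply(site_lists, function(ss)
    lapply(ss, slice_to_input, canvas = model$model_cfg$canvas))
  if (!is.null(model$rng)) assign(".Random.seed", model$rng, envir = globalenv())
  state <- model$state
  config <- model$config
  history <- list()
  for (k in seq_len(extra_steps)) {
    pair <- sample_site_pair(length(inputs))
    bi <- stack_batch(sample(inputs[[pair[1] + 1L]], config$batch_size, replace = TRUE))
    bj <- stack_batch(sample(inputs[[pair[2] + 1L]], config$batch_size, replace = TRUE))
    res <- cs_dct_step(model$bundle, bi, bj, pair[1], pair[2], config, state)
    state <- res$state
    history[[k]] <- c(step = state$step, site_i = pair[1], site_j = pair[2],
                      res$report[c("adv", "cont", "ca", "sd", "sty", "cyc", "id", "total")])
  }
  model$state <- state
  hd <- as.data.frame(do.call(rbind, lapply(history, unlist)))
  model$history <- rbind(model$history, hd)
  model
}
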