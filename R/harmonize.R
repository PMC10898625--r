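# Inference: harmonize a volume (or a single phantom slice) to a target
# site's sampled style, to a reference image's extracted style, to its own
# site (identity translation), or along a continuous style interpolation
# path.  No content perturbation is applied at inference.

check_trained <- function(bundle) {
  ok <- all(vapply(collect_params(bundle), function(p) all(is.finite(p$value)), logical(1)))
  if (!ok) stopf("model has non-finite parameters; cannot harmonize")
}

get_bundle <- function(model) {
  if (inherits(model, "styleharm")) model$bundle
  else if (inherits(model, "model_bundle")) model
  else stopf("model must be a fitted styleharm object or a model_bundle")
}

# Apply one style vector to every slice of the input; input may be an
# mr_volume, a phantom_sample, a slice25d, or a plain 2-D matrix.  Returns
# the same kind of object, harmonized.  For volumes, each 2.5D window's
# center channel is kept and reassembled; padding and normalization are
# inverted with the source slice's records.
apply_style <- function(bundle, input, style, n_central = NULL, chunk = 16L) {
  cv <- bundle$config$canvas
  if (inherits(input, "mr_volume")) {
    slices <- if (dim(input$voxels)[3] >= 3)
      lapply(extract_slices_25d(input, n_central), prep_slice, canvas = cv)
    else  # thin volume: each axial slice as a degenerate 2.5D window
      lapply(seq_len(dim(input$voxels)[3]), function(ci)
        prep_slice(as_slice25d(input$voxels[, , ci], site_id = input$site_id,
                               volume_id = input$volume_id, center_index = ci),
                   canvas = cv))
    outs <- slices
    for (start in seq(1, length(slices), by = chunk)) {
      idx <- start:min(start + chunk - 1L, length(slices))
      x <- stack_batch(lapply(slices[idx], function(s) s$pixels))
      co <- encode_content(bundle, x)
      y <- decode_image(bundle, co, matrix(style, nrow = length(style), ncol = length(idx)))
      if (length(dim(y)) == 3) y <- array(y, c(dim(y), 1))
      for (k in seq_along(idx)) outs[[idx[k]]]$pixels <- y[, , , k]
    }
    return(reassemble_volume(outs, input))
  }
  img2d <- inherits(input, "phantom_sample") || is.matrix(input)
  s <- if (inherits(input, "slice25d")) input
       else if (inherits(input, "phantom_sample")) as_slice25d(input$image, site_id = input$site_id)
       else as_slice25d(input)
  sp <- prep_slice(s, cv)
  co <- encode_content(bundle, sp$pixels)
  y <- decode_image(bundle, co, style)
  if (img2d) {
    ych <- crop_back(sp, array(y[, , 2], c(dim(y)[1:2], 1)))
    out <- denormalize_channels(sp, array(ych, c(dim(ych), 1)))
    if (inherits(input, "phantom_sample")) {
      res <- input; res$image <- out; return(res)
    }
    return(out)
  }
  sp$pixels <- y
  sp
}

#' Harmonize with an explicit style code
#'
#' Low-level worker behind all harmonization modes: applies one style vector
#' to every slice of the input.
#'
#' @param style a length-d_s style vector
#' @rdname harmonize_to_site
#' @export
harmonize_with_style <- function(model, input, style, n_central = NULL) {
  bundle <- get_bundle(model)
  check_trained(bundle)
  assert_that(length(style) == bundle$config$d_s,
              "style must have length d_s = %d", bundle$config$d_s)
  apply_style(bundle, input, style, n_central = n_central)
}

#' Harmonize to a target site with sampled styles
#'
#' Draws `n_styles` latent codes, maps each through the target site's style
#' generator (one style shared across all slices of the input per draw) and
#' decodes the input's content under each style.
#'
#' @param model fitted `styleharm` model (or a `model_bundle`)
#' @param input an [mr_volume()], `phantom_sample`, `slice25d`, or 2-D matrix
#' @param target_site 0-based site id
#' @param n_styles number of style draws (>= 1)
#' @param seed seed for the latent draws
#' @param n_central for volumes: restrict to this central band of slices
#' @return a list of `n_styles` harmonized objects (same kind as the input)
#' @export
harmonize_to_site <- function(model, input, target_site, n_styles = 1L,
                              seed = 1L, n_central = NULL) {
  bundle <- get_bundle(model)
  check_trained(bundle)
  check_site(bundle, target_site)
  assert_that(is_count(n_styles) && n_styles >= 1, "n_styles must be >= 1")
  zs <- with_seed(derive_seed(seed, "site-styles"),
                  matrix(rnorm(bundle$config$d_z * n_styles), bundle$config$d_z, n_styles))
  lapply(seq_len(n_styles), function(k) {
    s <- generate_style(bundle, zs[, k], target_site)
    apply_style(bundle, input, s, n_central = n_central)
  })
}

#' Harmonize to the style of a reference image
#'
#' The style is extracted once from the reference (its central 2.5D slice for
#' a volume) through the reference site's style-encoder branch and applied to
#' all slices of the input.
#'
#' @param reference reference image (same kinds as `input`)
#' @param reference_site 0-based site id of the reference's style branch
#' @rdname harmonize_to_site
#' @export
harmonize_to_reference <- function(model, input, reference, reference_site,
                                   n_central = NULL) {
  bundle <- get_bundle(model)
  check_trained(bundle)
  check_site(bundle, reference_site)
  if (missing(reference) || is.null(reference)) stopf("reference image is required")
  s <- extract_reference_style(bundle, reference, reference_site)
  apply_style(bundle, input, s, n_central = n_central)
}

extract_reference_style <- function(bundle, reference, site) {
  cv <- bundle$config$canvas
  rs <- if (inherits(reference, "mr_volume")) {
    d <- dim(reference$voxels)
    if (d[3] >= 3) extract_slices_25d(reference, n_central = 1L)[[1]]
    else as_slice25d(reference$voxels[, , (d[3] + 1L) %/% 2L])
  } else if (inherits(reference, "slice25d")) reference
  else if (inherits(reference, "phantom_sample")) as_slice25d(reference$image)
  else as_slice25d(reference)
  encode_style(bundle, prep_slice(rs, cv)$pixels, site)
}

#' Identity translation (harmonize to the own site)
#'
#' Decodes each slice from its own content and own extracted style; with a
#' fully disentangled model this reproduces the input.
#'
#' @param own_site the input's 0-based site id
#' @rdname harmonize_to_site
#' @export
identity_translate <- function(model, input, own_site, n_central = NULL) {
  bundle <- get_bundle(model)
  check_trained(bundle)
  check_site(bundle, own_site)
  declared <- if (inherits(input, "mr_volume") || inherits(input, "phantom_sample"))
    input$site_id else NA
  if (!is.na(declared) && declared != own_site)
    warning(sprintf("input is labelled site %s but own_site=%s; proceeding with own_site",
                    declared, own_site))
  s <- extract_reference_style(bundle, input, own_site)
  apply_style(bundle, input, s, n_central = n_central)
}

#' Convex interpolation of two style codes
#'
#' `(1 - beta) * s_a + beta * s_b` with `beta` in [0, 1].
#'
#' @param s_a,s_b style vectors of equal length
#' @param beta interpolation weight in [0, 1]
#' @export
interpolate_styles <- function(s_a, s_b, beta) {
  assert_that(is.numeric(beta) && length(beta) == 1 && beta >= 0 && beta <= 1,
              "beta must be a scalar in [0, 1]")
  assert_that(length(s_a) == length(s_b), "style codes must have equal length")
  (1 - beta) * s_a + beta * s_b
}

#' Continuous harmonization between two site styles
#'
#' Generates one output per `beta`, all sharing the input's content codes;
#' the endpoints (beta 0 and 1) equal the harmonizations with the site-A and
#' site-B styles themselves.
#'
#' @param site_a,site_b 0-based site ids of the two endpoint styles
#' @param betas nondecreasing values in [0, 1]
#' @param styles optional list(s_a, s_b) of endpoint styles; by default one
#'   seeded latent draw per site through the style generators
#' @rdname harmonize_to_site
#' @export
continuous_harmonize <- function(model, input, site_a, site_b, betas,
                                 seed = 1L, styles = NULL, n_central = NULL) {
  bundle <- get_bundle(model)
  check_trained(bundle)
  check_site(bundle, site_a); check_site(bundle, site_b)
  assert_that(length(betas) >= 1, "betas must be non-empty")
  assert_that(all(betas >= 0 & betas <= 1), "betas must lie in [0, 1]")
  if (is.null(styles)) {
    za <- with_seed(derive_seed(seed, "beta-a"), rnorm(bundle$config$d_z))
    zb <- with_seed(derive_seed(seed, "beta-b"), rnorm(bundle$config$d_z))
    styles <- list(generate_style(bundle, za, site_a),
                   generate_style(bundle, zb, site_b))
  }
  lapply(betas, function(b) {
    apply_style(bundle, input, interpolate_styles(styles[[1]], styles[[2]], b),
                n_central = n_central)
  })
}
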