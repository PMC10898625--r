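# S3 methods for the fitted model object.

#' @export
print.styleharm <- function(x, ...) {
  cat(sprintf("Multi-site harmonization model (%d sites, canvas %d)\n",
              x$model_cfg$n_sites, x$model_cfg$canvas))
  cat(sprintf("  trained %d steps, lr %g, batch %d, style mix %.2f\n",
              x$state$step, x$config$learning_rate, x$config$batch_size,
              x$config$style_source_mix))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  last step: cyc=%.3f id=%.3f adv=%.3f total=%.3f\n",
                last$cyc, last$id, last$adv, last$total))
  }
  invisible(x)
}

#' @export
summary.styleharm <- function(object, tail_frac = 0.1, ...) {
  h <- object$history
  counts <- vapply(bundle_param_groups(object$bundle), function(ps)
    sum(vapply(ps, function(p) length(p$value), numeric(1))), numeric(1))
  out <- list(n_sites = object$model_cfg$n_sites,
              canvas = object$model_cfg$canvas,
              steps = object$state$step,
              param_counts = counts)
  if (nrow(h) > 0) {
    k <- max(1L, floor(nrow(h) * tail_frac))
    tail_h <- h[(nrow(h) - k + 1):nrow(h), ]
    out$recent_means <- colMeans(tail_h[, c("adv", "cont", "ca", "sd", "sty", "cyc", "id", "total")])
  }
  class(out) <- "summary.styleharm"
  out
}

#' @export
print.summary.styleharm <- function(x, ...) {
  cat(sprintf("styleharm model: %d sites, canvas %d, %d training steps\n",
              x$n_sites, x$canvas, x$steps))
  cat("parameters:", paste(sprintf("%s=%d", names(x$param_counts), x$param_counts),
                           collapse = ", "), "\n")
  if (!is.null(x$recent_means)) {
    cat("recent loss means:\n")
    print(round(x$recent_means, 4))
  }
  invisible(x)
}

#' Harmonize new data with a fitted model
#'
#' Dispatches on `mode`: `"site"` ([harmonize_to_site()]), `"reference"`
#' ([harmonize_to_reference()]), `"identity"` ([identity_translate()]) or
#' `"interpolation"` ([continuous_harmonize()]).
#'
#' @param object a fitted `styleharm` model
#' @param newdata an [mr_volume()], `phantom_sample`, `slice25d` or matrix
#' @param mode harmonization mode
#' @param ... arguments of the mode's worker function
#' @export
predict.styleharm <- function(object, newdata,
                              mode = c("site", "reference", "identity", "interpolation"),
                              ...) {
  mode <- match.arg(mode)
  switch(mode,
         site = harmonize_to_site(object, newdata, ...),
         reference = harmonize_to_reference(object, newdata, ...),
         identity = identity_translate(object, newdata, ...),
         interpolation = continuous_harmonize(object, newdata, ...))
}

#' Plot the training loss history
#'
#' @param x a fitted `styleharm` model
#' @param terms which loss terms to draw
#' @param ... passed to [graphics::matplot()]
#' @export
plot.styleharm <- function(x, terms = c("cyc", "id", "cont", "sty"), ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$step, h[, terms, drop = FALSE], type = "l", lty = 1,
                    xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", legend = terms, col = seq_along(terms), lty = 1, bty = "n")
  invisible(x)
}
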