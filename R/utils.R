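# Shared numeric helpers: separable Gaussian filtering, smooth random fields,
# small assertion utilities.  All deterministic given the R RNG state.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' @noRd
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1-D Gaussian kernel, truncated at 3 sigma, normalized to sum 1.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 2-D matrix with edge replication.
# Implemented as banded matrix products so it is exact and fast at desk scale.
blur2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gauss_kernel(sigma)
  x <- apply_kernel_rows(x, k)
  t(apply_kernel_rows(t(x), k))
}

# Convolve each column of x with kernel k (odd length), replicating edges.
apply_kernel_rows <- function(x, k) {
  n <- nrow(x)
  r <- (length(k) - 1L) / 2L
  idx <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (i in seq_along(k)) {
    out <- out + k[i] * xp[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

# Smooth random field in [-1, 1]-ish range: white noise blurred to a given
# correlation length then rescaled to unit max amplitude.
smooth_field <- function(shape, scale) {
  z <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  f <- blur2d(z, scale)
  m <- max(abs(f))
  if (m == 0) f else f / m
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)

# Draw a derived 31-bit seed from a base seed and a stream label, so that
# independent components get independent, reproducible RNG streams.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(paste0(stream, ":", seed)) * seq_len(nchar(stream) + nchar(as.character(seed)) + 1L) * 2654435761)
  as.integer(abs(h) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
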