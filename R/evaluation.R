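# Quantitative evaluation: paired fidelity metrics, distributional distances
# on a fixed seeded image embedding, an internal 3-class tissue segmenter,
# tissue-volume distributions, and an edge-sharpness measure for the
# cross-resolution analysis.

#' Mean absolute error
#' @param x,y equal-shaped numeric arrays
#' @export
mae <- function(x, y) {
  check_same_shape(x, y)
  mean(abs(x - y))
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(peak^2 / MSE)`, capped when the images are identical.
#' @param peak data range (2 for data in [-1, 1])
#' @param cap returned value when MSE = 0 (default 100 dB)
#' @rdname mae
#' @export
psnr <- function(x, y, peak = 2, cap = 100) {
  check_same_shape(x, y)
  mse <- mean((x - y)^2)
  if (mse == 0) return(cap)
  min(10 * log10(peak^2 / mse), cap)
}

# Single-scale SSIM mean and contrast-structure mean, Gaussian window.
ssim_cs <- function(x, y, peak, sigma = 1.5) {
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  mu_x <- blur2d(x, sigma); mu_y <- blur2d(y, sigma)
  sxx <- blur2d(x * x, sigma) - mu_x^2
  syy <- blur2d(y * y, sigma) - mu_y^2
  sxy <- blur2d(x * y, sigma) - mu_x * mu_y
  l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  c(ssim = mean(l * cs), cs = mean(cs))
}

downsample2 <- function(x) {
  h <- 2 * (nrow(x) %/% 2); w <- 2 * (ncol(x) %/% 2)
  x <- x[seq_len(h), seq_len(w)]
  0.25 * (x[seq(1, h, 2), seq(1, w, 2)] + x[seq(2, h, 2), seq(1, w, 2)] +
          x[seq(1, h, 2), seq(2, w, 2)] + x[seq(2, h, 2), seq(2, w, 2)])
}

#' Multi-scale structural similarity
#'
#' Standard MS-SSIM with the conventional 5-scale weights; the number of
#' scales adapts to the image size (each scale halves the resolution and the
#' coarsest scale keeps at least ~8 pixels per axis), with the weights
#' renormalized.
#' @rdname mae
#' @export
ms_ssim <- function(x, y, peak = 2) {
  check_same_shape(x, y)
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  n_scales <- max(1L, min(5L, floor(log2(min(dim(x)) / 8)) + 1L))
  w <- w5[seq_len(n_scales)] / sum(w5[seq_len(n_scales)])
  vals <- numeric(n_scales)
  for (s in seq_len(n_scales)) {
    m <- ssim_cs(x, y, peak)
    vals[s] <- if (s == n_scales) m["ssim"] else m["cs"]
    if (s < n_scales) { x <- downsample2(x); y <- downsample2(y) }
  }
  # clamp tiny negative cs values before the weighted geometric mean
  prod(pmax(vals, 1e-8)^w)
}

#' Dice similarity coefficient for one tissue class
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both label sets are empty.
#' @param mask_a,mask_b integer label arrays of equal shape
#' @param class_id label value to compare
#' @export
dsc <- function(mask_a, mask_b, class_id) {
  check_same_shape(mask_a, mask_b)
  a <- mask_a == class_id
  b <- mask_b == class_id
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Largest 4-connected component of a logical matrix.
largest_component <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  cur <- 0L
  best_id <- 0L; best_n <- 0L
  idx_all <- which(fg & lab == 0L)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- integer(sum(fg)); queue[1] <- start; qn <- 1L; qh <- 1L
    lab[start] <- cur
    count <- 0L
    while (qh <= qn) {
      p <- queue[qh]; qh <- qh + 1L; count <- count + 1L
      r <- ((p - 1L) %% h) + 1L
      cl <- ((p - 1L) %/% h) + 1L
      for (nb in c(if (r > 1) p - 1L, if (r < h) p + 1L,
                   if (cl > 1) p - h, if (cl < w) p + h)) {
        if (fg[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          qn <- qn + 1L; queue[qn] <- nb
        }
      }
    }
    if (count > best_n) { best_n <- count; best_id <- cur }
  }
  lab == best_id
}

#' Segment a phantom image into background + 3 tissue classes
#'
#' Background is separated by an intensity floor (a fraction of the image
#' range above the minimum) followed by a largest-connected-component mask;
#' the three tissue classes are obtained by 3-means clustering of foreground
#' intensities (deterministic quantile initialization) and relabelled in
#' ascending mean-intensity order, so labels are invariant to positive
#' intensity scaling.
#'
#' @param image single-channel intensity matrix
#' @param floor_frac background threshold as a fraction of the range
#' @return integer mask (0 = background, 1..3 = tissues, ascending intensity)
#' @export
segment_phantom <- function(image, floor_frac = 0.12) {
  assert_that(is.matrix(image), "image must be a single-channel matrix")
  rng <- range(image)
  if (rng[1] == rng[2]) stopf("segmentation degenerate: constant image")
  thr <- rng[1] + floor_frac * (rng[2] - rng[1])
  fg <- largest_component(image > thr)
  vals <- image[fg]
  if (length(unique(vals)) < 3) stopf("segmentation degenerate: fewer than 3 foreground intensity levels")
  centers <- unique(quantile(vals, c(0.15, 0.5, 0.85), names = FALSE))
  if (length(centers) < 3)
    centers <- seq(min(vals), max(vals), length.out = 3)
  km <- suppressWarnings(kmeans(vals, centers = matrix(centers, ncol = 1),
                                iter.max = 50, algorithm = "Lloyd"))
  ord <- order(km$centers)
  relab <- integer(3); relab[ord] <- 1:3
  out <- matrix(0L, nrow(image), ncol(image))
  out[fg] <- relab[km$cluster]
  out
}

#' Fixed seeded image embedding for distributional metrics
#'
#' A deterministic, seeded, untrained convolutional feature extractor used by
#' [fid()]/[kid()].  Each input image is min-max normalized to [-1, 1],
#' passed through three strided random convolutions with leaky-ReLU, and
#' globally average-pooled to a `d_f`-dimensional vector.  A pretrained
#' embedding can be substituted anywhere a feature matrix is accepted.
#'
#' @param seed construction seed
#' @param d_f embedding dimension
#' @return an `embedding_model`
#' @export
embedding_model <- function(seed = 42L, d_f = 32L) {
  with_seed(derive_seed(seed, "embed"), {
    w <- list(
      list(W = conv_param(3, 3, 1, 8), b = bias_param(8)),
      list(W = conv_param(3, 3, 8, 16), b = bias_param(16)),
      list(W = conv_param(3, 3, 16, d_f), b = bias_param(d_f)))
    structure(list(layers = w, d_f = as.integer(d_f), seed = seed),
              class = "embedding_model")
  })
}

#' @rdname embedding_model
#' @param emb an `embedding_model`
#' @param images list of matrices (or one 3-D array stacked on axis 3)
#' @return numeric matrix, one feature row per image
#' @export
embed_images <- function(emb, images) {
  assert_that(inherits(emb, "embedding_model"), "emb must be an embedding_model")
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  if (is.matrix(images)) images <- list(images)
  feats <- lapply(images, function(im) {
    r <- range(im)
    x <- if (r[2] > r[1]) 2 * (im - r[1]) / (r[2] - r[1]) - 1 else im * 0
    h <- array(x, c(dim(x), 1, 1))
    for (ly in emb$layers) {
      h <- conv2d_fwd_cpp(h, ly$W$value, ly$b$value, 2L, 1L)
      h <- pmax(h, 0) + 0.2 * pmin(h, 0)
    }
    colMeans(matrix(h, dim(h)[1] * dim(h)[2], dim(h)[3]))
  })
  do.call(rbind, feats)
}

#' Frechet distance between two feature sets
#'
#' `||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})` on the feature
#' means and covariances; the matrix square root uses an eigen-decomposition
#' with negative eigenvalues clipped at zero.
#'
#' @param features_a,features_b numeric matrices (rows = samples)
#' @export
fid <- function(features_a, features_b) {
  assert_that(nrow(features_a) >= 2 && nrow(features_b) >= 2,
              "need at least 2 feature vectors per set")
  mu_a <- colMeans(features_a); mu_b <- colMeans(features_b)
  S_a <- cov(features_a); S_b <- cov(features_b)
  ev <- eigen(S_a %*% S_b, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(Re(ev), 0)))
  sum((mu_a - mu_b)^2) + sum(diag(S_a)) + sum(diag(S_b)) - 2 * tr_sqrt
}

#' Kernel distance (unbiased polynomial-kernel MMD^2)
#'
#' Kernel `k(x, y) = (x . y / d + 1)^3` with the unbiased two-sample MMD^2
#' estimator.
#' @rdname fid
#' @export
kid <- function(features_a, features_b) {
  m <- nrow(features_a); n <- nrow(features_b)
  assert_that(m >= 2 && n >= 2, "need at least 2 feature vectors per set")
  d <- ncol(features_a)
  Kaa <- (features_a %*% t(features_a) / d + 1)^3
  Kbb <- (features_b %*% t(features_b) / d + 1)^3
  Kab <- (features_a %*% t(features_b) / d + 1)^3
  (sum(Kaa) - sum(diag(Kaa))) / (m * (m - 1)) +
    (sum(Kbb) - sum(diag(Kbb))) / (n * (n - 1)) -
    2 * mean(Kab)
}

#' Tissue-volume distributions by group
#'
#' Computes per-class tissue volumes (voxel count times voxel volume) for
#' each mask, summarizes medians and quartiles per group, and tests the
#' between-group distribution difference per class (Wilcoxon rank-sum for two
#' groups, Kruskal-Wallis otherwise).
#'
#' @param masks list of integer masks
#' @param groups group label per mask
#' @param voxel_volume volume per voxel (e.g. mm^3)
#' @param classes tissue classes to report
#' @return list with `volumes` (data.frame), `summary` (per group x class)
#'   and `tests` (per class statistic and p-value)
#' @export
volumetric_distributions <- function(masks, groups, voxel_volume = 1,
                                     classes = 1:3) {
  assert_that(length(masks) == length(groups), "one group label per mask")
  assert_that(length(masks) >= 1 && all(table(groups) >= 1), "groups must be non-empty")
  vols <- do.call(rbind, lapply(seq_along(masks), function(i) {
    data.frame(group = groups[i], class = classes,
               volume = vapply(classes, function(k) sum(masks[[i]] == k) * voxel_volume,
                               numeric(1)))
  }))
  summ <- do.call(rbind, lapply(split(vols, list(vols$group, vols$class)), function(df) {
    q <- quantile(df$volume, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = df$group[1], class = df$class[1], n = nrow(df),
               q25 = q[1], median = q[2], q75 = q[3])
  }))
  rownames(summ) <- NULL
  tests <- lapply(classes, function(k) {
    v <- vols[vols$class == k, ]
    if (length(unique(groups)) == 2) {
      sp <- split(v$volume, v$group)
      if (identical(sp[[1]], sp[[2]]))
        return(list(class = k, statistic = 0, p_value = 1))
      wt <- suppressWarnings(wilcox.test(sp[[1]], sp[[2]]))
      list(class = k, statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      kt <- suppressWarnings(stats::kruskal.test(v$volume, factor(v$group)))
      list(class = k, statistic = unname(kt$statistic), p_value = kt$p.value)
    }
  })
  list(volumes = vols, summary = summ, tests = tests)
}

#' Edge transition width of an image
#'
#' A blur-sensitive sharpness proxy: for every row whose intensity range is a
#' substantial fraction of the image range, the ratio of the row's robust
#' intensity range to its maximum absolute finite difference estimates the
#' 10-90% transition width of the strongest edge; the median over selected
#' rows (and columns) is returned.  Larger values mean blurrier edges.
#'
#' @param image intensity matrix
#' @return edge width in pixels (scaled ratio)
#' @export
edge_transition_width <- function(image) {
  width_1d <- function(m) {
    rng <- apply(m, 1, function(r) diff(range(r)))
    keep <- rng > 0.5 * max(rng)
    vapply(which(keep), function(i) {
      r <- m[i, ]
      g <- max(abs(diff(r)))
      if (g == 0) return(NA_real_)
      0.8 * diff(quantile(r, c(0.05, 0.95), names = FALSE)) / g
    }, numeric(1))
  }
  vals <- c(width_1d(image), width_1d(t(image)))
  median(vals, na.rm = TRUE)
}
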