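#' Volume container
#'
#' A light wrapper around a 3-D intensity array: voxels, voxel spacing in mm,
#' an optional integer site label and a volume identifier.  The third array
#' axis is the axial (slice) axis.
#'
#' @param voxels 3-D numeric array
#' @param spacing positive mm-per-voxel for the three axes
#' @param site_id integer site label or NA
#' @param volume_id identifier string
#' @return an `mr_volume` object
#' @export
mr_volume <- function(voxels, spacing = c(1, 1, 1), site_id = NA_integer_,
                      volume_id = "vol") {
  assert_that(length(dim(voxels)) == 3, "voxels must have exactly 3 axes")
  assert_that(all(is.finite(voxels)), "voxels must be finite")
  assert_that(length(spacing) == 3 && all(spacing > 0), "spacing must be 3 positive values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 site_id = site_id, volume_id = volume_id),
            class = "mr_volume")
}

#' @export
print.mr_volume <- function(x, ...) {
  cat(sprintf("<mr_volume '%s'> %s voxels, spacing %s mm, site %s\n",
              x$volume_id, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              ifelse(is.na(x$site_id), "?", x$site_id)))
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' @param path a .nii or .nii.gz file
#' @param site_id,volume_id metadata attached on load (not stored in NIfTI)
#' @param promote_2d treat a 2-D image as a single-slice 3-D volume?
#' @return `load_volume`: an [mr_volume()]; `save_volume`: the path, invisibly
#' @export
load_volume <- function(path, site_id = NA_integer_, volume_id = NULL,
                        promote_2d = FALSE) {
  if (!file.exists(path)) stopf("cannot read volume: file '%s' does not exist", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("cannot parse '%s' as NIfTI: %s", path, conditionMessage(e)))
  vox <- as.array(img)
  if (length(dim(vox)) == 2 && promote_2d) vox <- array(vox, c(dim(vox), 1))
  if (length(dim(vox)) != 3)
    stopf("'%s' is %d-D; expected a 3-D volume", path, length(dim(vox)))
  sp <- attr(img, "pixdim")
  if (is.null(sp) || length(sp) < 3) sp <- c(1, 1, 1)
  mr_volume(vox, spacing = sp[1:3], site_id = site_id,
            volume_id = volume_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' @rdname load_volume
#' @param volume an [mr_volume()]
#' @export
save_volume <- function(volume, path) {
  assert_that(inherits(volume, "mr_volume"), "volume must be an mr_volume")
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract 2.5D slices from a volume
#'
#' Selects the `n_central` centermost axial slices and forms one three-channel
#' window per retained center index at the given stride: channels are the
#' previous, the center, and the next axial slice, with edge slices replicated
#' so every retained index can be a window center.
#'
#' @param volume an [mr_volume()]
#' @param n_central number of central axial slices to retain (default: all)
#' @param stride spacing between consecutive window centers
#' @return list of `slice25d` objects; each records its `center_index`
#'   (1-based axial index into the volume), `site_id` and `volume_id`
#' @export
extract_slices_25d <- function(volume, n_central = NULL, stride = 1L) {
  assert_that(inherits(volume, "mr_volume"), "volume must be an mr_volume")
  d <- dim(volume$voxels)
  if (d[3] < 3) stopf("volume has %d axial slices; need at least 3", d[3])
  n_central <- n_central %||% d[3]
  assert_that(n_central >= 1 && n_central <= d[3],
              "n_central must be between 1 and the axial extent (%d)", d[3])
  band_start <- as.integer(floor((d[3] - n_central) / 2)) + 1L
  centers <- as.integer(seq(band_start, band_start + n_central - 1L, by = stride))
  lapply(centers, function(ci) {
    idx <- pmin(pmax(c(ci - 1L, ci, ci + 1L), 1L), d[3])
    px <- volume$voxels[, , idx, drop = FALSE]
    structure(list(pixels = px, site_id = volume$site_id,
                   volume_id = volume$volume_id, center_index = ci,
                   norm_record = NULL, pad_record = NULL),
              class = "slice25d")
  })
}

# Wrap a single 2-D image as a degenerate 2.5D slice (all channels equal),
# the limit case of edge replication for a volume of thickness one.
#' @rdname extract_slices_25d
#' @param image 2-D matrix or H x W x 3 array
#' @export
as_slice25d <- function(image, site_id = NA_integer_, volume_id = "img",
                        center_index = 1L) {
  px <- if (length(dim(image)) == 3) image else array(image, c(dim(image), 3))
  assert_that(length(dim(px)) == 3 && dim(px)[3] == 3, "need a 2-D image or an HxWx3 array")
  structure(list(pixels = px, site_id = site_id, volume_id = volume_id,
                 center_index = center_index, norm_record = NULL,
                 pad_record = NULL),
            class = "slice25d")
}

#' Normalize each channel of a 2.5D slice to [-1, 1]
#'
#' Linear per-channel map sending the channel minimum to -1 and maximum to +1.
#' The (min, max) pair is stored in `norm_record` so [denormalize_channels()]
#' inverts exactly.  A constant channel maps to all zeros and is flagged.
#'
#' @param slice a `slice25d`
#' @return the slice with pixels in [-1, 1] and `norm_record` set
#' @export
normalize_channels <- function(slice) {
  px <- slice$pixels
  if (!all(is.finite(px))) stopf("non-finite pixel values in slice '%s'", slice$volume_id)
  rec <- vector("list", dim(px)[3])
  for (k in seq_len(dim(px)[3])) {
    ch <- px[, , k]
    lo <- min(ch); hi <- max(ch)
    if (hi > lo) {
      px[, , k] <- 2 * (ch - lo) / (hi - lo) - 1
      rec[[k]] <- list(min = lo, max = hi, degenerate = FALSE)
    } else {
      px[, , k] <- 0
      rec[[k]] <- list(min = lo, max = hi, degenerate = TRUE)
    }
  }
  slice$pixels <- px
  slice$norm_record <- rec
  slice
}

#' @rdname normalize_channels
#' @param pixels optional array to denormalize with this slice's record
#'   (e.g. a harmonized output, which has no native intensity scale and is
#'   mapped back with the source slice's record)
#' @export
denormalize_channels <- function(slice, pixels = NULL) {
  rec <- slice$norm_record
  assert_that(!is.null(rec), "slice has no norm_record; normalize first")
  px <- pixels %||% slice$pixels
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 1))
  for (k in seq_len(dim(px)[3])) {
    r <- rec[[min(k, length(rec))]]
    px[, , k] <- if (r$degenerate) r$min else (px[, , k] + 1) / 2 * (r$max - r$min) + r$min
  }
  if (dim(px)[3] == 1) px <- px[, , 1] else px
}

#' Zero-pad a 2.5D slice to a square canvas
#'
#' Pixels are centered; on an odd size difference the extra pixel goes to the
#' bottom/right.  `pad_record` stores the original size and the top-left
#' offset so [crop_back()] is bit-exact.
#'
#' @param slice a `slice25d`
#' @param canvas canvas side length
#' @export
pad_to_canvas <- function(slice, canvas) {
  d <- dim(slice$pixels)
  if (d[1] > canvas || d[2] > canvas)
    stopf("slice %dx%d exceeds canvas %d; refusing to crop silently", d[1], d[2], canvas)
  off <- c(floor((canvas - d[1]) / 2), floor((canvas - d[2]) / 2))
  out <- array(0, c(canvas, canvas, d[3]))
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), ] <- slice$pixels
  slice$pixels <- out
  slice$pad_record <- list(orig = d[1:2], offset = off)
  slice
}

#' @rdname pad_to_canvas
#' @param pixels optional canvas-sized array to crop with this slice's record
#' @export
crop_back <- function(slice, pixels = NULL) {
  pr <- slice$pad_record
  assert_that(!is.null(pr), "slice has no pad_record; pad first")
  px <- pixels %||% slice$pixels
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 1))
  out <- px[pr$offset[1] + seq_len(pr$orig[1]),
            pr$offset[2] + seq_len(pr$orig[2]), , drop = FALSE]
  if (dim(out)[3] == 1) out[, , 1] else out
}

#' Reassemble a volume from per-slice center-channel outputs
#'
#' Inverts padding and normalization using each slice's recorded metadata and
#' places each output's center channel at its `center_index`.  Axial slices
#' outside the retained central band are copied unchanged from the template.
#'
#' @param slices list of `slice25d` whose `pixels` hold the (canvas-sized,
#'   normalized) outputs; each must carry `norm_record`, `pad_record`,
#'   `center_index`
#' @param template the source [mr_volume()]
#' @export
reassemble_volume <- function(slices, template) {
  assert_that(inherits(template, "mr_volume"), "template must be an mr_volume")
  centers <- vapply(slices, function(s) s$center_index, integer(1))
  if (anyDuplicated(centers)) stopf("duplicate center_index in slice set")
  vox <- template$voxels
  for (s in slices) {
    px <- s$pixels
    ch <- if (length(dim(px)) == 3) px[, , (dim(px)[3] + 1) %/% 2] else px
    ch <- crop_back(s, array(ch, c(dim(ch), 1)))
    rec <- s$norm_record[[(length(s$norm_record) + 1) %/% 2]]
    ch <- if (rec$degenerate) matrix(rec$min, nrow(ch), ncol(ch)) else
      (ch + 1) / 2 * (rec$max - rec$min) + rec$min
    vox[, , s$center_index] <- ch
  }
  mr_volume(vox, spacing = template$spacing, site_id = template$site_id,
            volume_id = template$volume_id)
}

# Normalize + pad in one step; the canonical preprocessing before the model.
#' @rdname normalize_channels
#' @param canvas canvas side length
#' @export
prep_slice <- function(slice, canvas) {
  pad_to_canvas(normalize_channels(slice), canvas)
}
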