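# Preprocessing pipeline: cohort normalization, RGB fusion, axial MPR
# reslicing, auto-crop, resizing to 64 x 64, and hex-range wall removal.
# Inputs are co-registered three-contrast volumes plus a lesion ROI mask.

#' Construct a contrast volume
#'
#' @param voxels 3-D array of non-negative intensities.
#' @param spacing_mm Voxel spacing, three positive reals (mm).
#' @param contrast One of `"T1w"`, `"T2w"`, `"UTE"`.
#' @param lesion_id Optional lesion identifier.
#' @return A `contrast_volume`.
#' @export
contrast_volume <- function(voxels, spacing_mm = c(1, 1, 1),
                            contrast = c("T1w", "T2w", "UTE"),
                            lesion_id = "lesion") {
  contrast <- match.arg(contrast)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  if (any(dim(voxels) < 1L)) stop("all spatial dimensions must be >= 1",
                                  call. = FALSE)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (anyNA(voxels) || min(voxels) < 0)
    stop("voxel intensities must be non-negative and finite", call. = FALSE)
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 contrast = contrast, lesion_id = lesion_id),
            class = "contrast_volume")
}

#' @export
print.contrast_volume <- function(x, ...) {
  cat(sprintf("<contrast_volume> %s '%s' [%s], spacing %s mm\n", x$contrast,
              x$lesion_id, paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing_mm), collapse = " x ")))
  invisible(x)
}

#' Construct a lesion ROI mask
#'
#' @param voxels 3-D logical (or 0/1) array congruent with the volumes it
#'   outlines; must contain at least one foreground voxel.
#' @param lesion_id Lesion identifier.
#' @return An `roi_mask`.
#' @export
roi_mask <- function(voxels, lesion_id = "lesion") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  voxels <- array(as.logical(voxels != 0), dim(voxels))
  if (!any(voxels)) stop("ROI mask has no foreground voxels", call. = FALSE)
  structure(list(voxels = voxels, lesion_id = lesion_id), class = "roi_mask")
}

new_pseudo_color_volume <- function(voxels, spacing_mm = c(1, 1, 1)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L, dim(voxels)[4] == 3L)
  structure(voxels, spacing_mm = as.numeric(spacing_mm),
            class = "pseudo_color_volume")
}

#' Read a NIfTI contrast volume
#'
#' Loads a `.nii`/`.nii.gz` file with RNifti; the NIfTI affine is consulted
#' only to identify the third array axis as inferior-superior (axial slicing
#' axis). Negative intensities (possible after registration resampling) are
#' clipped to zero.
#'
#' @param path NIfTI file path.
#' @inheritParams contrast_volume
#' @return A `contrast_volume`.
#' @export
read_contrast_volume <- function(path, contrast, lesion_id = "lesion") {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim(img)[1:3])
  vox[vox < 0] <- 0
  contrast_volume(vox, spacing_mm = RNifti::pixdim(img)[1:3],
                  contrast = contrast, lesion_id = lesion_id)
}

#' Read a NIfTI ROI mask
#' @param path NIfTI file path (nonzero voxels are foreground).
#' @param lesion_id Lesion identifier.
#' @return An `roi_mask`.
#' @export
read_roi_mask <- function(path, lesion_id = "lesion") {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img), dim(img)[1:3]) != 0, lesion_id = lesion_id)
}

#' Normalize intensities across a cohort, per contrast
#'
#' Equalizes image contrasts across lesions: for each contrast, intensities of
#' all volumes of that contrast are pooled, and a single linear map sending
#' the pooled 1st percentile to 0 and the pooled 99th percentile to 255
#' (clipped to `[0, 255]`) is applied to every volume of the contrast.
#' Volumes of the same contrast from different lesions therefore share one
#' mapping.
#'
#' @param volumes List of [contrast_volume()] objects (any mix of contrasts;
#'   at least one volume per contrast present).
#' @param probs Lower/upper pooled percentiles anchoring the map,
#'   default `c(0.01, 0.99)`.
#' @return List of normalized `contrast_volume`s in the input order.
#' @export
normalize_cohort <- function(volumes, probs = c(0.01, 0.99)) {
  stopifnot(is.list(volumes), length(volumes) >= 1L,
            all(vapply(volumes, inherits, logical(1), "contrast_volume")))
  contrasts <- vapply(volumes, `[[`, character(1), "contrast")
  maps <- list()
  for (ct in unique(contrasts)) {
    pooled <- unlist(lapply(volumes[contrasts == ct],
                            function(v) as.numeric(v$voxels)), use.names = FALSE)
    q <- stats::quantile(pooled, probs, names = FALSE)
    if (q[2] <= q[1])
      stop(sprintf("contrast %s has constant pooled intensity (p%g = p%g); cannot normalize",
                   ct, probs[1] * 100, probs[2] * 100), call. = FALSE)
    maps[[ct]] <- q
  }
  lapply(volumes, function(v) {
    q <- maps[[v$contrast]]
    v$voxels <- clip255((v$voxels - q[1]) / (q[2] - q[1]) * 255)
    v
  })
}

#' Fuse three contrasts into a pseudo-color volume
#'
#' Voxelwise channel stack with red = T1w, green = T2w, blue = UTE. No
#' resampling is performed; the three volumes must already be co-registered,
#' congruent in shape and spacing, and normalized to `[0, 255]`.
#'
#' @param t1,t2,ute [contrast_volume()]s with matching shape and spacing.
#' @return A `pseudo_color_volume` (X x Y x Z x 3 array).
#' @export
fuse_contrasts <- function(t1, t2, ute) {
  vols <- list(t1, t2, ute)
  stopifnot(all(vapply(vols, inherits, logical(1), "contrast_volume")))
  shapes <- lapply(vols, function(v) dim(v$voxels))
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop(sprintf("volume shapes differ: T1w [%s], T2w [%s], UTE [%s]",
                 paste(shapes[[1]], collapse = " x "),
                 paste(shapes[[2]], collapse = " x "),
                 paste(shapes[[3]], collapse = " x ")), call. = FALSE)
  if (!isTRUE(all.equal(t1$spacing_mm, t2$spacing_mm)) ||
      !isTRUE(all.equal(t1$spacing_mm, ute$spacing_mm)))
    stop("voxel spacings differ between contrasts", call. = FALSE)
  d <- shapes[[1]]
  out <- array(0, c(d, 3))
  out[, , , 1] <- t1$voxels
  out[, , , 2] <- t2$voxels
  out[, , , 3] <- ute$voxels
  new_pseudo_color_volume(out, spacing_mm = t1$spacing_mm)
}

#' Extract axial MPR slices restricted to a lesion ROI
#'
#' Reslices the pseudo-color volume perpendicular to its inferior-superior
#' (third) axis at the original in-plane resolution: one slice per axial
#' index inside the ROI's axial bounding range, in increasing order. Pixels
#' outside the ROI are set to black.
#'
#' @param volume A `pseudo_color_volume`.
#' @param roi An [roi_mask()] congruent with the volume.
#' @return A `lesion_stack` (unlabelled); `meta$axial_indices` records the
#'   source slice indices.
#' @export
extract_axial_mpr <- function(volume, roi) {
  stopifnot(inherits(volume, "pseudo_color_volume"), inherits(roi, "roi_mask"))
  d <- dim(volume)
  if (!identical(d[1:3], dim(roi$voxels)))
    stop("ROI mask shape does not match the volume", call. = FALSE)
  z_any <- which(apply(roi$voxels, 3, any))
  if (length(z_any) == 0L) stop("ROI mask is empty", call. = FALSE)
  zs <- seq(min(z_any), max(z_any))
  slices <- lapply(zs, function(z) {
    img <- volume[, , z, , drop = TRUE]
    dim(img) <- c(d[1], d[2], 3)
    m <- roi$voxels[, , z]
    for (ch in 1:3) img[, , ch] <- img[, , ch] * m
    img
  })
  new_lesion_stack(slices, lesion_id = roi$lesion_id,
                   meta = list(axial_indices = zs))
}

#' Auto-crop a pseudo-color image to its content
#'
#' Returns the minimal bounding box containing every pixel that differs from
#' the background color (exact black by default).
#'
#' @param image H x W x 3 array on `[0, 255]`.
#' @param background Background intensity per channel (default black);
#'   `tolerance` allows near-background pixels to count as background.
#' @param tolerance Non-negative scalar, default 0 (exact match).
#' @return The cropped image.
#' @export
autocrop <- function(image, background = c(0, 0, 0), tolerance = 0) {
  assert_pseudocolor(image)
  fg <- abs(image[, , 1] - background[1]) > tolerance |
        abs(image[, , 2] - background[2]) > tolerance |
        abs(image[, , 3] - background[3]) > tolerance
  if (!any(fg)) stop("image is entirely background; nothing to crop",
                     call. = FALSE)
  rows <- range(which(apply(fg, 1, any)))
  cols <- range(which(apply(fg, 2, any)))
  image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
}

#' Resize a pseudo-color image to the standard side length
#'
#' Bilinear resampling of each channel independently to `side` x `side`
#' (EBImage); output clipped to `[0, 255]`. A same-size input is returned
#' unchanged.
#'
#' @param image H x W x 3 array on `[0, 255]`.
#' @param side Target side length, default 64.
#' @return A `side` x `side` x 3 array.
#' @export
resize_to_standard <- function(image, side = 64) {
  assert_pseudocolor(image)
  if (dim(image)[1] == side && dim(image)[2] == side) return(image)
  out <- EBImage::resize(image, w = side, h = side, filter = "bilinear")
  clip255(unclass(out))
}

#' Remove pixels in a packed-hex RGB range
#'
#' Replaces by black every pixel whose packed 24-bit value
#' `v = red * 65536 + green * 256 + blue` (channels rounded to integers)
#' satisfies `lo <= v <= hi`. The default range `0x800000`-`0xff0000` removes
#' the red/pink arterial-wall signal, leaving the dark (hard) and bright-blue
#' (soft) luminal components. Idempotent: black never re-enters the range
#' (for any `lo > 0`).
#'
#' @param image H x W x 3 array on `[0, 255]`.
#' @param lo,hi Inclusive packed 24-bit range endpoints, `lo <= hi`.
#' @return The filtered image.
#' @export
remove_hex_range <- function(image, lo = 0x800000, hi = 0xff0000) {
  assert_pseudocolor(image)
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  v <- round(image[, , 1]) * 65536 + round(image[, , 2]) * 256 +
    round(image[, , 3])
  hit <- v >= lo & v <= hi
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[hit] <- 0
    image[, , ch] <- plane
  }
  image
}

#' Standardize one slice: auto-crop, resize, hex-filter
#'
#' The per-slice tail of the preprocessing pipeline, applied after reslicing:
#' crop to content, bilinear-resize to `side` x `side`, then remove the
#' arterial-wall hex range.
#'
#' @param image H x W x 3 array.
#' @param side Target side length, default 64.
#' @param hex_lo,hex_hi Wall-removal range (see [remove_hex_range()]).
#' @return A `side` x `side` x 3 array.
#' @export
standardize_slice <- function(image, side = 64, hex_lo = 0x800000,
                              hex_hi = 0xff0000) {
  image |>
    autocrop() |>
    resize_to_standard(side = side) |>
    remove_hex_range(lo = hex_lo, hi = hex_hi)
}

#' Full preprocessing chain for one lesion
#'
#' Reslices a fused pseudo-color volume inside its ROI and standardizes every
#' slice ([standardize_slice()]). Input volumes are expected to be cohort-
#' normalized ([normalize_cohort()]) and fused ([fuse_contrasts()]) first.
#'
#' @param volume A `pseudo_color_volume`.
#' @param roi An [roi_mask()].
#' @inheritParams standardize_slice
#' @return A `lesion_stack` of `side` x `side` slices.
#' @export
preprocess_lesion <- function(volume, roi, side = 64, hex_lo = 0x800000,
                              hex_hi = 0xff0000) {
  stack <- extract_axial_mpr(volume, roi)
  # interior bounding-box slices with no ROI voxels standardize to a black
  # canvas rather than aborting the lesion
  stack$slices <- lapply(stack$slices, function(sl) {
    if (all(sl == 0)) return(array(0, c(side, side, 3)))
    standardize_slice(sl, side = side, hex_lo = hex_lo, hex_hi = hex_hi)
  })
  stack$meta$standardized <- list(side = side, hex_lo = hex_lo, hex_hi = hex_hi)
  stack
}
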