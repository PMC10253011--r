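# Shared image and stack containers.
#
# A pseudo-color image is a plain numeric H x W x 3 array with intensities on
# [0, 255]; channel order is red = T1w, green = T2w, blue = UTE. A lesion
# stack is an ordered list of such slices, optionally with ground-truth
# tissue-class labels (phantoms carry them, real lesions do not).

#' Tissue class score map
#'
#' The fixed per-slice tissue score by class: class 1 (lumen patent) scores 0,
#' class 2 (partially patent) 1, class 3 (mostly occluded, soft tissue) 3 and
#' class 4 (mostly occluded, hard tissue) 5.
#'
#' @return Named numeric vector of length 4 (names `"1"`..`"4"`).
#' @export
#' @examples
#' tissue_score_map()
tissue_score_map <- function() {
  c(`1` = 0, `2` = 1, `3` = 3, `4` = 5)
}

#' Tissue class labels
#' @return Named character vector of descriptive labels by class id.
#' @export
tissue_class_labels <- function() {
  c(`1` = "lumen patent",
    `2` = "lumen partially patent",
    `3` = "mostly occluded, soft tissue",
    `4` = "mostly occluded, hard tissue")
}

assert_pseudocolor <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array, got dim [%s]",
                 arg, paste(dim(img), collapse = " x ")), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` intensities must lie in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

new_lesion_stack <- function(slices, labels = NULL, lesion_id = "lesion",
                             meta = list()) {
  stopifnot(is.list(slices), length(slices) >= 1L)
  if (!is.null(labels)) {
    if (length(labels) != length(slices))
      stop("`labels` must have one entry per slice", call. = FALSE)
    labels <- as.integer(labels)
    if (!all(labels %in% 1:4))
      stop("labels must be tissue classes in {1, 2, 3, 4}", call. = FALSE)
  }
  structure(list(slices = slices, labels = labels,
                 lesion_id = lesion_id, meta = meta),
            class = "lesion_stack")
}

#' @export
print.lesion_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<lesion_stack> '%s': %d slices of %d x %d x %d%s\n",
              x$lesion_id, length(x$slices), d[1], d[2], d[3],
              if (is.null(x$labels)) "" else " (labelled)"))
  if (!is.null(x$labels))
    cat("  class counts:",
        paste(sprintf("%d:%d", 1:4, tabulate(x$labels, 4L)), collapse = " "),
        "\n")
  invisible(x)
}

#' @export
length.lesion_stack <- function(x) length(x$slices)

# Stack a list of H x W x 3 slices into an (H, W, C, N) array (model input) or
# an (H, W, N, C) volume (axial pseudo-color volume, third axis = slice).
stack_to_array <- function(slices) {
  d <- dim(slices[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(slices)))
  for (i in seq_along(slices)) out[, , , i] <- slices[[i]]
  out
}

#' Convert a lesion stack to an axial pseudo-color volume
#'
#' Stacks the slices of a lesion along the third (inferior-superior) axis,
#' producing an H x W x n_slices x 3 array — the inverse of
#' [extract_axial_mpr()] for born-aligned stacks.
#'
#' @param stack A `lesion_stack`.
#' @return A `pseudo_color_volume` (H x W x Z x 3 array, unit spacing).
#' @export
stack_to_volume <- function(stack) {
  stopifnot(inherits(stack, "lesion_stack"))
  d <- dim(stack$slices[[1]])
  n <- length(stack$slices)
  vol <- array(0, c(d[1], d[2], n, 3))
  for (i in seq_len(n)) vol[, , i, ] <- stack$slices[[i]]
  new_pseudo_color_volume(vol, spacing_mm = c(1, 1, 1))
}

#' Write a lesion stack to disk
#'
#' Writes one PNG per slice plus a JSON sidecar holding the lesion id, the
#' per-slice labels (when present) and the stack metadata; optionally also a
#' 4-D NIfTI volume (slice stacked on the third axis, channel on the fourth).
#'
#' @param stack A `lesion_stack`.
#' @param dir Output directory (created if missing).
#' @param nifti Also write a 4-D NIfTI volume? Default `FALSE`.
#' @return Invisibly, a tibble manifest (slice_index, file).
#' @export
write_stack <- function(stack, dir, nifti = FALSE) {
  stopifnot(inherits(stack, "lesion_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(stack$slices))
  for (i in seq_along(stack$slices)) {
    files[i] <- file.path(dir, sprintf("%s_slice%04d.png", stack$lesion_id, i))
    png::writePNG(stack$slices[[i]] / 255, files[i])
  }
  sidecar <- list(lesion_id = stack$lesion_id,
                  n_slices = length(stack$slices),
                  labels = stack$labels,
                  meta = stack$meta)
  jsonlite::write_json(sidecar, file.path(dir, paste0(stack$lesion_id, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (nifti) {
    vol <- stack_to_volume(stack)
    RNifti::writeNifti(unclass(vol),
                       file.path(dir, paste0(stack$lesion_id, ".nii.gz")))
  }
  invisible(tibble::tibble(slice_index = seq_along(files), file = files))
}

#' Read a lesion stack written by [write_stack()]
#'
#' @param dir Directory holding the per-slice PNGs and the JSON sidecar.
#' @param lesion_id Lesion identifier (sidecar file stem).
#' @return A `lesion_stack`.
#' @export
read_stack <- function(dir, lesion_id) {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(lesion_id, ".json")),
                                 simplifyVector = TRUE)
  files <- file.path(dir, sprintf("%s_slice%04d.png", lesion_id,
                                  seq_len(sidecar$n_slices)))
  slices <- lapply(files, function(f) {
    px <- png::readPNG(f)
    round(px[, , 1:3, drop = FALSE] * 255)
  })
  labels <- sidecar$labels
  if (length(labels) == 0L) labels <- NULL
  new_lesion_stack(slices, labels = labels, lesion_id = lesion_id,
                   meta = sidecar$meta)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)
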