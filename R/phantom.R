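# Synthetic vessel-phantom generator.
#
# Each slice is an axial cross-section of an artery: an annular wall around a
# circular lumen, with the lumen progressively infilled by occluding tissue
# according to the slice's tissue class. Color semantics follow the
# pseudo-color convention (red = T1w, green = T2w, blue = UTE): arterial wall
# red/pink, free lumen green, soft occluding tissue bright blue, collagen dark
# blue, calcium black. Ground-truth geometry masks are retained per slice so
# tests can verify labels by direct pixel counting.

# Color prototypes on the 0-255 scale, before noise.
phantom_palette <- function() {
  list(wall     = c(200, 120, 120),
       lumen    = c(0, 200, 0),
       soft     = c(60, 60, 230),
       collagen = c(20, 20, 90),
       calcium  = c(0, 0, 0))
}

# Generator-internal class geometry: fraction of the lumen area occluded.
# "Partially patent" means 30-70% occluded, "mostly occluded" means > 70%.
# Sampled targets keep a margin from the defining thresholds so the intended
# class of every slice is unambiguous.
phantom_geometry_conventions <- function() {
  list(partial_band = c(0.30, 0.70),
       mostly_min = 0.70,
       partial_target = c(0.35, 0.65),
       mostly_target = c(0.75, 0.95),
       calcium_fraction = 0.30)
}

#' Specify a synthetic vessel phantom
#'
#' @param n_slices Number of axial slices.
#' @param class_sequence Integer vector of per-slice tissue classes in
#'   `{1, 2, 3, 4}`, one per slice: 1 lumen patent, 2 partially patent,
#'   3 mostly occluded by soft tissue, 4 mostly occluded by hard tissue.
#' @param image_side Slice side length in pixels (>= 16), default 64.
#' @param wall_thickness_px Arterial wall thickness in pixels, default 5.
#' @param noise_sd Additive i.i.d. Gaussian channel noise standard deviation
#'   on the `[0, 1]` intensity scale (applied as `255 * noise_sd` on the
#'   stored scale, then clipped). Default 0.
#' @param seed Integer seed; identical specs (including seed) generate
#'   bit-identical stacks.
#' @return A `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(4, class_sequence = c(1, 2, 3, 4), seed = 7)
#' stack <- generate_phantom(spec)
#' stack
phantom_spec <- function(n_slices, class_sequence, image_side = 64,
                         wall_thickness_px = 5, noise_sd = 0, seed = 1) {
  n_slices <- as.integer(n_slices)
  stopifnot(length(n_slices) == 1L, n_slices >= 1L)
  if (length(class_sequence) != n_slices)
    stop("`class_sequence` must have one entry per slice (length ",
         n_slices, ")", call. = FALSE)
  bad <- which(!(class_sequence %in% 1:4))
  if (length(bad) > 0L)
    stop(sprintf("invalid tissue class %s at slice index %d (must be 1-4)",
                 format(class_sequence[bad[1]]), bad[1]), call. = FALSE)
  image_side <- as.integer(image_side)
  if (image_side < 16L) stop("`image_side` must be >= 16", call. = FALSE)
  wall_thickness_px <- as.integer(wall_thickness_px)
  stopifnot(wall_thickness_px >= 1L)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(n_slices = n_slices,
                 class_sequence = as.integer(class_sequence),
                 image_side = image_side,
                 wall_thickness_px = wall_thickness_px,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d slices (%dpx), wall %dpx, noise sd %.3f, seed %d\n",
              x$n_slices, x$image_side, x$wall_thickness_px, x$noise_sd, x$seed))
  invisible(x)
}

# Randomized region growing: start from seed pixels inside `mask` and expand
# the cheapest frontier pixel (random per-pixel weights) until `target`
# pixels are claimed. Gives irregular but connected blobs with an exact mask.
grow_blob <- function(mask, target, n_seeds = 1L) {
  dims <- dim(mask)
  nH <- dims[1]
  npx <- length(mask)
  if (target <= 0L) return(matrix(FALSE, dims[1], dims[2]))
  w <- stats::runif(npx)
  inside <- which(mask)
  seeds <- inside[sample.int(length(inside), min(n_seeds, length(inside)))]
  blob <- rep(FALSE, npx)
  queued <- rep(FALSE, npx)
  frontier <- seeds
  queued[seeds] <- TRUE
  count <- 0L
  while (count < target && length(frontier) > 0L) {
    pick <- which.min(w[frontier])
    j <- frontier[pick]
    frontier <- frontier[-pick]
    blob[j] <- TRUE
    count <- count + 1L
    r <- (j - 1L) %% nH + 1L
    cc <- (j - 1L) %/% nH + 1L
    nb <- c(if (r > 1L) j - 1L, if (r < nH) j + 1L,
            if (cc > 1L) j - nH, if (cc < dims[2]) j + nH)
    nb <- nb[mask[nb] & !queued[nb]]
    if (length(nb) > 0L) {
      frontier <- c(frontier, nb)
      queued[nb] <- TRUE
    }
  }
  matrix(blob, dims[1], dims[2])
}

paint <- function(img, mask, rgb) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

# Render one cross-section; returns image plus ground-truth geometry.
render_phantom_slice <- function(class_id, side, wall_px) {
  pal <- phantom_palette()
  conv <- phantom_geometry_conventions()
  cx <- side / 2 + 0.5 + stats::runif(1, -side * 0.03, side * 0.03)
  cy <- side / 2 + 0.5 + stats::runif(1, -side * 0.03, side * 0.03)
  r_out <- side * 0.40 + stats::runif(1, -side * 0.02, side * 0.02)
  r_lumen <- max(r_out - wall_px, 3)
  dist <- sqrt(outer((seq_len(side) - cx)^2, (seq_len(side) - cy)^2, `+`))
  wall <- dist <= r_out & dist > r_lumen
  lumen <- dist <= r_lumen

  img <- array(0, c(side, side, 3))
  img <- paint(img, wall, pal$wall)
  img <- paint(img, lumen, pal$lumen)

  occlusion <- matrix(FALSE, side, side)
  calcium <- matrix(FALSE, side, side)
  if (class_id >= 2L) {
    band <- if (class_id == 2L) conv$partial_target else conv$mostly_target
    frac <- stats::runif(1, band[1], band[2])
    occlusion <- grow_blob(lumen, round(frac * sum(lumen)),
                           n_seeds = if (class_id == 2L) 1L else 2L)
    if (class_id %in% c(2L, 3L)) {
      img <- paint(img, occlusion, pal$soft)
    } else {
      img <- paint(img, occlusion, pal$collagen)
      calcium <- grow_blob(occlusion, round(conv$calcium_fraction * sum(occlusion)))
      img <- paint(img, calcium, pal$calcium)
    }
  }
  list(image = img,
       geometry = list(lumen = lumen, wall = wall, occlusion = occlusion,
                       calcium = calcium,
                       occlusion_fraction = sum(occlusion) / sum(lumen)))
}

#' Generate a synthetic vessel phantom stack
#'
#' Draws one annular-wall cross-section per entry of the spec's class
#' sequence, infills the lumen according to the class (see [phantom_spec()]),
#' adds clipped Gaussian channel noise, and returns the slices together with
#' their ground-truth labels and geometry masks.
#'
#' @param spec A [phantom_spec()].
#' @param lesion_id Identifier stored in the returned stack.
#' @return A `lesion_stack` with `labels` set; `meta$geometry` holds per-slice
#'   lumen/occlusion masks and occlusion fractions, `meta$conventions` the
#'   generator's patency thresholds, `meta$spec` an echo of the spec.
#' @export
generate_phantom <- function(spec, lesion_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  bad <- which(!(spec$class_sequence %in% 1:4))
  if (length(bad) > 0L)
    stop(sprintf("invalid tissue class %s at slice index %d",
                 format(spec$class_sequence[bad[1]]), bad[1]), call. = FALSE)
  withr::with_seed(spec$seed, {
    rendered <- lapply(seq_len(spec$n_slices), function(i) {
      sl <- render_phantom_slice(spec$class_sequence[i], spec$image_side,
                                 spec$wall_thickness_px)
      if (spec$noise_sd > 0) {
        sl$image <- clip255(sl$image +
          array(stats::rnorm(length(sl$image), 0, 255 * spec$noise_sd),
                dim(sl$image)))
      }
      sl
    })
    new_lesion_stack(
      slices = lapply(rendered, `[[`, "image"),
      labels = spec$class_sequence,
      lesion_id = lesion_id,
      meta = list(spec = unclass(spec),
                  conventions = phantom_geometry_conventions(),
                  palette = phantom_palette(),
                  geometry = lapply(rendered, `[[`, "geometry")))
  })
}

#' Recover the tissue class of a phantom slice from its geometry mask
#'
#' Independent pixel-counting oracle over the generator's ground-truth
#' geometry: computes the occluded lumen fraction and the dominant occluding
#' color directly from the rendered image, then applies the generator's
#' patency conventions (patent < 30% occluded; partially patent 30-70%;
#' mostly occluded > 70%, split soft vs hard by the occluding color).
#'
#' @param image The rendered slice (H x W x 3).
#' @param geometry The matching `meta$geometry` entry of the stack.
#' @return Integer tissue class in 1-4.
#' @export
classify_phantom_slice <- function(image, geometry) {
  conv <- phantom_geometry_conventions()
  frac <- sum(geometry$occlusion) / sum(geometry$lumen)
  if (frac < conv$partial_band[1]) return(1L)
  if (frac <= conv$partial_band[2]) return(2L)
  occ <- geometry$occlusion
  r <- image[, , 1][occ]; g <- image[, , 2][occ]; b <- image[, , 3][occ]
  dark <- (r < 0x40 & b < 0x40) | (b > r & b > g & b < 0x80)
  if (mean(dark) >= 0.5) 4L else 3L
}
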