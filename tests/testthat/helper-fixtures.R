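# Shared fixtures and independent oracles used across test files.

# A tiny VAE configuration that trains in seconds (five stages, 64 -> 2).
tiny_vae_config <- function(epochs = 3, ...) {
  vae_config(encoder_depths = c(2, 3, 4, 5, 6), epochs = epochs,
             batch_size = 8, kl_weight = 1 / (64^2 * 3), ...)
}

# One noise-free phantom slice per requested class, standardized.
phantom_slices_by_class <- function(classes, seed = 1) {
  st <- generate_phantom(phantom_spec(length(classes),
                                      class_sequence = classes, seed = seed))
  st$slices <- lapply(st$slices, standardize_slice)
  st
}

# Independent per-pixel double-loop oracle for the hex-range filter.
brute_force_hex_filter <- function(img, lo, hi) {
  out <- img
  for (i in seq_len(dim(img)[1])) {
    for (j in seq_len(dim(img)[2])) {
      v <- round(img[i, j, 1]) * 65536 + round(img[i, j, 2]) * 256 +
        round(img[i, j, 3])
      if (v >= lo && v <= hi) out[i, j, ] <- 0
    }
  }
  out
}

# Independent quadrant test for the latent partition.
oracle_quadrant_class <- function(x, y, xt, yt, class_map) {
  key <- paste(if (x < xt) "lo" else "hi", if (y < yt) "lo" else "hi",
               sep = "_")
  unname(class_map[key])
}

random_image <- function(side = 64) {
  array(stats::runif(side * side * 3, 0, 255), c(side, side, 3))
}
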