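# Public surface of the convolutional variational autoencoder: configuration,
# model construction, the reparameterization trick, the loss, the training
# loop, and deterministic encoding into the 2-D latent space.

#' Configure the convolutional VAE
#'
#' Defaults follow the reference training recipe: five convolutional encoder
#' stages of strictly increasing depth compressing a 64 x 64 x 3 pseudo-color
#' image to a 2-D latent space, mirrored by five transposed-convolution
#' decoder stages; 500 epochs, batch size 128, learning rate 0.0005 with Adam.
#'
#' @param image_side Input side length (square images), default 64.
#' @param channels Input channels, default 3.
#' @param encoder_depths Five strictly increasing stage depths,
#'   default `c(32, 64, 128, 256, 512)`.
#' @param kernel_size Odd convolution kernel size, default 3.
#' @param stride Stride of every stage, default 2.
#' @param latent_dim Latent dimension, default 2.
#' @param epochs Training epochs, default 500.
#' @param batch_size Mini-batch size, default 128 (final partial batch kept).
#' @param learning_rate Adam learning rate, default 5e-4.
#' @param kl_weight Weight of the KL term against the per-pixel-mean squared
#'   reconstruction error, default 1. `kl_weight = 1/(image_side^2 * channels)`
#'   reproduces the canonical unit-beta ELBO (which sums reconstruction error
#'   over pixels); see the methods vignette.
#' @param seed Integer seed controlling weight initialization, epoch
#'   shuffling and reparameterization noise.
#' @return A `vae_config`.
#' @export
vae_config <- function(image_side = 64, channels = 3,
                       encoder_depths = c(32, 64, 128, 256, 512),
                       kernel_size = 3, stride = 2, latent_dim = 2,
                       epochs = 500, batch_size = 128, learning_rate = 5e-4,
                       kl_weight = 1, seed = 1) {
  cfg <- list(image_side = as.integer(image_side),
              channels = as.integer(channels),
              encoder_depths = as.integer(encoder_depths),
              kernel_size = as.integer(kernel_size),
              stride = as.integer(stride),
              latent_dim = as.integer(latent_dim),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              kl_weight = as.numeric(kl_weight),
              seed = as.integer(seed))
  if (length(cfg$encoder_depths) != 5L)
    stop("exactly five encoder stages are required", call. = FALSE)
  if (any(diff(cfg$encoder_depths) <= 0))
    stop("encoder depths must be strictly increasing", call. = FALSE)
  stopifnot(cfg$latent_dim >= 1L, cfg$epochs >= 1L, cfg$batch_size >= 1L,
            cfg$learning_rate > 0, cfg$kl_weight > 0, cfg$image_side >= 2L)
  class(cfg) <- "vae_config"
  cfg
}

#' @export
print.vae_config <- function(x, ...) {
  cat(sprintf(paste0("<vae_config> %dx%dx%d -> latent %d; depths %s; ",
                     "k%d s%d; %d epochs, batch %d, lr %g, kl_weight %g, seed %d\n"),
              x$image_side, x$image_side, x$channels, x$latent_dim,
              paste(x$encoder_depths, collapse = "-"), x$kernel_size,
              x$stride, x$epochs, x$batch_size, x$learning_rate,
              x$kl_weight, x$seed))
  invisible(x)
}

#' Build an untrained VAE
#'
#' Initializes encoder and decoder parameters (He/Glorot, seeded by
#' `config$seed`). The encoder maps an image through five strided
#' convolutions to a flattened dense layer feeding two linear heads (mean and
#' log-variance, each of size `latent_dim`); the decoder mirrors it with
#' transposed convolutions back to the image shape, with a sigmoid output
#' bounded to the intensity range. Rejects stride/kernel combinations that do
#' not evenly reduce `image_side` across the five stages.
#'
#' @param config A [vae_config()].
#' @return A `vae_model` (untrained).
#' @export
build_vae <- function(config) {
  stopifnot(inherits(config, "vae_config"))
  chain <- encoder_shape_chain(config)
  params <- withr::with_seed(config$seed, init_vae_params(config))
  structure(list(params = params, config = config, shape_chain = chain,
                 trained = FALSE, loss_trace = NULL),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<vae_model> %s; spatial chain %s; %s parameters%s\n",
              if (x$trained) "trained" else "untrained",
              paste(c(x$config$image_side, x$shape_chain), collapse = " -> "),
              format(np, big.mark = ","),
              if (x$trained) sprintf("; %d epochs", nrow(x$loss_trace)) else ""))
  invisible(x)
}

#' Reparameterization trick
#'
#' Draws a latent point from the encoder's Gaussian posterior:
#' `mean + exp(0.5 * log_variance) * noise`.
#'
#' @param mean,log_variance Numeric vectors of the latent dimension.
#' @param noise Standard-normal draws of the same length (zero noise returns
#'   the mean exactly).
#' @return Numeric vector: the latent point.
#' @export
#' @examples
#' reparameterize(c(1, 0), c(0, 0), c(1, 1))  # mean + unit sd
reparameterize <- function(mean, log_variance, noise) {
  stopifnot(length(mean) == length(log_variance),
            length(mean) == length(noise),
            all(is.finite(mean)), all(is.finite(log_variance)))
  mean + exp(0.5 * log_variance) * noise
}

#' VAE loss for one image
#'
#' `recon` is the mean squared error over all pixels and channels on the
#' `[0, 1]` intensity scale; `kl` is the closed-form Gaussian KL divergence
#' `0.5 * sum(exp(log_variance) + mean^2 - 1 - log_variance)` (always
#' non-negative); `total = recon + kl_weight * kl`.
#'
#' @param input,reconstruction Congruent H x W x 3 arrays on `[0, 255]`.
#' @param mean,log_variance Latent posterior parameters for the image.
#' @param kl_weight KL weight, default 1.
#' @return List with `total`, `recon` and `kl`.
#' @export
vae_loss <- function(input, reconstruction, mean, log_variance,
                     kl_weight = 1) {
  if (!identical(dim(input), dim(reconstruction)))
    stop("input and reconstruction shapes differ", call. = FALSE)
  recon <- base::mean(((input - reconstruction) / 255)^2)
  kl <- 0.5 * sum(exp(log_variance) + mean^2 - 1 - log_variance)
  list(total = recon + kl_weight * kl, recon = recon, kl = kl)
}

#' Train the VAE
#'
#' Adam optimization for `config$epochs` epochs at `config$learning_rate`,
#' with epoch-level shuffling and the final partial batch kept. All
#' randomness (weight initialization, shuffling, reparameterization noise) is
#' controlled by `config$seed`: the same seed and data give an identical loss
#' trace on one platform (floating-point reductions may differ across
#' BLAS/architectures).
#'
#' @param stack A `lesion_stack`, list of H x W x 3 arrays on `[0, 255]`, or
#'   an (H, W, C, N) array.
#' @param config A [vae_config()].
#' @param verbose Print per-epoch losses? Default `FALSE`.
#' @return A trained `vae_model` with `loss_trace` (tibble: epoch, total,
#'   recon, kl).
#' @export
train_vae <- function(stack, config, verbose = FALSE) {
  stopifnot(inherits(config, "vae_config"))
  x4 <- as_batch_array(stack, config)
  N <- dim(x4)[4]
  if (N < 1L) stop("training stack is empty", call. = FALSE)

  model <- build_vae(config)
  p <- model$params
  state <- adam_init(p)
  ld <- config$latent_dim
  trace <- matrix(0, config$epochs, 3,
                  dimnames = list(NULL, c("total", "recon", "kl")))

  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = config$batch_size)
      ep_loss <- c(total = 0, recon = 0, kl = 0)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, N)]
        xb <- x4[, , , idx, drop = FALSE]
        B <- length(idx)
        eps <- matrix(stats::rnorm(ld * B), ld, B)
        fwd <- vae_forward(p, xb, eps, config)
        terms <- vae_loss_terms(xb, fwd, config$kl_weight)
        grads <- vae_backward(p, fwd, xb, config)
        upd <- adam_step(p, grads, state, config$learning_rate)
        p <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + B * c(terms$total, terms$recon, terms$kl)
      }
      trace[ep, ] <- ep_loss / N
      if (verbose)
        message(sprintf("epoch %d/%d  total %.6f  recon %.6f  kl %.4f",
                        ep, config$epochs, trace[ep, 1], trace[ep, 2],
                        trace[ep, 3]))
    }
  })
  model$params <- p
  model$trained <- TRUE
  model$loss_trace <- tibble::tibble(epoch = seq_len(config$epochs),
                                     total = trace[, 1], recon = trace[, 2],
                                     kl = trace[, 3])
  model
}

# Accept a lesion_stack, a list of slices, or a prebuilt (H,W,C,N) array;
# returns intensities on [0, 1].
as_batch_array <- function(stack, config) {
  if (inherits(stack, "lesion_stack")) stack <- stack$slices
  if (is.list(stack)) stack <- stack_to_array(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 4L)
  d <- dim(stack)
  if (d[1] != config$image_side || d[2] != config$image_side ||
      d[3] != config$channels)
    stop(sprintf("images are %d x %d x %d but the model expects %d x %d x %d",
                 d[1], d[2], d[3], config$image_side, config$image_side,
                 config$channels), call. = FALSE)
  stack / 255
}

#' Encode images into the latent space
#'
#' Deterministic embedding: returns the mean-head output (no posterior
#' sampling), so repeated encodings of the same image are identical and the
#' downstream classification is reproducible.
#'
#' @param model A trained `vae_model`.
#' @param stack A `lesion_stack`, list of slices, a single H x W x 3 image,
#'   or an (H, W, C, N) array.
#' @return A tibble with one row per image: `slice_index`, `x`, `y` (first
#'   two latent components; further components are named `z3`, `z4`, ... for
#'   higher-dimensional latents) and, when the input stack is labelled,
#'   `label`.
#' @export
vae_encode <- function(model, stack) {
  stopifnot(inherits(model, "vae_model"))
  labels <- if (inherits(stack, "lesion_stack")) stack$labels else NULL
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- list(stack)
  x4 <- as_batch_array(stack, model$config)
  B <- dim(x4)[4]
  eps <- matrix(0, model$config$latent_dim, B)
  fwd <- vae_forward(model$params, x4, eps, model$config, sample_latent = FALSE)
  mu <- t(fwd$mu)
  nm <- c("x", "y", if (ncol(mu) > 2) paste0("z", 3:ncol(mu)))[seq_len(ncol(mu))]
  colnames(mu) <- nm
  out <- tibble::as_tibble(mu)
  out <- tibble::add_column(out, slice_index = seq_len(B), .before = 1)
  if (!is.null(labels)) out$label <- labels
  out
}

#' Decode latent points into images
#'
#' @param model A trained `vae_model`.
#' @param z Numeric vector of length `latent_dim`, or a matrix/data frame
#'   with one point per row (columns `x`, `y` accepted).
#' @return A list of H x W x 3 arrays on `[0, 255]` (a single array when one
#'   point is given).
#' @export
vae_decode <- function(model, z) {
  stopifnot(inherits(model, "vae_model"))
  cfg <- model$config
  if (is.data.frame(z)) z <- as.matrix(z[, c("x", "y")])
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  stopifnot(ncol(z) == cfg$latent_dim)
  p <- model$params
  chain <- model$shape_chain
  zB <- t(z)
  f <- lrelu(p$dec_W %*% zB + p$dec_b)
  d <- array(f, c(chain[5], chain[5], cfg$encoder_depths[5], nrow(z)))
  k <- cfg$kernel_size; s <- cfg$stride; pad <- (k - 1L) %/% 2L
  sizes_up <- c(rev(chain)[-1], cfg$image_side)
  for (j in 1:5) {
    t_j <- .convt_fwd(d, p[[paste0("dect", j, "_W")]],
                      p[[paste0("dect", j, "_b")]], k, s, pad,
                      sizes_up[j], sizes_up[j])
    d <- if (j < 5) lrelu(t_j) else sigmoid(t_j)
  }
  imgs <- lapply(seq_len(nrow(z)), function(i) 255 * d[, , , i])
  if (nrow(z) == 1L) imgs[[1]] else imgs
}

#' Save / load a trained VAE
#'
#' Writes the model in R's native serialization alongside a JSON echo of the
#' configuration and a CSV of the loss trace.
#'
#' @param model A `vae_model`.
#' @param path File stem; writes `<path>.rds`, `<path>_config.json` and
#'   `<path>_loss.csv`.
#' @return `save_vae`: invisibly, the paths written. `load_vae`: the model.
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "vae_model"))
  paths <- c(model = paste0(path, ".rds"),
             config = paste0(path, "_config.json"),
             loss = paste0(path, "_loss.csv"))
  saveRDS(model, paths["model"])
  jsonlite::write_json(unclass(model$config), paths["config"],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(model$loss_trace))
    utils::write.csv(model$loss_trace, paths["loss"], row.names = FALSE)
  invisible(paths)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  model <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(model, "vae_model"))
  model
}

#' @method tidy vae_model
#' @export
tidy.vae_model <- function(x, ...) {
  if (is.null(x$loss_trace)) return(tibble::tibble(epoch = integer(),
                                                   total = numeric(),
                                                   recon = numeric(),
                                                   kl = numeric()))
  x$loss_trace
}

#' @method glance vae_model
#' @export
glance.vae_model <- function(x, ...) {
  tr <- x$loss_trace
  tibble::tibble(
    trained = x$trained,
    epochs = if (is.null(tr)) 0L else nrow(tr),
    final_total = if (is.null(tr)) NA_real_ else tr$total[nrow(tr)],
    final_recon = if (is.null(tr)) NA_real_ else tr$recon[nrow(tr)],
    final_kl = if (is.null(tr)) NA_real_ else tr$kl[nrow(tr)],
    latent_dim = x$config$latent_dim,
    n_parameters = sum(vapply(x$params, length, numeric(1))))
}

#' @method autoplot vae_model
#' @export
autoplot.vae_model <- function(object, ...) {
  tr <- tidy(object)
  long <- tidyr::pivot_longer(tr, -"epoch", names_to = "term",
                              values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", color = NULL) +
    ggplot2::theme_minimal()
}
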