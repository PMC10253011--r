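# Internal network machinery for the convolutional VAE: parameter
# initialization, forward/backward passes (conv primitives in src/convnet.cpp)
# and the Adam optimizer. Everything operates on batches stored as
# (H, W, C, N) arrays with intensities on [0, 1].

LRELU_ALPHA <- 0.2
LOGVAR_CLAMP <- 15  # numerical guard on the log-variance head

lrelu <- function(x) pmax(x, LRELU_ALPHA * x)
dlrelu <- function(pre) LRELU_ALPHA + (1 - LRELU_ALPHA) * (pre > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Spatial size chain through the encoder; errors if any stage does not
# reduce evenly (the decoder must be able to mirror it exactly).
encoder_shape_chain <- function(config) {
  k <- config$kernel_size
  s <- config$stride
  if (k %% 2L != 1L)
    stop("kernel_size must be odd (symmetric same-padding)", call. = FALSE)
  side <- config$image_side
  chain <- integer(5)
  for (i in 1:5) {
    if (side %% s != 0L)
      stop(sprintf(paste0("stride %d does not evenly reduce the image: ",
                          "shape chain %s with stage %d input %d not divisible"),
                   s, paste(c(config$image_side, chain[seq_len(i - 1)]),
                            collapse = " -> "), i, side), call. = FALSE)
    side <- side %/% s
    chain[i] <- side
  }
  if (side < 1L)
    stop("image_side too small for 5 stages at this stride", call. = FALSE)
  chain
}

# He-normal for conv/lrelu stages, Glorot for the linear heads.
init_vae_params <- function(config) {
  k <- config$kernel_size
  depths <- config$encoder_depths
  chain <- encoder_shape_chain(config)
  flat <- chain[5]^2 * depths[5]
  ld <- config$latent_dim

  he <- function(F, fan_in) matrix(stats::rnorm(F * fan_in, 0, sqrt(2 / fan_in)),
                                   F, fan_in)
  glorot <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0,
                                                 sqrt(2 / (nr + nc))), nr, nc)
  p <- list()
  cin <- config$channels
  for (i in 1:5) {
    p[[paste0("enc", i, "_W")]] <- he(depths[i], k * k * cin)
    p[[paste0("enc", i, "_b")]] <- numeric(depths[i])
    cin <- depths[i]
  }
  p$mu_W <- glorot(ld, flat); p$mu_b <- numeric(ld)
  p$lv_W <- glorot(ld, flat); p$lv_b <- numeric(ld)
  p$dec_W <- glorot(flat, ld); p$dec_b <- numeric(flat)
  # decoder transposed-conv stages mirror the encoder: d5 -> d4 -> ... -> d1
  # -> channels; filter bank of stage j has F = input depth, C = output depth
  outs <- c(rev(depths)[-1], config$channels)
  ins <- rev(depths)
  for (j in 1:5) {
    p[[paste0("dect", j, "_W")]] <- he(ins[j], k * k * outs[j]) *
      sqrt(1 / config$stride^2)  # account for stride-s scatter overlap
    p[[paste0("dect", j, "_b")]] <- numeric(outs[j])
  }
  p
}

# Forward pass over a batch; keeps intermediates needed for backprop.
vae_forward <- function(p, x4, eps, config, sample_latent = TRUE) {
  k <- config$kernel_size; s <- config$stride; pad <- (k - 1L) %/% 2L
  depths <- config$encoder_depths
  chain <- encoder_shape_chain(config)
  B <- dim(x4)[4]

  acts <- vector("list", 5); pres <- vector("list", 5)
  a <- x4
  for (i in 1:5) {
    z <- .conv_fwd(a, p[[paste0("enc", i, "_W")]], p[[paste0("enc", i, "_b")]],
                   k, s, pad)
    pres[[i]] <- z
    a <- lrelu(z)
    acts[[i]] <- a
  }
  flat <- matrix(a, ncol = B)
  mu <- p$mu_W %*% flat + p$mu_b
  lv_raw <- p$lv_W %*% flat + p$lv_b
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  z <- if (sample_latent) mu + exp(0.5 * lv) * eps else mu

  f_pre <- p$dec_W %*% z + p$dec_b
  f <- lrelu(f_pre)
  d <- array(f, c(chain[5], chain[5], depths[5], B))
  sizes_up <- c(rev(chain)[-1], config$image_side)
  dpres <- vector("list", 5); dacts <- vector("list", 5)
  for (j in 1:5) {
    t_j <- .convt_fwd(d, p[[paste0("dect", j, "_W")]],
                      p[[paste0("dect", j, "_b")]], k, s, pad,
                      sizes_up[j], sizes_up[j])
    dpres[[j]] <- t_j
    d <- if (j < 5) lrelu(t_j) else sigmoid(t_j)
    dacts[[j]] <- d
  }
  list(acts = acts, pres = pres, flat = flat, mu = mu, lv = lv,
       lv_raw = lv_raw, z = z, f_pre = f_pre, f = f,
       dpres = dpres, dacts = dacts, xhat = d, eps = eps, B = B)
}

vae_loss_terms <- function(x4, fwd, kl_weight) {
  B <- fwd$B
  P <- length(x4) / B
  recon <- sum((fwd$xhat - x4)^2) / (P * B)
  kl_each <- 0.5 * colSums(exp(fwd$lv) + fwd$mu^2 - 1 - fwd$lv)
  kl <- mean(kl_each)
  list(total = recon + kl_weight * kl, recon = recon, kl = kl)
}

vae_backward <- function(p, fwd, x4, config) {
  k <- config$kernel_size; s <- config$stride; pad <- (k - 1L) %/% 2L
  depths <- config$encoder_depths
  chain <- encoder_shape_chain(config)
  B <- fwd$B
  P <- length(x4) / B
  w <- config$kl_weight
  g <- list()

  # decoder
  g_out <- (2 / (P * B)) * (fwd$xhat - x4) * fwd$xhat * (1 - fwd$xhat)
  for (j in 5:1) {
    input_j <- if (j == 1)
      array(fwd$f, c(chain[5], chain[5], depths[5], B))
    else fwd$dacts[[j - 1]]
    bw <- .convt_bwd(input_j, p[[paste0("dect", j, "_W")]], g_out, k, s, pad)
    g[[paste0("dect", j, "_W")]] <- bw$gW
    g[[paste0("dect", j, "_b")]] <- bw$gb
    g_out <- if (j > 1) bw$gx * dlrelu(fwd$dpres[[j - 1]]) else bw$gx
  }
  g_f <- matrix(g_out, ncol = B)
  g_fpre <- g_f * dlrelu(matrix(fwd$f_pre, ncol = B))
  g$dec_W <- g_fpre %*% t(fwd$z)
  g$dec_b <- rowSums(g_fpre)
  g_z <- t(p$dec_W) %*% g_fpre

  # latent heads (KL gradients averaged over the batch)
  g_mu <- g_z + (w / B) * fwd$mu
  g_lv <- g_z * fwd$eps * 0.5 * exp(0.5 * fwd$lv) +
    (w / B) * 0.5 * (exp(fwd$lv) - 1)
  g_lv[abs(fwd$lv_raw) > LOGVAR_CLAMP] <- 0
  g$mu_W <- g_mu %*% t(fwd$flat); g$mu_b <- rowSums(g_mu)
  g$lv_W <- g_lv %*% t(fwd$flat); g$lv_b <- rowSums(g_lv)
  g_flat <- t(p$mu_W) %*% g_mu + t(p$lv_W) %*% g_lv

  # encoder
  g_a <- array(g_flat, c(chain[5], chain[5], depths[5], B))
  for (i in 5:1) {
    g_pre <- g_a * dlrelu(fwd$pres[[i]])
    input_i <- if (i == 1) x4 else fwd$acts[[i - 1]]
    bw <- .conv_bwd(input_i, p[[paste0("enc", i, "_W")]], g_pre, k, s, pad)
    g[[paste0("enc", i, "_W")]] <- bw$gW
    g[[paste0("enc", i, "_b")]] <- bw$gb
    g_a <- bw$gx
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
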