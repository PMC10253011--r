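test_that("the encoder halves the spatial size five times and heads match latent_dim", {
  cfg <- vae_config(seed = 1)
  m <- build_vae(cfg)
  expect_identical(m$shape_chain, c(32L, 16L, 8L, 4L, 2L))
  expect_identical(dim(m$params$mu_W), c(2L, 2L * 2L * 512L))
  expect_identical(dim(m$params$lv_W), c(2L, 2L * 2L * 512L))
  expect_length(m$params$mu_b, 2L)
  expect_length(m$params$lv_b, 2L)
})

test_that("non-reducing stride/kernel combinations are rejected with the shape chain", {
  expect_error(build_vae(vae_config(image_side = 48)), "48 -> 24 -> 12 -> 6")
  expect_error(vae_config(encoder_depths = c(8, 16, 32, 64)), "five")
  expect_error(vae_config(encoder_depths = c(8, 8, 16, 32, 64)),
               "strictly increasing")
  expect_error(build_vae(vae_config(kernel_size = 4)), "odd")
})

test_that("the decoder maps any latent point to a full-size image in range", {
  cfg <- tiny_vae_config(seed = 2)
  m <- build_vae(cfg)
  for (z in list(c(0, 0), c(3, -2), c(-4, 4))) {
    img <- vae_decode(m, z)
    expect_identical(dim(img), c(64L, 64L, 3L))
    expect_gte(min(img), 0)
    expect_lte(max(img), 255)
  }
})

test_that("reparameterization follows mean + exp(log_variance / 2) * noise", {
  expect_identical(reparameterize(c(0.3, -1.2), c(0.5, 2), c(0, 0)),
                   c(0.3, -1.2))
  expect_equal(reparameterize(c(1, 0), c(0, 0), c(1, 1)), c(2, 1))
  # Monte-Carlo: empirical mean of draws matches the mean within 3 SE
  withr::local_seed(123)
  n <- 10000
  mu <- c(0.7, -0.4); lv <- c(0.3, -1)
  draws <- vapply(seq_len(n), function(i)
    reparameterize(mu, lv, stats::rnorm(2)), numeric(2))
  se <- exp(0.5 * lv) / sqrt(n)
  expect_true(all(abs(rowMeans(draws) - mu) < 3 * se))
})

test_that("the loss decomposes into reconstruction MSE and a closed-form KL", {
  img <- random_image()
  perfect <- vae_loss(img, img, mean = c(0, 0), log_variance = c(0, 0))
  expect_equal(perfect$total, 0)
  expect_equal(perfect$recon, 0)
  expect_equal(perfect$kl, 0)
  half <- vae_loss(img, img, mean = c(1, 0), log_variance = c(0, 0))
  expect_equal(half$kl, 0.5)
  # independent scalar-loop recomputation of both terms on a random pair
  withr::local_seed(4)
  rec <- random_image()
  mu <- stats::rnorm(2); lv <- stats::rnorm(2)
  got <- vae_loss(img, rec, mu, lv, kl_weight = 0.7)
  kl_ref <- 0
  for (j in 1:2) kl_ref <- kl_ref + 0.5 * (exp(lv[j]) + mu[j]^2 - 1 - lv[j])
  mse_ref <- 0
  for (v in seq_along(img)) mse_ref <- mse_ref + ((img[v] - rec[v]) / 255)^2
  mse_ref <- mse_ref / length(img)
  expect_equal(got$kl, kl_ref)
  expect_equal(got$recon, mse_ref)
  expect_equal(got$total, mse_ref + 0.7 * kl_ref)
  expect_gte(got$kl, 0)
})

test_that("analytic gradients match central finite differences on smooth paths", {
  cfg <- vae_config(image_side = 32, encoder_depths = c(2, 3, 4, 5, 6),
                    epochs = 1, batch_size = 2, kl_weight = 0.3, seed = 3)
  m <- build_vae(cfg)
  p <- m$params
  withr::local_seed(9)
  x4 <- array(stats::runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  eps <- matrix(stats::rnorm(4), 2, 2)
  fwd <- plaquevae:::vae_forward(p, x4, eps, cfg)
  g <- plaquevae:::vae_backward(p, fwd, x4, cfg)
  lossf <- function(p) plaquevae:::vae_loss_terms(
    x4, plaquevae:::vae_forward(p, x4, eps, cfg), cfg$kl_weight)$total
  h <- 1e-5
  # weight matrices and latent heads: smooth in each coordinate almost surely
  # (bias shifts of inner stages can cross leaky-ReLU kinks and are excluded)
  for (nm in c("enc1_W", "enc3_W", "enc5_W", "mu_W", "mu_b", "lv_W", "lv_b",
               "dec_W", "dect2_W", "dect5_W", "dect5_b")) {
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      p_hi <- p; p_hi[[nm]][i] <- p_hi[[nm]][i] + h
      p_lo <- p; p_lo[[nm]][i] <- p_lo[[nm]][i] - h
      fd <- (lossf(p_hi) - lossf(p_lo)) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-3,
                   label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("training reduces the loss on learnable data across seeds", {
  st <- phantom_slices_by_class(rep(1:4, each = 5), seed = 61)
  improved <- vapply(1:3, function(s) {
    m <- train_vae(st$slices, tiny_vae_config(epochs = 8, seed = s))
    tr <- tidy(m)
    tr$total[nrow(tr)] < tr$total[1]
  }, logical(1))
  expect_gte(sum(improved), 2)
})

test_that("the same seed and data reproduce the loss trace exactly", {
  st <- phantom_slices_by_class(c(1, 2, 3, 4, 1, 2, 3, 4), seed = 55)
  cfg <- tiny_vae_config(epochs = 3, seed = 7)
  m1 <- train_vae(st$slices, cfg)
  m2 <- train_vae(st$slices, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$loss_trace), cfg$epochs)
  expect_true(all(m1$loss_trace$kl >= 0))
})

test_that("a single repeated image is memorized to low reconstruction error", {
  st <- generate_phantom(phantom_spec(1, class_sequence = 2, seed = 3))
  img <- standardize_slice(st$slices[[1]])
  cfg <- vae_config(encoder_depths = c(4, 8, 16, 32, 64), epochs = 200,
                    batch_size = 4, learning_rate = 2e-3,
                    kl_weight = 1 / (64^2 * 3), seed = 1)
  m <- train_vae(rep(list(img), 16), cfg)
  z <- vae_encode(m, list(img))
  rec <- vae_decode(m, as.numeric(z[1, c("x", "y")]))
  expect_lt(mean(((rec - img) / 255)^2), 0.01)
})

test_that("encoding is deterministic and labelled stacks carry labels through", {
  st <- phantom_slices_by_class(c(1, 4, 2, 3), seed = 19)
  m <- train_vae(st$slices, tiny_vae_config(epochs = 2, seed = 5))
  e1 <- vae_encode(m, st)
  e2 <- vae_encode(m, st)
  expect_identical(e1, e2)
  expect_identical(e1$label, st$labels)
  expect_true(all(is.finite(e1$x)) && all(is.finite(e1$y)))
  # single image encodes to the same point as its batch position
  single <- vae_encode(m, st$slices[[2]])
  expect_equal(single$x, e1$x[2])
  expect_equal(single$y, e1$y[2])
})

test_that("models round-trip through save and load", {
  dir <- withr::local_tempdir()
  st <- phantom_slices_by_class(c(1, 2, 3, 4), seed = 23)
  m <- train_vae(st$slices, tiny_vae_config(epochs = 2, seed = 5))
  save_vae(m, file.path(dir, "model"))
  back <- load_vae(file.path(dir, "model"))
  expect_identical(back$params, m$params)
  expect_identical(vae_encode(back, st), vae_encode(m, st))
  g <- glance(m)
  expect_identical(g$epochs, 2L)
  expect_true(is.finite(g$final_total))
})
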