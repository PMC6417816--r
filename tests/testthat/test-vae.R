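test_that("architecture follows the depth convention exactly", {
  g <- 80
  m1 <- build_vae(vae_config(depth = 1, seed = 1), g)
  expect_named(m1$params, c("mu.W", "mu.b", "lv.W", "lv.b", "out.W", "out.b"))
  expect_equal(dim(m1$params$mu.W), c(g, 20))
  expect_equal(dim(m1$params$out.W), c(20, g))

  m3 <- build_vae(vae_config(depth = 3, first_hidden_dim = 500,
                             hidden_dim = 100, seed = 1), g)
  expect_equal(dim(m3$params$enc1.W), c(g, 500))
  expect_equal(dim(m3$params$enc2.W), c(500, 100))
  expect_equal(dim(m3$params$mu.W), c(100, 20))
  # decoder mirrors the encoder
  expect_equal(dim(m3$params$dec1.W), c(20, 100))
  expect_equal(dim(m3$params$dec2.W), c(100, 500))
  expect_equal(dim(m3$params$out.W), c(500, g))

  expect_error(vae_config(depth = 4), "depth")

  a <- build_vae(vae_config(depth = 2, seed = 5), g)
  b <- build_vae(vae_config(depth = 2, seed = 5), g)
  expect_identical(a$params, b$params)
})

test_that("KL closed form matches a quadrature oracle", {
  expect_equal(kl_divergence(0, 0), 0)
  expect_equal(kl_divergence(1, 0), 0.5)

  # independent dims: KL = sum over dims of the 1-D KL integral
  # \int N(x; mu, s2) log(N(x; mu, s2) / N(x; 0, 1)) dx
  kl_1d_quad <- function(mu, s2) {
    f <- function(x) {
      p <- stats::dnorm(x, mu, sqrt(s2))
      p * (stats::dnorm(x, mu, sqrt(s2), log = TRUE) -
             stats::dnorm(x, 0, 1, log = TRUE))
    }
    stats::integrate(f, mu - 12 * sqrt(s2) - 12, mu + 12 * sqrt(s2) + 12,
                     rel.tol = 1e-10)$value
  }
  set.seed(1)
  mu <- stats::rnorm(20, sd = 0.8)
  logvar <- stats::rnorm(20, sd = 0.5)
  oracle <- sum(mapply(kl_1d_quad, mu, exp(logvar)))
  expect_equal(kl_divergence(mu, logvar), oracle, tolerance = 1e-4)
  expect_gte(kl_divergence(mu, logvar), 0)
})

test_that("reparameterization has the right moments and limits", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(3, -1e6, 100), 3)
  set.seed(2)
  noise <- stats::rnorm(1e5)
  z <- reparameterize(0.7, log(2.25), noise)
  expect_equal(mean(z), 0.7, tolerance = 0.02)
  expect_equal(stats::var(z), 2.25, tolerance = 0.05)
})

test_that("loss matches a hand-computed BCE + KL toy case", {
  # 2 cells x 3 genes, every term written out by hand
  x <- rbind(c(1, 0, 0.5), c(0, 1, 0.25))
  xr <- rbind(c(0.9, 0.2, 0.5), c(0.1, 0.8, 0.5))
  bce_by_hand <- -(log(0.9) + log(0.8) + 0.5 * log(0.5) + 0.5 * log(0.5) +
                     log(0.9) + log(0.8) + 0.25 * log(0.5) +
                     0.75 * log(0.5)) / 2
  mu <- rbind(c(0.5, 0), c(0, -0.5))
  lv <- rbind(c(0, 0.1), c(-0.1, 0))
  kl_by_hand <- (0.5 * (0.25 + 1 - 0 - 1) +
                   0.5 * (0 + exp(0.1) - 0.1 - 1) +
                   0.5 * (0 + exp(-0.1) + 0.1 - 1) +
                   0.5 * (0.25 + 1 - 0 - 1)) / 2
  ls <- vae_loss(x, xr, mu, lv, kl_weight = 2)
  expect_equal(ls$reconstruction, bce_by_hand)
  expect_equal(ls$kl, kl_by_hand)
  expect_equal(ls$total, bce_by_hand + 2 * kl_by_hand)

  # perfect binary reconstruction at the prior -> zero loss
  xb <- rbind(c(1, 0, 1))
  z0 <- matrix(0, 1, 2)
  ls0 <- vae_loss(xb, xb, z0, z0, kl_weight = 5)
  expect_equal(ls0$total, 0, tolerance = 1e-5)
  # kl_weight 0 -> total equals reconstruction
  ls1 <- vae_loss(x, xr, mu, lv, kl_weight = 0)
  expect_equal(ls1$total, ls1$reconstruction)
  expect_error(vae_loss(x, xr + 1, mu, lv), "guard")
})

test_that("training reduces loss, is deterministic and respects epochs = 0", {
  ds <- easy_dataset(n_cells = 200, n_genes = 120)
  norm <- zero_one_scale(tpm_normalize(ds$counts))
  cfg <- vae_config(depth = 2, epochs = 15, batch_size = 50,
                    learning_rate = 1e-3, seed = 4)
  model <- build_vae(cfg, 120)
  fit <- train_vae(model, norm)
  expect_lt(fit$history$total[15], fit$history$total[1])
  expect_equal(nrow(fit$history), 15)
  expect_true(all(fit$history$kl >= 0))

  fit2 <- train_vae(build_vae(cfg, 120), norm)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)

  cfg0 <- vae_config(depth = 2, epochs = 0, seed = 4)
  m0 <- build_vae(cfg0, 120)
  expect_identical(train_vae(m0, norm)$params, m0$params)

  expect_error(train_vae(build_vae(vae_config(batch_size = 999), 120), norm),
               "batch_size")
})

test_that("compiled and reference training loops agree", {
  ds <- easy_dataset(n_cells = 150, n_genes = 100)
  norm <- zero_one_scale(tpm_normalize(ds$counts))
  for (depth in c(1, 3)) {
    cfg <- vae_config(depth = depth, first_hidden_dim = 60, hidden_dim = 40,
                      epochs = 4, batch_size = 64, learning_rate = 1e-3,
                      precision = "double", seed = 6)
    f_cpp <- train_vae(build_vae(cfg, 100), norm, backend = "cpp")
    f_r <- train_vae(build_vae(cfg, 100), norm, backend = "R")
    expect_equal(f_cpp$params, f_r$params, tolerance = 1e-12)
    expect_equal(f_cpp$history, f_r$history, tolerance = 1e-12)
  }
  # the single-precision default tracks the double trajectory closely over
  # a short run
  cfg_s <- vae_config(depth = 2, first_hidden_dim = 60, epochs = 4,
                      batch_size = 64, learning_rate = 1e-3, seed = 6)
  cfg_d <- cfg_s
  cfg_d$precision <- "double"
  f_s <- train_vae(build_vae(cfg_s, 100), norm)
  f_d <- train_vae(build_vae(cfg_d, 100), norm)
  expect_equal(f_s$history$total, f_d$history$total, tolerance = 1e-3)
})

test_that("encoding is pure, shaped and row-consistent", {
  ds <- easy_dataset(n_cells = 120, n_genes = 90)
  norm <- zero_one_scale(tpm_normalize(ds$counts))
  cfg <- vae_config(depth = 2, epochs = 5, batch_size = 40, seed = 7)
  fit <- train_vae(build_vae(cfg, 90), norm)
  emb <- encode_cells(fit, norm)
  expect_equal(dim(emb$coords), c(120, 20))
  expect_equal(emb$method_tag$method, "vae")

  # duplicate input cells encode identically; subsets encode identically
  dup <- norm$values[, c(1, 1, 2)]
  e2 <- encode_cells(fit, dup)
  expect_equal(e2$coords[1, ], e2$coords[2, ])
  expect_equal(unname(e2$coords[3, ]), unname(emb$coords[2, ]))
  expect_error(encode_cells(fit, norm$values[1:10, ]), "gene count")
})

test_that("with no KL pressure a low-rank toy is reconstructed near its floor", {
  # rank-3 noiseless data in [0,1]: a plain-autoencoder limit
  set.seed(8)
  basis <- matrix(stats::runif(3 * 40), 3, 40)
  weights <- matrix(stats::runif(50 * 3), 50, 3)
  X <- weights %*% basis
  X <- X / max(X)
  cfg <- vae_config(depth = 2, first_hidden_dim = 30, latent_dim = 5,
                    epochs = 400, batch_size = 25, learning_rate = 2e-3,
                    kl_weight = 0, recon_loss = "mse", seed = 9)
  fit <- train_vae(build_vae(cfg, 40), t(X))
  # mse per cell summed over 40 genes; floor is 0 for rank-3 data with 5
  # latent dims, so a small residual indicates the limit is approached
  expect_lt(tail(fit$history$reconstruction, 1), 0.05)
  expect_lt(tail(fit$history$reconstruction, 1),
            0.02 * fit$history$reconstruction[1])
})

test_that("a well-separated simulation yields a high-NMI latent space", {
  ds <- easy_dataset(n_cells = 400, n_genes = 300, seed = 21)
  norm <- zero_one_scale(tpm_normalize(ds$counts))
  cfg <- vae_config(depth = 2, first_hidden_dim = 100, epochs = 60,
                    batch_size = 50, learning_rate = 1e-3, seed = 10)
  fit <- train_vae(build_vae(cfg, 300), norm)
  emb <- encode_cells(fit, norm)
  km <- kmeans_protocol(emb, ds$labels, repeats = 20, seed = 1)
  expect_gte(km$nmi_mean, 0.9)
})
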