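#' Configuration of a Tybalt-style variational autoencoder
#'
#' The architecture is named by its total layer count, matching the
#' one/two/three-layer convention used for gene-expression VAEs: `depth = 1`
#' maps the input directly to the 20-dimensional Gaussian latent code;
#' `depth = 2` inserts one hidden layer; `depth = 3` inserts two.  The
#' decoder always mirrors the encoder.  Hidden units are rectifiers, the
#' output is a sigmoid (data are zero-one scaled), and training minimizes
#' binary cross-entropy reconstruction loss plus the KL divergence between
#' the approximate posterior and the standard-normal prior, with Adam.
#'
#' @param depth total layer count, 1, 2 or 3.
#' @param hidden_dim width of the (second) hidden layer, default 100.
#' @param first_hidden_dim width of the first hidden layer (the tuned
#'   "dimensionality of the first layer"); defaults to `hidden_dim`.
#' @param latent_dim latent features, default 20.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size; must not exceed the number of cells.
#' @param epochs number of full passes over the training cells; no early
#'   stopping.
#' @param kl_weight weight on the KL term (constant by default).
#' @param kl_warmup_epochs if positive, the KL weight ramps linearly from 0
#'   to `kl_weight` over this many epochs (warm-up), then stays constant.
#' @param recon_loss `"bce"` (default) or `"mse"`.
#' @param precision `"single"` (default; the working precision of the
#'   deep-learning frameworks this model family comes from, and about twice
#'   as fast) or `"double"` (matches the pure-R reference loop exactly).
#' @param seed integer seed controlling initialization, shuffling and
#'   reparameterization noise.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(depth = 2, hidden_dim = 100, first_hidden_dim = NULL,
                       latent_dim = 20, learning_rate = 0.0005,
                       batch_size = 50, epochs = 50, kl_weight = 1,
                       kl_warmup_epochs = 0, recon_loss = c("bce", "mse"),
                       precision = c("single", "double"),
                       seed = 1L) {
  recon_loss <- match.arg(recon_loss)
  precision <- match.arg(precision)
  if (!depth %in% 1:3) stop("depth must be 1, 2 or 3")
  if (is.null(first_hidden_dim)) first_hidden_dim <- hidden_dim
  if (min(hidden_dim, first_hidden_dim, latent_dim, learning_rate,
          batch_size, epochs + 1) <= 0)
    stop("dims, rates, batch size must be positive (epochs >= 0)")
  structure(list(
    depth = as.integer(depth), hidden_dim = as.integer(hidden_dim),
    first_hidden_dim = as.integer(first_hidden_dim),
    latent_dim = as.integer(latent_dim), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    kl_weight = kl_weight, kl_warmup_epochs = kl_warmup_epochs,
    recon_loss = recon_loss, precision = precision, seed = as.integer(seed)
  ), class = "vae_config")
}

#' @export
print.vae_config <- function(x, ...) {
  widths <- c(encoder_widths(x), x$latent_dim)
  cat(sprintf(
    "vae_config: depth %d (G -> %s), lr %g, batch %d, epochs %d, %s loss\n",
    x$depth, paste(widths, collapse = " -> "), x$learning_rate,
    x$batch_size, x$epochs, x$recon_loss
  ))
  invisible(x)
}

# hidden-layer widths of the encoder, input side first
encoder_widths <- function(config) {
  switch(config$depth,
         integer(0),
         config$first_hidden_dim,
         c(config$first_hidden_dim, config$hidden_dim))
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Build (initialize) a VAE model
#'
#' Allocates encoder hidden layers, the latent mean and log-variance heads,
#' and the mirrored decoder, with Glorot-uniform weights and zero biases.
#' Initialization is deterministic under `config$seed`.
#'
#' @param config a [vae_config()].
#' @param n_genes input dimensionality.
#' @return object of class `vae_model` with `$params` (named weight
#'   matrices), `$config`, `$n_genes` and an empty `$history`.
#' @export
build_vae <- function(config, n_genes) {
  stopifnot(inherits(config, "vae_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  widths <- encoder_widths(config)
  dims <- c(n_genes, widths)
  params <- list()
  for (i in seq_along(widths)) {
    params[[paste0("enc", i, ".W")]] <- glorot(dims[i], dims[i + 1])
    params[[paste0("enc", i, ".b")]] <- numeric(dims[i + 1])
  }
  top <- dims[length(dims)]
  params[["mu.W"]] <- glorot(top, config$latent_dim)
  params[["mu.b"]] <- numeric(config$latent_dim)
  params[["lv.W"]] <- glorot(top, config$latent_dim)
  params[["lv.b"]] <- numeric(config$latent_dim)
  ddims <- c(config$latent_dim, rev(widths))
  for (i in seq_along(widths)) {
    params[[paste0("dec", i, ".W")]] <- glorot(ddims[i], ddims[i + 1])
    params[[paste0("dec", i, ".b")]] <- numeric(ddims[i + 1])
  }
  params[["out.W"]] <- glorot(ddims[length(ddims)], n_genes)
  params[["out.b"]] <- numeric(n_genes)

  structure(list(params = params, config = config,
                 n_genes = as.integer(n_genes),
                 n_hidden = length(widths),
                 history = NULL, trained_epochs = 0L),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("vae_model: depth %d, %d genes, %d parameters, %d epoch(s) trained\n",
              x$config$depth, x$n_genes, n_par, x$trained_epochs))
  invisible(x)
}

relu <- function(x) x * (x > 0)

# full forward pass; X is cells x genes in [0,1]; eps is the standard-normal
# noise matrix (NULL -> use the posterior mean, no sampling)
vae_forward <- function(model, X, eps = NULL) {
  p <- model$params
  h_in <- list()
  a <- list()
  h <- X
  for (i in seq_len(model$n_hidden)) {
    h_in[[i]] <- h
    a[[i]] <- sweep_add(h %*% p[[paste0("enc", i, ".W")]],
                        p[[paste0("enc", i, ".b")]])
    h <- relu(a[[i]])
  }
  mu <- sweep_add(h %*% p$mu.W, p$mu.b)
  lv <- sweep_add(h %*% p$lv.W, p$lv.b)
  z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  d_in <- list()
  da <- list()
  d <- z
  for (i in seq_len(model$n_hidden)) {
    d_in[[i]] <- d
    da[[i]] <- sweep_add(d %*% p[[paste0("dec", i, ".W")]],
                         p[[paste0("dec", i, ".b")]])
    d <- relu(da[[i]])
  }
  logits <- sweep_add(d %*% p$out.W, p$out.b)
  xr <- stats::plogis(logits)
  list(h_in = h_in, a = a, h_top = h, mu = mu, lv = lv, z = z,
       d_in = d_in, da = da, d_top = d, xr = xr)
}

sweep_add <- function(m, b) m + rep(b, each = nrow(m))

#' Closed-form KL divergence to the standard-normal prior
#'
#' For a diagonal Gaussian posterior `N(mu, diag(sigma^2))` with
#' `logvar = log(sigma^2)`, returns
#' `sum_j 0.5 * (mu_j^2 + sigma_j^2 - logvar_j - 1)`, the KL divergence to
#' `N(0, I)`.  For matrix inputs (cells in rows) the per-cell KL is averaged.
#'
#' @param mu,logvar numeric vectors (one posterior) or matrices (one row per
#'   cell).
#' @return non-negative scalar.
#' @export
kl_divergence <- function(mu, logvar) {
  stopifnot(all(is.finite(mu)), all(is.finite(logvar)))
  per <- 0.5 * (mu^2 + exp(logvar) - logvar - 1)
  if (is.matrix(mu)) mean(rowSums(per)) else sum(per)
}

#' Reparameterization trick
#'
#' `z = mu + exp(logvar / 2) * noise`, expressing a posterior sample as a
#' deterministic function of the parameters and standard-normal noise.
#'
#' @param mu,logvar,noise conformable numeric vectors/matrices.
#' @return `z`, same shape.
#' @export
reparameterize <- function(mu, logvar, noise) {
  mu + exp(0.5 * logvar) * noise
}

#' VAE loss (reconstruction + weighted KL)
#'
#' Reconstruction is elementwise binary cross-entropy summed over genes and
#' averaged over cells (or mean-squared error summed over genes, if chosen);
#' the KL term is summed over latent dimensions and averaged over cells;
#' `total = reconstruction + kl_weight * kl`.
#'
#' @param x,x_recon observed and reconstructed values in `[0, 1]`; vectors or
#'   cells x genes matrices.
#' @param mu,logvar posterior parameters, same cell count as `x`.
#' @param kl_weight weight on the KL term.
#' @param recon_loss `"bce"` or `"mse"`.
#' @return list with `total`, `reconstruction`, `kl`.
#' @export
vae_loss <- function(x, x_recon, mu, logvar, kl_weight = 1,
                     recon_loss = "bce") {
  guard <- 1e-6
  if (any(x_recon < -guard) || any(x_recon > 1 + guard))
    stop("x_recon outside [0,1] beyond the numerical guard")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x_recon)) x_recon <- matrix(x_recon, nrow = 1)
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1)
  if (!is.matrix(logvar)) logvar <- matrix(logvar, nrow = 1)
  n <- nrow(x)
  if (recon_loss == "bce") {
    p <- pmin(pmax(x_recon, 1e-7), 1 - 1e-7)
    rec <- -sum(x * log(p) + (1 - x) * log(1 - p)) / n
  } else {
    rec <- sum((x - x_recon)^2) / n
  }
  kl <- sum(0.5 * (mu^2 + exp(logvar) - logvar - 1)) / n
  list(total = rec + kl_weight * kl, reconstruction = rec, kl = kl)
}

#' Train a VAE by minibatch Adam
#'
#' Runs exactly `config$epochs` epochs of shuffled minibatch optimization of
#' the reconstruction + KL objective (no early stopping, no gradient
#' clipping), recording per-epoch mean total/reconstruction/KL losses in
#' `$history`.  All randomness (epoch shuffles, reparameterization noise) is
#' drawn up front from R's RNG under `config$seed`, then consumed by the
#' optimization loop, so training is bit-reproducible and both backends —
#' the compiled default and the pure-R reference loop — follow the same
#' stream.  A non-finite loss aborts with a condition of class
#' `"vae_divergence"` carrying the epoch and batch: deep or long-trained
#' configurations can genuinely fail to train, and the sweep harness scores
#' such cells as failures rather than dropping them.
#'
#' @param model a [build_vae()] model.
#' @param data zero-one-scaled genes x cells matrix (a `normalized_matrix`
#'   tagged `zero_one`, or a plain matrix with values in `[0, 1]`).
#' @param backend `"cpp"` (compiled, default) or `"R"` (reference loop; same
#'   results, slower).
#' @return the trained `vae_model` (history filled, `trained_epochs` set).
#' @export
train_vae <- function(model, data, backend = c("cpp", "R")) {
  stopifnot(inherits(model, "vae_model"))
  backend <- match.arg(backend)
  config <- model$config
  X <- t(as_value_matrix(data))
  if (inherits(data, "normalized_matrix") && !"zero_one" %in% data$tags)
    warning("training data is not tagged zero_one")
  if (min(X) < 0 || max(X) > 1) stop("training data must lie in [0, 1]")
  if (ncol(X) != model$n_genes) stop("gene count does not match the model")
  n <- nrow(X)
  if (config$batch_size > n) stop("batch_size exceeds the number of cells")
  if (config$epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), total = numeric(0),
                                reconstruction = numeric(0), kl = numeric(0))
    return(model)
  }

  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)

  epochs <- config$epochs
  perms <- t(vapply(seq_len(epochs), function(e) sample.int(n),
                    integer(n)))
  noise <- matrix(stats::rnorm(epochs * n * config$latent_dim),
                  epochs * n, config$latent_dim)
  klw <- rep(config$kl_weight, epochs)
  if (config$kl_warmup_epochs > 0)
    klw <- klw * pmin(1, seq_len(epochs) / config$kl_warmup_epochs)

  if (backend == "cpp") {
    fit <- train_vae_cpp(model$params, X, perms, noise, model$n_hidden,
                         config$batch_size, config$learning_rate, klw,
                         config$recon_loss == "bce",
                         identical(config$precision %||% "single", "single"))
    if (fit$diverged) {
      stop(structure(class = c("vae_divergence", "error", "condition"),
                     list(message = sprintf(
                       "non-finite loss at epoch %d, batch %d (recon %g, kl %g)",
                       fit$epoch, fit$batch, fit$recon, fit$kl),
                       call = NULL, epoch = fit$epoch, batch = fit$batch)))
    }
    p <- fit$params
    hist <- fit$history
  } else {
    p <- model$params
    m <- lapply(p, function(w) w * 0)
    v <- lapply(p, function(w) w * 0)
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    lr <- config$learning_rate
    step <- 0L
    hist <- matrix(NA_real_, nrow = epochs, ncol = 3)
    for (epoch in seq_len(epochs)) {
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- c(0, 0, 0)
      for (bi in seq_along(starts)) {
        s <- starts[bi]
        pos <- s:min(s + config$batch_size - 1L, n)
        xb <- X[perms[epoch, pos], , drop = FALSE]
        eps <- noise[(epoch - 1L) * n + pos, , drop = FALSE]
        fw <- vae_forward_params(p, model$n_hidden, xb, eps)
        ls <- batch_loss(xb, fw, klw[epoch], config$recon_loss)
        if (!all(is.finite(unlist(ls)))) {
          stop(structure(class = c("vae_divergence", "error", "condition"),
                         list(message = sprintf(
                           "non-finite loss at epoch %d, batch %d (recon %g, kl %g)",
                           epoch, bi, ls$reconstruction, ls$kl),
                           call = NULL, epoch = epoch, batch = bi)))
        }
        g <- vae_backward(p, model$n_hidden, xb, fw, eps, klw[epoch],
                          config$recon_loss)
        step <- step + 1L
        c1 <- 1 - b1^step
        c2 <- 1 - b2^step
        for (nm in names(p)) {
          gi <- g[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gi
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gi * gi
          p[[nm]] <- p[[nm]] - lr * (m[[nm]] / c1) /
            (sqrt(v[[nm]] / c2) + adam_eps)
        }
        ep_loss <- ep_loss + c(ls$total, ls$reconstruction, ls$kl)
      }
      hist[epoch, ] <- ep_loss / length(starts)
    }
  }
  # matrix products propagate gene/cell dimnames into the parameters in the
  # reference loop; strip them so both backends return identical objects
  model$params <- lapply(p, function(w) {
    if (is.matrix(w)) dimnames(w) <- NULL else names(w) <- NULL
    w
  })
  model$history <- data.frame(
    epoch = seq_len(epochs),
    total = hist[, 1], reconstruction = hist[, 2], kl = hist[, 3]
  )
  model$trained_epochs <- epochs
  model
}

# forward taking a raw parameter list (used inside the training loop where
# the model object's params are stale)
vae_forward_params <- function(p, n_hidden, X, eps) {
  fake <- list(params = p, n_hidden = n_hidden)
  vae_forward(fake, X, eps)
}

batch_loss <- function(x, fw, klw, recon_loss) {
  n <- nrow(x)
  if (recon_loss == "bce") {
    pr <- pmin(pmax(fw$xr, 1e-7), 1 - 1e-7)
    rec <- -sum(x * log(pr) + (1 - x) * log(1 - pr)) / n
  } else {
    rec <- sum((x - fw$xr)^2) / n
  }
  kl <- sum(0.5 * (fw$mu^2 + exp(fw$lv) - fw$lv - 1)) / n
  list(total = rec + klw * kl, reconstruction = rec, kl = kl)
}

vae_backward <- function(p, n_hidden, x, fw, eps, klw, recon_loss) {
  n <- nrow(x)
  g <- list()
  dl <- if (recon_loss == "bce") (fw$xr - x) / n
        else 2 * (fw$xr - x) * fw$xr * (1 - fw$xr) / n
  g[["out.W"]] <- crossprod(fw$d_top, dl)
  g[["out.b"]] <- colSums(dl)
  gd <- dl %*% t(p$out.W)
  for (i in rev(seq_len(n_hidden))) {
    gd <- gd * (fw$da[[i]] > 0)
    g[[paste0("dec", i, ".W")]] <- crossprod(fw$d_in[[i]], gd)
    g[[paste0("dec", i, ".b")]] <- colSums(gd)
    gd <- gd %*% t(p[[paste0("dec", i, ".W")]])
  }
  g_mu <- gd + klw * fw$mu / n
  g_lv <- gd * eps * exp(0.5 * fw$lv) * 0.5 + klw * 0.5 * (exp(fw$lv) - 1) / n
  g[["mu.W"]] <- crossprod(fw$h_top, g_mu)
  g[["mu.b"]] <- colSums(g_mu)
  g[["lv.W"]] <- crossprod(fw$h_top, g_lv)
  g[["lv.b"]] <- colSums(g_lv)
  gh <- g_mu %*% t(p$mu.W) + g_lv %*% t(p$lv.W)
  for (i in rev(seq_len(n_hidden))) {
    gh <- gh * (fw$a[[i]] > 0)
    g[[paste0("enc", i, ".W")]] <- crossprod(fw$h_in[[i]], gh)
    g[[paste0("enc", i, ".b")]] <- colSums(gh)
    gh <- gh %*% t(p[[paste0("enc", i, ".W")]])
  }
  g
}

#' Encode cells into the latent space
#'
#' Returns the posterior mean `mu(x)` per cell (no sampling), the
#' conventional deterministic embedding.  Encoding is a pure function of the
#' model parameters, so encoding the same cells in any grouping gives
#' identical rows.
#'
#' @param model a trained `vae_model`.
#' @param data zero-one-scaled genes x cells matrix or `normalized_matrix`.
#' @return a [latent_embedding()] with `latent_dim` columns.
#' @export
encode_cells <- function(model, data) {
  X <- t(as_value_matrix(data))
  if (ncol(X) != model$n_genes) stop("gene count does not match the model")
  fw <- vae_forward(model, X, eps = NULL)
  coords <- fw$mu
  rownames(coords) <- rownames(X) %||% paste0("cell", seq_len(nrow(X)))
  colnames(coords) <- paste0("L", seq_len(ncol(coords)))
  latent_embedding(coords, method = "vae",
                   params = unclass(model$config))
}

#' Reconstruct cells through the decoder
#'
#' Passes the posterior mean through the decoder; mainly a diagnostic (e.g.
#' checking the plain-autoencoder limit at `kl_weight = 0`).
#'
#' @inheritParams encode_cells
#' @return genes x cells matrix of reconstructions in `[0, 1]`.
#' @export
vae_reconstruct <- function(model, data) {
  X <- t(as_value_matrix(data))
  fw <- vae_forward(model, X, eps = NULL)
  t(fw$xr)
}
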