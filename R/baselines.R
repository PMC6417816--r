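#' Latent embedding container
#'
#' A cells x d coordinate matrix tagged with the method and its full
#' hyperparameter record, so any embedding can be re-run from its record.
#'
#' @param coords cells x d numeric matrix (finite entries; rownames = cell
#'   ids).
#' @param method method name string.
#' @param params named list of every hyperparameter (including the seed for
#'   stochastic methods).
#' @return object of class `latent_embedding` with `$coords`, `$method_tag`,
#'   `$d`.
#' @export
latent_embedding <- function(coords, method, params = list()) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("embedding coordinates must be finite")
  structure(list(coords = coords,
                 method_tag = c(list(method = method), params),
                 d = ncol(coords)),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("latent_embedding: %s, %d cells x %d dims\n",
              x$method_tag$method, nrow(x$coords), x$d))
  invisible(x)
}

embed_input <- function(data) {
  # methods operate on cells in rows
  t(as_value_matrix(data))
}

#' PCA embedding
#'
#' Top principal-component scores of the (cells x genes) matrix, computed by
#' truncated SVD.  Deterministic up to sign; the sign of each component is
#' fixed so its largest-magnitude gene loading is positive.
#'
#' @param data genes x cells matrix or `normalized_matrix` (conventionally
#'   `log1p(TPM)` for this method).
#' @param out_dim number of components (default 20, the parity choice with
#'   the VAE latent width).
#' @param seed seed for the randomized SVD start.
#' @param center,scale. passed to the underlying decomposition.
#' @return a `latent_embedding`.
#' @export
embed_pca <- function(data, out_dim = 20, seed = 1L, center = TRUE,
                      scale. = FALSE) {
  X <- embed_input(data)
  if (out_dim > min(dim(X)))
    stop("out_dim must not exceed min(n_genes, n_cells)")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (out_dim <= min(dim(X)) / 3 && min(dim(X)) > 50) {
    fit <- irlba::prcomp_irlba(X, n = out_dim, center = center,
                               scale. = scale.)
  } else {
    fit <- stats::prcomp(X, rank. = out_dim, center = center, scale. = scale.)
  }
  scores <- fit$x[, seq_len(out_dim), drop = FALSE]
  load <- fit$rotation[, seq_len(out_dim), drop = FALSE]
  flip <- vapply(seq_len(out_dim), function(j) {
    sign(load[which.max(abs(load[, j])), j])
  }, 1)
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(out_dim))
  latent_embedding(scores, "pca",
                   list(out_dim = out_dim, center = center, scale = scale.,
                        seed = seed))
}

#' t-SNE embedding
#'
#' Barnes-Hut t-SNE of the cells; stochastic, reproducible under `seed`.
#'
#' @inheritParams embed_pca
#' @param out_dim output dimensionality (default 2, the conventional regime).
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (n_cells - 1) / 3`.
#' @param seed RNG seed (recorded in the method tag).
#' @return a `latent_embedding`.
#' @export
embed_tsne <- function(data, out_dim = 2, perplexity = 30, seed = 1L) {
  X <- embed_input(data)
  n <- nrow(X)
  if (perplexity >= (n - 1) / 3)
    stop(sprintf("perplexity must be < (n_cells - 1)/3 = %.2f", (n - 1) / 3))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(X, dims = out_dim, perplexity = perplexity,
                      check_duplicates = FALSE, pca = ncol(X) > 50,
                      num_threads = 1)
  coords <- fit$Y
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("TSNE", seq_len(out_dim))
  latent_embedding(coords, "tsne",
                   list(out_dim = out_dim, perplexity = perplexity,
                        seed = seed))
}

#' UMAP embedding
#'
#' @inheritParams embed_tsne
#' @param n_neighbors,min_dist UMAP neighbourhood size and minimum embedding
#'   distance (library defaults 15 and 0.1, frozen here for
#'   reproducibility).
#' @return a `latent_embedding`.
#' @export
embed_umap <- function(data, out_dim = 2, n_neighbors = 15, min_dist = 0.1,
                       seed = 1L) {
  X <- embed_input(data)
  if (n_neighbors >= nrow(X))
    stop("n_neighbors must be smaller than the number of cells")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  coords <- uwot::umap(X, n_components = out_dim, n_neighbors = n_neighbors,
                       min_dist = min_dist, n_threads = 1,
                       n_sgd_threads = 1)
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("UMAP", seq_len(out_dim))
  latent_embedding(coords, "umap",
                   list(out_dim = out_dim, n_neighbors = n_neighbors,
                        min_dist = min_dist, seed = seed))
}

#' External ZIFA adapter
#'
#' Zero-inflated factor analysis is not reimplemented here; if a
#' user-supplied adapter executable is available it is invoked as
#' `adapter input.tsv output.tsv out_dim` where `input.tsv` is the cells x
#' genes matrix and `output.tsv` must come back as a cells x out_dim table
#' (no header).  Without an adapter the method is cleanly skipped: the
#' return value has class `latent_embedding_skipped` and downstream report
#' code records the row as `"zifa: skipped"` instead of failing.
#'
#' @inheritParams embed_pca
#' @param adapter_path path to the adapter executable, or `NULL`.
#' @return a `latent_embedding`, or a `latent_embedding_skipped` marker.
#' @export
embed_external_zifa <- function(data, out_dim = 2, adapter_path = NULL) {
  if (is.null(adapter_path) || !file.exists(adapter_path)) {
    message("zifa: skipped (no adapter installed)")
    return(structure(list(method_tag = list(method = "zifa",
                                            status = "skipped")),
                     class = "latent_embedding_skipped"))
  }
  X <- embed_input(data)
  inp <- tempfile(fileext = ".tsv")
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(inp, out)))
  utils::write.table(X, inp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  status <- system2(adapter_path, c(inp, out, out_dim))
  if (status != 0 || !file.exists(out))
    stop("ZIFA adapter failed with status ", status)
  coords <- as.matrix(utils::read.table(out, sep = "\t"))
  if (nrow(coords) != nrow(X))
    stop("ZIFA adapter returned a wrong number of rows")
  dimnames(coords) <- list(rownames(X), paste0("ZIFA", seq_len(ncol(coords))))
  latent_embedding(coords, "zifa",
                   list(out_dim = out_dim, adapter = adapter_path))
}
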