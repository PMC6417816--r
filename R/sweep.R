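#' Hyperparameter grid specification
#'
#' Cartesian grid over the tuned VAE hyperparameters: learning rate, batch
#' size, epochs, depth and first-hidden-layer width, plus replicate seeds.
#' Defaults are the benchmark's full tuning grid (batch 50/100/200, epochs
#' 25/50/100/200, depth 2/3, first layer 100/250/500, learning rates
#' 0.0005/0.001/0.002), one replicate seed per cell.
#'
#' @param learning_rates,batch_sizes,epochs,depths,first_hidden_dims
#'   non-empty value lists.
#' @param replicate_seeds integer seeds; each grid cell is run once per
#'   seed.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(learning_rates = c(0.0005, 0.001, 0.002),
                      batch_sizes = c(50, 100, 200),
                      epochs = c(25, 50, 100, 200),
                      depths = c(2, 3),
                      first_hidden_dims = c(100, 250, 500),
                      replicate_seeds = 1L) {
  lists <- list(learning_rates = learning_rates, batch_sizes = batch_sizes,
                epochs = epochs, depths = depths,
                first_hidden_dims = first_hidden_dims,
                replicate_seeds = replicate_seeds)
  if (any(vapply(lists, length, 1L) == 0))
    stop("all grid lists must be non-empty")
  structure(lists, class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cells x %d seed(s)\n",
              grid_size(x) / length(x$replicate_seeds),
              length(x$replicate_seeds)))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @return `grid_size()`: total number of (cell, seed) runs.
#' @export
grid_size <- function(grid) {
  nrow(expand_grid_spec(grid))
}

# deterministic lexicographic expansion (sorted values) so the resume ledger
# is stable across runs
expand_grid_spec <- function(grid) {
  g <- expand.grid(
    seed = sort(grid$replicate_seeds),
    first_hidden_dim = sort(grid$first_hidden_dims),
    epochs = sort(grid$epochs),
    batch_size = sort(grid$batch_sizes),
    learning_rate = sort(grid$learning_rates),
    depth = sort(grid$depths),
    KEEP.OUT.ATTRS = FALSE
  )
  g <- g[, c("depth", "learning_rate", "batch_size", "epochs",
             "first_hidden_dim", "seed")]
  g[do.call(order, g), , drop = FALSE]
}

cell_id <- function(dataset_id, row) {
  sprintf("%s_d%d_l%g_b%d_e%d_c%d_s%d", dataset_id, row$depth,
          row$learning_rate, row$batch_size, row$epochs,
          row$first_hidden_dim, row$seed)
}

#' Run a VAE hyperparameter sweep
#'
#' Executes every (dataset x grid cell x replicate seed) combination: the
#' counts are TPM- then zero-one-normalized, the VAE is trained on a
#' stratified 90% split under the cell's hyperparameters, all cells are
#' encoded, and the latent space is scored by the repeated k-means protocol.
#' A training failure (non-finite loss) never aborts the sweep: the cell is
#' recorded with NMI/ARI 0 and `failed = TRUE`, because failed runs are part
#' of the tuning landscape being measured.  With `out_dir` set, each
#' completed cell is written to a plain-text ledger and an interrupted sweep
#' resumes without recomputation or duplication.
#'
#' @param datasets one `labeled_dataset` or a named list of them.
#' @param grid a [grid_spec()].
#' @param kmeans_repeats k-means repeats per cell (default 50).
#' @param test_fraction held-out fraction excluded from VAE training.
#' @param out_dir optional directory for the resume ledger.
#' @param eval_seed master seed for the scoring protocol.
#' @param verbose print one line per cell.
#' @return a `sweep_result`: long-format data frame, one row per run, with
#'   the config, NMI/ARI means and sds, final losses and the failure flag.
#' @export
run_grid <- function(datasets, grid, kmeans_repeats = 50,
                     test_fraction = 0.1, out_dir = NULL, eval_seed = 1L,
                     verbose = FALSE) {
  if (inherits(datasets, "labeled_dataset")) datasets <- list(data = datasets)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  cells <- expand_grid_spec(grid)
  ledger_dir <- NULL
  if (!is.null(out_dir)) {
    ledger_dir <- file.path(out_dir, "cells")
    dir.create(ledger_dir, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list()
  for (ds_id in names(datasets)) {
    ds <- datasets[[ds_id]]
    norm <- zero_one_scale(tpm_normalize(ds$counts))
    split <- split_train_test(ds$labels, test_fraction = test_fraction,
                              seed = eval_seed)
    train_mat <- norm$values[, split$train, drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      row <- cells[i, ]
      id <- cell_id(ds_id, row)
      if (!is.null(ledger_dir)) {
        f <- file.path(ledger_dir, paste0(id, ".tsv"))
        if (file.exists(f)) {
          rows[[id]] <- utils::read.delim(f)
          next
        }
      }
      res <- run_one_cell(train_mat, norm$values, ds$labels, ds_id, row,
                          kmeans_repeats, eval_seed)
      if (verbose)
        message(sprintf("%s: NMI %.3f%s", id, res$nmi_mean,
                        if (res$failed) " [FAILED]" else ""))
      rows[[id]] <- res
      if (!is.null(ledger_dir))
        utils::write.table(res, file.path(ledger_dir, paste0(id, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

run_one_cell <- function(train_mat, full_mat, labels, ds_id, row,
                         kmeans_repeats, eval_seed) {
  config <- vae_config(
    depth = row$depth, first_hidden_dim = row$first_hidden_dim,
    learning_rate = row$learning_rate, batch_size = row$batch_size,
    epochs = row$epochs, seed = row$seed
  )
  failed <- FALSE
  fail_msg <- ""
  final <- c(NA_real_, NA_real_, NA_real_)
  km <- NULL
  model <- build_vae(config, n_genes = nrow(train_mat))
  trained <- tryCatch(train_vae(model, train_mat), vae_divergence = identity)
  if (inherits(trained, "condition")) {
    failed <- TRUE
    fail_msg <- conditionMessage(trained)
  } else {
    h <- trained$history
    if (!is.null(h) && nrow(h) > 0)
      final <- as.numeric(h[nrow(h), c("total", "reconstruction", "kl")])
    emb <- tryCatch(encode_cells(trained, full_mat), error = identity)
    if (inherits(emb, "error")) {
      failed <- TRUE
      fail_msg <- conditionMessage(emb)
    } else {
      km <- tryCatch(
        kmeans_protocol(emb, labels, repeats = kmeans_repeats,
                        seed = eval_seed),
        error = identity)
      if (inherits(km, "error")) {
        failed <- TRUE
        fail_msg <- conditionMessage(km)
      }
    }
  }
  data.frame(
    dataset_id = ds_id, method = "vae", depth = row$depth,
    learning_rate = row$learning_rate, batch_size = row$batch_size,
    epochs = row$epochs, first_hidden_dim = row$first_hidden_dim,
    seed = row$seed,
    nmi_mean = if (failed) 0 else km$nmi_mean,
    nmi_sd = if (failed) 0 else km$nmi_sd,
    ari_mean = if (failed) 0 else km$ari_mean,
    ari_sd = if (failed) 0 else km$ari_sd,
    final_total = final[1], final_recon = final[2], final_kl = final[3],
    failed = failed, fail_msg = fail_msg
  )
}

#' Best and worst grid cells
#'
#' Per group (by default dataset x depth), the argmax and argmin rows by
#' mean NMI.  Ties are broken by higher mean ARI, then by lexicographically
#' smallest configuration (learning rate, batch, epochs, first hidden
#' width).  Output follows the conventional best/worst tuning-table layout
#' (l, b, e, c, NMI, ARI).
#'
#' @param result a `sweep_result`.
#' @param by grouping columns.
#' @return data frame with one best and one worst row per group and a
#'   `role` column.
#' @export
best_worst <- function(result, by = c("dataset_id", "depth")) {
  stopifnot(nrow(result) > 0)
  groups <- split(seq_len(nrow(result)),
                  result[, by, drop = FALSE], drop = TRUE)
  pick <- function(idx, decreasing) {
    sub <- result[idx, ]
    o <- order(if (decreasing) -sub$nmi_mean else sub$nmi_mean,
               if (decreasing) -sub$ari_mean else sub$ari_mean,
               sub$learning_rate, sub$batch_size, sub$epochs,
               sub$first_hidden_dim)
    idx[o[1]]
  }
  rows <- lapply(groups, function(idx) {
    rbind(
      cbind(role = "best", result[pick(idx, TRUE), ]),
      cbind(role = "worst", result[pick(idx, FALSE), ])
    )
  })
  out <- do.call(rbind, rows)
  out <- out[, c(by, "role", "learning_rate", "batch_size", "epochs",
                 "first_hidden_dim", "nmi_mean", "ari_mean", "failed")]
  names(out)[match(c("learning_rate", "batch_size", "epochs",
                     "first_hidden_dim", "nmi_mean", "ari_mean"),
                   names(out))] <- c("l", "b", "e", "c", "NMI", "ARI")
  rownames(out) <- NULL
  out
}

#' Project a latent embedding to 2-D for visualization
#'
#' t-SNE applied to the latent coordinates themselves (not the raw data);
#' 2-D inputs pass through unchanged.
#'
#' @param embedding a `latent_embedding` with `d >= 2`.
#' @param seed t-SNE seed.
#' @param perplexity t-SNE perplexity.
#' @return a `latent_embedding` with 2 columns.
#' @export
project_2d <- function(embedding, seed = 1L, perplexity = 30) {
  stopifnot(inherits(embedding, "latent_embedding"))
  if (embedding$d < 2) stop("embedding must have at least 2 dimensions")
  if (embedding$d == 2) return(embedding)
  embed_tsne(t(embedding$coords), out_dim = 2, perplexity = perplexity,
             seed = seed)
}

#' Write an aggregate sweep report
#'
#' Writes `results.tsv` (the full long table, deterministically sorted),
#' `best_worst.tsv` (NMI/ARI printed with 2 decimals, the usual presentation
#' precision of tuning tables), and `report.json` (sorted keys: per-dataset
#' per-depth score summaries, best/worst cells, and a failure inventory).
#'
#' @param result a `sweep_result`.
#' @param out_dir output directory.
#' @return (invisibly) the report list written to JSON.
#' @export
make_report <- function(result, out_dir) {
  stopifnot(nrow(result) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ord <- do.call(order, result[, c("dataset_id", "depth", "learning_rate",
                                   "batch_size", "epochs",
                                   "first_hidden_dim", "seed")])
  res <- result[ord, ]
  utils::write.table(res, file.path(out_dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bw <- best_worst(res)
  bw_out <- bw
  bw_out$NMI <- sprintf("%.2f", bw$NMI)
  bw_out$ARI <- sprintf("%.2f", bw$ARI)
  utils::write.table(bw_out, file.path(out_dir, "best_worst.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  failures <- res[res$failed, c("dataset_id", "depth", "learning_rate",
                                "batch_size", "epochs", "first_hidden_dim",
                                "seed", "fail_msg")]
  summary <- lapply(split(res, list(res$dataset_id, res$depth), drop = TRUE),
                    function(s) list(
                      n_cells = nrow(s),
                      nmi_mean = round(mean(s$nmi_mean), 4),
                      nmi_max = round(max(s$nmi_mean), 4),
                      nmi_min = round(min(s$nmi_mean), 4),
                      n_failed = sum(s$failed)))
  report <- list(
    summary = summary[order(names(summary))],
    best_worst = bw,
    failures = failures
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}

#' Compare embedding methods on one dataset
#'
#' The multi-method harness: embeds one labeled dataset with PCA, t-SNE,
#' UMAP and/or a default-configuration VAE and scores every embedding with
#' all three protocols.  Baselines are fed `log1p(TPM)`; the VAE is fed
#' zero-one-scaled TPM (its sigmoid output models `[0,1]` data).
#'
#' @param dataset a `labeled_dataset`.
#' @param methods subset of `c("pca", "tsne", "umap", "vae")`.
#' @param vae_cfg VAE configuration for the `"vae"` entry.
#' @param pca_dim,tsne_perplexity,umap_neighbors baseline knobs.
#' @param seed master seed for stochastic methods and the protocols.
#' @param kmeans_repeats passed to the k-means protocol.
#' @return data frame with one row per method (flattened eval reports).
#' @export
compare_methods <- function(dataset,
                            methods = c("pca", "tsne", "umap", "vae"),
                            vae_cfg = vae_config(),
                            pca_dim = 20, tsne_perplexity = 30,
                            umap_neighbors = 15, seed = 1L,
                            kmeans_repeats = 50) {
  methods <- match.arg(methods, several.ok = TRUE)
  logtpm <- tpm_normalize(dataset$counts, log = TRUE)
  reports <- lapply(methods, function(m) {
    emb <- switch(m,
      pca = embed_pca(logtpm, out_dim = pca_dim, seed = seed),
      tsne = embed_tsne(logtpm, perplexity = tsne_perplexity, seed = seed),
      umap = embed_umap(logtpm, n_neighbors = umap_neighbors, seed = seed),
      vae = {
        zo <- zero_one_scale(tpm_normalize(dataset$counts))
        cfg <- vae_cfg
        cfg$seed <- as.integer(seed)
        model <- train_vae(build_vae(cfg, nrow(zo$values)), zo)
        encode_cells(model, zo)
      })
    as.data.frame(evaluate_embedding(emb, dataset$labels,
                                     kmeans_repeats = kmeans_repeats,
                                     seed = seed))
  })
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}
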