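#' Normalized mutual information between two partitions
#'
#' `NMI = I(A;B) / ((H(A) + H(B)) / 2)` — mutual information normalized by
#' the arithmetic mean of the two entropies (natural logs; the ratio is
#' base-free).  If either partition has a single class (zero entropy) the
#' value is 0 by convention.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return value in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  if (length(labels_a) == 0) stop("labels must be non-empty")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(0)
  pij <- tab / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  val <- mi / ((ha + hb) / 2)
  min(max(val, 0), 1)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting Rand index corrected for chance under the permutation
#' model:
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5*(sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`.
#'
#' @inheritParams nmi
#' @return value `<= 1` (can be slightly negative); identical partitions
#'   give 1.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  den <- (sa + sb) / 2 - e
  if (den == 0) return(1)  # both partitions trivial (all-singletons/all-one)
  (sij - e) / den
}

#' Repeated k-means scoring of an embedding
#'
#' Runs k-means on the embedding coordinates `repeats` times (k = number of
#' distinct true labels, each repeat independently seeded with a fresh
#' random initialization), scores every run against the true labels by NMI
#' and ARI, and returns means and standard deviations — the repeated-
#' clustering protocol that gives a stable measurement of how well a
#' hypersphere in the latent space captures cell types.
#'
#' @param embedding a `latent_embedding` (or bare cells x d matrix).
#' @param true_labels label per cell.
#' @param repeats number of k-means runs (default 50).
#' @param seed master seed; repeat `r` uses `seed + r`.
#' @param init `"kmeanspp"` (default): each repeat is independently seeded
#'   greedy k-means++ initialization, the convention of the standard
#'   clustering toolkits this protocol mirrors; `"random"`: plain random
#'   starts.
#' @param nstart initializations per repeat (default 1; the repeats
#'   themselves supply the independent initializations).
#' @param iter.max k-means iteration cap.
#' @return list with `nmi_mean`, `nmi_sd`, `ari_mean`, `ari_sd`, `repeats`
#'   and the per-repeat `values` data frame.
#' @export
kmeans_protocol <- function(embedding, true_labels, repeats = 50, seed = 1L,
                            init = c("kmeanspp", "random"), nstart = 1,
                            iter.max = 100) {
  init <- match.arg(init)
  coords <- if (inherits(embedding, "latent_embedding")) embedding$coords
            else as.matrix(embedding)
  if (nrow(coords) != length(true_labels))
    stop("embedding rows must match label length")
  k <- length(unique(true_labels))
  if (k > nrow(coords)) stop("more classes than cells")
  # a collapsed embedding (fewer distinct points than clusters) cannot be
  # partitioned into k clusters; every cell is effectively one point, which
  # carries no label information, so the protocol scores it 0 — collapsed
  # latent spaces are a real failure mode of deep embeddings and must stay
  # comparable, not crash the harness
  if (nrow(unique(coords)) < k) {
    return(list(nmi_mean = 0, nmi_sd = 0, ari_mean = 0, ari_sd = 0,
                repeats = repeats, degenerate = TRUE,
                values = data.frame(repeat_ = seq_len(repeats), nmi = 0,
                                    ari = 0)))
  }
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  vals <- vapply(seq_len(repeats), function(r) {
    set.seed(seed + r)
    centers <- if (init == "kmeanspp") kmeanspp_centers(coords, k) else k
    cl <- tryCatch(
      suppressWarnings(stats::kmeans(coords, centers = centers,
                                     nstart = if (init == "kmeanspp") 1
                                              else nstart,
                                     iter.max = iter.max))$cluster,
      error = function(e) rep(1L, nrow(coords)))
    c(nmi(cl, true_labels), ari(cl, true_labels))
  }, c(nmi = 0, ari = 0))
  list(nmi_mean = mean(vals["nmi", ]), nmi_sd = stats::sd(vals["nmi", ]),
       ari_mean = mean(vals["ari", ]), ari_sd = stats::sd(vals["ari", ]),
       repeats = repeats, degenerate = FALSE,
       values = data.frame(repeat_ = seq_len(repeats),
                           nmi = vals["nmi", ], ari = vals["ari", ]))
}

# k-means++ seeding: first centre uniform, each next centre drawn with
# probability proportional to squared distance to the nearest chosen centre
kmeanspp_centers <- function(coords, k) {
  n <- nrow(coords)
  centers <- matrix(0, k, ncol(coords))
  i <- sample.int(n, 1)
  centers[1, ] <- coords[i, ]
  d2 <- rowSums(sweep(coords, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1)
         else sample.int(n, 1, prob = d2 / tot)
    centers[j, ] <- coords[i, ]
    d2 <- pmin(d2, rowSums(sweep(coords, 2, centers[j, ])^2))
  }
  # tiny jitter resolves duplicate centres picked from coincident points
  if (anyDuplicated(centers))
    centers <- centers + stats::rnorm(length(centers), sd = 1e-9)
  centers
}

# stratified fold assignment: within each class, cells are dealt round-robin
# into folds in shuffled order
make_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (idx in split(seq_along(labels), labels)) {
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# smallest k in k_grid maximizing accuracy (ties -> smallest, grid sorted)
choose_k <- function(k_grid, accuracies) {
  o <- order(k_grid)
  k_grid[o][which.max(accuracies[o])]
}

#' Nested cross-validated kNN scoring of an embedding
#'
#' Stratified `outer_folds`-fold cross validation; within each outer
#' training set the neighbour count is tuned by `inner_folds`-fold cross
#' validation over `k_grid` (ties broken toward the smallest k), so
#' outer-test labels are never touched during tuning.  Outer-fold test
#' predictions are pooled and scored by accuracy plus macro-averaged
#' precision, recall and F1.
#'
#' @inheritParams kmeans_protocol
#' @param outer_folds,inner_folds protocol folds (defaults 5 and 3).
#' @param k_grid candidate neighbour counts; odd values avoid vote ties.
#' @param seed seed for the fold assignments.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, per-fold
#'   `fold_k` (chosen neighbour counts) and `fold_accuracy`.
#' @export
knn_protocol <- function(embedding, true_labels, outer_folds = 5,
                         inner_folds = 3, k_grid = seq(1, 21, by = 2),
                         seed = 1L) {
  coords <- if (inherits(embedding, "latent_embedding")) embedding$coords
            else as.matrix(embedding)
  if (length(k_grid) == 0) stop("k_grid must be non-empty")
  y <- factor(true_labels)
  if (min(table(y)) < outer_folds)
    warning("a class has fewer members than outer_folds; ",
            "folds will miss it in places")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- make_folds(y, outer_folds)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_k <- integer(outer_folds)
  fold_acc <- numeric(outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    inner <- make_folds(y[tr], inner_folds)
    acc <- vapply(k_grid, function(kk) {
      ok <- 0L
      for (g in seq_len(inner_folds)) {
        itr <- tr[inner != g]
        ite <- tr[inner == g]
        kk_eff <- min(kk, length(itr))
        p <- class::knn(coords[itr, , drop = FALSE],
                        coords[ite, , drop = FALSE], y[itr], k = kk_eff)
        ok <- ok + sum(p == y[ite])
      }
      ok / length(tr)
    }, 0)
    fold_k[f] <- choose_k(k_grid, acc)
    p <- class::knn(coords[tr, , drop = FALSE], coords[te, , drop = FALSE],
                    y[tr], k = min(fold_k[f], length(tr)))
    pred[te] <- p
    fold_acc[f] <- mean(p == y[te])
  }
  cm <- table(truth = y, pred = pred)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(pred == y), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1),
       fold_k = fold_k, fold_accuracy = fold_acc)
}

#' Average silhouette width of the true labels in an embedding
#'
#' For each cell, `s = (b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to cells of the same class and `b` the smallest mean distance to
#' any other class; cells in singleton classes score 0.  Returns the mean
#' over cells, in `[-1, 1]`.
#'
#' @inheritParams kmeans_protocol
#' @return scalar in `[-1, 1]`.
#' @export
avg_silhouette <- function(embedding, true_labels) {
  coords <- if (inherits(embedding, "latent_embedding")) embedding$coords
            else as.matrix(embedding)
  y <- as.integer(factor(true_labels))
  if (length(unique(y)) < 2) stop("silhouette needs at least two classes")
  dm <- as.matrix(stats::dist(coords))
  n <- nrow(dm)
  classes <- sort(unique(y))
  # mean distance from every cell to every class
  class_mean <- vapply(classes, function(k) {
    idx <- y == k
    rowSums(dm[, idx, drop = FALSE]) / sum(idx)
  }, numeric(n))
  sizes <- tabulate(y)
  s <- vapply(seq_len(n), function(i) {
    k <- y[i]
    if (sizes[k] == 1) return(0)
    a <- class_mean[i, k] * sizes[k] / (sizes[k] - 1)  # exclude self
    b <- min(class_mean[i, -k])
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Score one embedding with all three protocols
#'
#' Convenience wrapper producing a flat evaluation report for one
#' (dataset, method, hyperparameter) combination.
#'
#' @inheritParams kmeans_protocol
#' @param dataset_id free-text dataset identifier for the report.
#' @param kmeans_repeats,knn_outer,knn_inner,knn_grid protocol parameters.
#' @return object of class `eval_report` (named list; see
#'   [as.data.frame.eval_report()]).
#' @export
evaluate_embedding <- function(embedding, true_labels, dataset_id = "data",
                               kmeans_repeats = 50, knn_outer = 5,
                               knn_inner = 3, knn_grid = seq(1, 21, 2),
                               seed = 1L) {
  km <- kmeans_protocol(embedding, true_labels, repeats = kmeans_repeats,
                        seed = seed)
  kn <- knn_protocol(embedding, true_labels, outer_folds = knn_outer,
                     inner_folds = knn_inner, k_grid = knn_grid, seed = seed)
  sil <- avg_silhouette(embedding, true_labels)
  structure(list(
    dataset_id = dataset_id,
    method_tag = if (inherits(embedding, "latent_embedding"))
      embedding$method_tag else list(method = "matrix"),
    kmeans_nmi = km$nmi_mean, kmeans_nmi_sd = km$nmi_sd,
    kmeans_ari = km$ari_mean, kmeans_ari_sd = km$ari_sd,
    knn_accuracy = kn$accuracy, knn_precision = kn$precision,
    knn_recall = kn$recall, knn_f1 = kn$f1,
    silhouette = sil,
    protocol = list(kmeans_repeats = kmeans_repeats, knn_outer = knn_outer,
                    knn_inner = knn_inner, knn_grid = knn_grid),
    seed = seed
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report [%s / %s]: kmeans NMI %.3f (ARI %.3f), kNN acc %.3f, silhouette %.3f\n",
    x$dataset_id, x$method_tag$method, x$kmeans_nmi, x$kmeans_ari,
    x$knn_accuracy, x$silhouette))
  invisible(x)
}

#' Flatten an eval_report to a one-row data frame
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(
    dataset_id = x$dataset_id, method = x$method_tag$method,
    kmeans_nmi = x$kmeans_nmi, kmeans_nmi_sd = x$kmeans_nmi_sd,
    kmeans_ari = x$kmeans_ari, kmeans_ari_sd = x$kmeans_ari_sd,
    knn_accuracy = x$knn_accuracy, knn_precision = x$knn_precision,
    knn_recall = x$knn_recall, knn_f1 = x$knn_f1,
    silhouette = x$silhouette, seed = x$seed
  )
}
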