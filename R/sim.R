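#' Simulation parameters for a labeled single-cell count matrix
#'
#' Builds and validates the full generative configuration for one synthetic
#' scRNA-seq dataset.  The generative hierarchy follows the widely used
#' gamma-Poisson model for droplet data: gene base means are gamma draws, a
#' fraction of genes are expression outliers whose mean is inflated relative
#' to the median gene, each cell group perturbs a random subset of genes by
#' lognormal differential-expression factors, cells receive lognormal library
#' sizes, counts are Poisson (optionally gamma-Poisson), and an optional
#' logistic dropout step zeroes low-expression entries preferentially.
#'
#' Defaults are "splatter-like": they mirror the published defaults of the
#' Splatter simulator (shipped in
#' `system.file("extdata", "splatter_like_defaults.yaml", package =
#' "latentbench")`) and are overridable; they are a convention, not a fitted
#' truth.
#'
#' @param n_genes,n_cells,n_groups positive integers: genes, cells, cell
#'   groups (cell types).
#' @param group_probs probability vector of length `n_groups` summing to 1;
#'   default equal probabilities.
#' @param outlier_prob probability that a gene is an expression outlier.
#' @param mean_shape,mean_rate shape and rate of the gamma prior on gene
#'   base means.
#' @param outlier_fac_loc,outlier_fac_scale meanlog/sdlog of the lognormal
#'   inflation factor applied (times the median gene mean) to outlier genes.
#' @param lib_loc,lib_scale meanlog/sdlog of the lognormal per-cell library
#'   size.
#' @param de_prob probability that a gene is differentially expressed in a
#'   given group.
#' @param de_fac_loc,de_fac_scale meanlog/sdlog of the lognormal DE factors.
#' @param de_down_prob probability that a DE factor is inverted (1/f), i.e.
#'   down-regulated; 0.5 keeps regulation symmetric.
#' @param dropout_enabled logical; apply the logistic dropout stage?
#' @param dropout_mid,dropout_shape location and slope of the logistic
#'   dropout curve on the log-mean scale (`dropout_shape < 0` zeroes
#'   low-mean entries more often).
#' @param dispersion common biological coefficient of variation; 0 (default)
#'   gives pure Poisson counts, > 0 multiplies each Poisson rate by a
#'   mean-one gamma variable with CV `dispersion`.
#' @param seed integer RNG seed; the dataset is a pure function of the
#'   parameter set including this seed.
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- simulation_params(n_genes = 200, n_cells = 100, n_groups = 3, seed = 1)
#' ds <- generate_dataset(p)
#' dim(ds$counts)
#' @export
simulation_params <- function(n_genes = 2000,
                              n_cells = 500,
                              n_groups = 5,
                              group_probs = NULL,
                              outlier_prob = 0.05,
                              mean_shape = 0.6,
                              mean_rate = 0.3,
                              outlier_fac_loc = 4,
                              outlier_fac_scale = 0.5,
                              lib_loc = 11,
                              lib_scale = 0.2,
                              de_prob = 0.1,
                              de_fac_loc = 0.1,
                              de_fac_scale = 0.4,
                              de_down_prob = 0.5,
                              dropout_enabled = FALSE,
                              dropout_mid = 0,
                              dropout_shape = -1,
                              dispersion = 0,
                              seed = 1L) {
  if (is.null(group_probs)) group_probs <- rep(1 / n_groups, n_groups)
  p <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_groups = as.integer(n_groups), group_probs = as.numeric(group_probs),
    outlier_prob = outlier_prob, mean_shape = mean_shape,
    mean_rate = mean_rate, outlier_fac_loc = outlier_fac_loc,
    outlier_fac_scale = outlier_fac_scale, lib_loc = lib_loc,
    lib_scale = lib_scale, de_prob = de_prob, de_fac_loc = de_fac_loc,
    de_fac_scale = de_fac_scale, de_down_prob = de_down_prob,
    dropout_enabled = isTRUE(dropout_enabled), dropout_mid = dropout_mid,
    dropout_shape = dropout_shape, dispersion = dispersion,
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_genes < 1L || p$n_cells < 1L || p$n_groups < 1L)
    stop("n_genes, n_cells and n_groups must be positive integers")
  if (p$n_groups > p$n_cells)
    stop("n_groups must not exceed n_cells")
  probs <- c(p$outlier_prob, p$de_prob, p$de_down_prob, p$group_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (length(p$group_probs) != p$n_groups)
    stop("group_probs must have length n_groups")
  if (abs(sum(p$group_probs) - 1) > 1e-9)
    stop("group_probs must sum to 1 (within 1e-9)")
  pos <- c(p$mean_shape, p$mean_rate, p$outlier_fac_scale, p$lib_scale,
           p$de_fac_scale)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("shape/rate/scale parameters must be strictly positive")
  if (p$dispersion < 0) stop("dispersion must be >= 0")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params: %d genes x %d cells, %d groups (seed %d)\n",
    x$n_genes, x$n_cells, x$n_groups, x$seed
  ))
  cat(sprintf(
    "  outlier_prob %.3g | de_prob %.3g, de_fac ~ LN(%.3g, %.3g) | dropout %s\n",
    x$outlier_prob, x$de_prob, x$de_fac_loc, x$de_fac_scale,
    if (x$dropout_enabled) "on" else "off"
  ))
  invisible(x)
}

#' Draw gene base means with expression outliers
#'
#' Gene means are independent Gamma(`mean_shape`, rate = `mean_rate`) draws.
#' Each gene is then independently flagged an outlier with probability
#' `outlier_prob`; a flagged gene's mean is replaced by the median of all
#' means times a LogNormal(`outlier_fac_loc`, `outlier_fac_scale`) inflation
#' factor.
#'
#' @param params a [simulation_params()] object.
#' @return list with `means` (length `n_genes`, positive) and `outlier`
#'   (logical mask).
#' @export
simulate_gene_means <- function(params) {
  validate_sim_params(params)
  means <- stats::rgamma(params$n_genes, shape = params$mean_shape,
                         rate = params$mean_rate)
  outlier <- stats::runif(params$n_genes) < params$outlier_prob
  if (any(outlier)) {
    fac <- stats::rlnorm(sum(outlier), meanlog = params$outlier_fac_loc,
                         sdlog = params$outlier_fac_scale)
    means[outlier] <- stats::median(means) * fac
  }
  list(means = means, outlier = outlier)
}

#' Assign cells to groups
#'
#' I.i.d. categorical draws from `group_probs`.
#'
#' @param n_cells number of cells.
#' @param group_probs probability vector over groups (need not be normalized;
#'   must be non-negative with positive sum).
#' @return integer vector of labels in `1..length(group_probs)`.
#' @export
assign_groups <- function(n_cells, group_probs) {
  if (length(group_probs) < 1L) stop("group_probs must be non-empty")
  if (any(group_probs < 0) || sum(group_probs) <= 0)
    stop("group_probs must be non-negative with positive sum")
  sample.int(length(group_probs), size = n_cells, replace = TRUE,
             prob = group_probs)
}

#' Apply group-wise differential-expression factors
#'
#' For every (gene, group) pair the gene's mean is, with probability
#' `de_prob`, multiplied by an independent LogNormal(`de_fac_loc`,
#' `de_fac_scale`) factor; with probability `de_down_prob` the factor is
#' inverted (1/f) so regulation is symmetric up/down and group means are not
#' systematically inflated.
#'
#' @param gene_means positive base means (length G).
#' @param n_groups number of groups.
#' @param de_prob,de_fac_loc,de_fac_scale,de_down_prob see
#'   [simulation_params()].
#' @return list with `group_means` (G x n_groups matrix) and `de` (logical
#'   G x n_groups mask of perturbed entries).
#' @export
apply_group_de <- function(gene_means, n_groups, de_prob,
                           de_fac_loc = 0.1, de_fac_scale = 0.4,
                           de_down_prob = 0.5) {
  if (any(gene_means <= 0)) stop("gene_means must be positive")
  g <- length(gene_means)
  de <- matrix(stats::runif(g * n_groups) < de_prob, g, n_groups)
  fac <- matrix(1, g, n_groups)
  n_de <- sum(de)
  if (n_de > 0) {
    f <- stats::rlnorm(n_de, meanlog = de_fac_loc, sdlog = de_fac_scale)
    down <- stats::runif(n_de) < de_down_prob
    f[down] <- 1 / f[down]
    fac[de] <- f
  }
  list(group_means = gene_means * fac, de = de)
}

#' Sample Poisson counts with lognormal library sizes
#'
#' Each cell draws a library size `L ~ LogNormal(lib_loc, lib_scale)`; its
#' group's mean profile is rescaled to sum to `L` and counts are Poisson
#' draws from the rescaled profile (gamma-Poisson when
#' `params$dispersion > 0`).
#'
#' @param group_means G x n_groups matrix of group mean profiles.
#' @param labels integer group label per cell.
#' @param params a [simulation_params()] object.
#' @return list with `counts` (G x n_cells integer matrix), `lambda` (the
#'   Poisson rates, kept for the dropout stage and for tests) and `lib_size`.
#' @export
simulate_counts <- function(group_means, labels, params) {
  g <- nrow(group_means)
  n <- length(labels)
  if (max(labels) > ncol(group_means)) stop("label outside group_means columns")
  lib <- stats::rlnorm(n, meanlog = params$lib_loc, sdlog = params$lib_scale)
  profile <- sweep(group_means, 2, colSums(group_means), "/")
  lambda <- profile[, labels, drop = FALSE] *
    rep(lib, each = g)
  if (params$dispersion > 0) {
    cv2 <- params$dispersion^2
    lambda <- lambda * matrix(
      stats::rgamma(g * n, shape = 1 / cv2, rate = 1 / cv2), g, n)
  }
  counts <- matrix(stats::rpois(g * n, lambda), g, n)
  list(counts = counts, lambda = lambda, lib_size = lib)
}

#' Logistic dropout
#'
#' Zeroes each count independently with probability
#' `p = 1 / (1 + exp(-dropout_shape * (log(lambda) - dropout_mid)))`, the
#' logistic curve on the log expected-expression scale.  With the default
#' negative `dropout_shape`, entries with low expected expression are zeroed
#' more often; output never exceeds input.
#'
#' @param counts G x n count matrix.
#' @param lambda matching matrix of expected expression (Poisson rates).
#' @param dropout_mid,dropout_shape logistic location and slope.
#' @return matrix of the same shape with some entries set to zero.
#' @export
apply_dropout <- function(counts, lambda, dropout_mid = 0,
                          dropout_shape = -1) {
  stopifnot(all(dim(counts) == dim(lambda)))
  p_drop <- stats::plogis(dropout_shape * (log(lambda) - dropout_mid))
  keep <- matrix(stats::runif(length(counts)) >= p_drop,
                 nrow(counts), ncol(counts))
  counts * keep
}

#' Generate one labeled synthetic dataset
#'
#' Composes the generative stages in a fixed, documented sub-stream order
#' (gene means and outliers, labels, DE factors, library sizes and counts,
#' dropout) under a single seeded RNG, so a dataset is bit-reproducible from
#' its `sim_params` alone.  The caller's RNG state is preserved.
#'
#' @param params a [simulation_params()] object.
#' @return An object of class `labeled_dataset`: a list with `counts`
#'   (G x n integer matrix with gene/cell dimnames), `labels` (integer
#'   vector in `1..n_groups`), `gene_means` (base means), `group_means`,
#'   `outlier` mask, `de` mask, `lib_size` and the echoed `params`.
#' @export
generate_dataset <- function(params) {
  validate_sim_params(params)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  gm <- simulate_gene_means(params)
  labels <- assign_groups(params$n_cells, params$group_probs)
  de <- apply_group_de(gm$means, params$n_groups, params$de_prob,
                       params$de_fac_loc, params$de_fac_scale,
                       params$de_down_prob)
  cs <- simulate_counts(de$group_means, labels, params)
  counts <- cs$counts
  if (params$dropout_enabled) {
    counts <- apply_dropout(counts, cs$lambda,
                            params$dropout_mid, params$dropout_shape)
  }
  dimnames(counts) <- list(
    paste0("gene", seq_len(params$n_genes)),
    paste0("cell", seq_len(params$n_cells))
  )
  structure(
    list(counts = counts, labels = labels, gene_means = gm$means,
         group_means = de$group_means, outlier = gm$outlier, de = de$de,
         lib_size = cs$lib_size, params = params),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "labeled_dataset: %d genes x %d cells, %d groups, %.1f%% zeros\n",
    nrow(x$counts), ncol(x$counts), x$params$n_groups,
    100 * mean(x$counts == 0)
  ))
  invisible(x)
}

#' One-factor-at-a-time simulation design manifest
#'
#' The benchmark's default design sweeps one generative factor at a time over
#' ten values while the others stay at their defaults: cells 500-5000, genes
#' 20000-60000, groups 5-15, outlier probability 0.1-0.5; 40 datasets in
#' total.  The manifest is a plain data frame so users can substitute their
#' own design.
#'
#' @param base a [simulation_params()] object supplying the non-swept values.
#' @return data.frame with columns `id`, `swept`, `n_cells`, `n_genes`,
#'   `n_groups`, `outlier_prob`, `seed` (one row per dataset).
#' @export
simulation_design <- function(base = simulation_params()) {
  lvl <- list(
    n_cells = round(seq(500, 5000, length.out = 10)),
    n_genes = round(seq(20000, 60000, length.out = 10)),
    n_groups = round(seq(5, 15, length.out = 10)),
    outlier_prob = seq(0.1, 0.5, length.out = 10)
  )
  rows <- lapply(seq_along(lvl), function(i) {
    fac <- names(lvl)[i]
    d <- data.frame(
      swept = fac,
      n_cells = base$n_cells, n_genes = base$n_genes,
      n_groups = base$n_groups, outlier_prob = base$outlier_prob
    )[rep(1, 10), ]
    d[[fac]] <- lvl[[i]]
    d
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("sim%02d", seq_len(nrow(out)))
  out$seed <- base$seed + seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("id", "swept", "n_cells", "n_genes", "n_groups", "outlier_prob",
          "seed")]
}
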