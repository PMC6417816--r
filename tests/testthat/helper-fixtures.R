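# fixtures built in code, shared across test files

# three tight, well-separated gaussian blobs in 5-D (n points per blob)
blobs_fixture <- function(n_per = 50, d = 5, sep = 12, sd = 0.5, seed = 42) {
  set.seed(seed)
  centers <- matrix(0, 3, d)
  centers[2, 1] <- sep
  centers[3, 2] <- sep
  coords <- do.call(rbind, lapply(1:3, function(k) {
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      rep(centers[k, ], each = n_per)
  }))
  rownames(coords) <- paste0("cell", seq_len(nrow(coords)))
  list(coords = coords, labels = rep(1:3, each = n_per))
}

# small well-separated 5-group simulation for end-to-end checks
easy_dataset <- function(n_cells = 300, n_genes = 200, seed = 7) {
  generate_dataset(simulation_params(
    n_genes = n_genes, n_cells = n_cells, n_groups = 5,
    outlier_prob = 0.1, de_prob = 0.3, de_fac_loc = 1.2, de_fac_scale = 0.4,
    seed = seed
  ))
}

# all set partitions of seq_len(n) as label vectors (restricted growth
# strings); used by the brute-force NMI/ARI oracles
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(k + 1L)) grow(c(labels, v), max(k, v))
  }
  grow(integer(0), 0L)
  out
}

# entropy-based NMI oracle computed from first principles on the joint
# distribution (no contingency-table shortcuts shared with the implementation)
oracle_nmi <- function(a, b) {
  n <- length(a)
  joint <- numeric(0)
  pa <- table(a) / n
  pb <- table(b) / n
  mi <- 0
  for (x in names(pa)) for (y in names(pb)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (pa[[x]] * pb[[y]]))
  }
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  denom <- (h(as.numeric(pa)) + h(as.numeric(pb))) / 2
  if (denom == 0) 0 else as.numeric(mi / denom)
}

# pair-counting ARI oracle: enumerate every pair of items
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}
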