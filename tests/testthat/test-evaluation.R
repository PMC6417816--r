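test_that("NMI and ARI match brute-force oracles on all small partitions", {
  # exhaustive: every pair of partitions of 5 items (52 x 52), plus the
  # worked 4-item contingency case
  parts5 <- all_partitions(5)
  for (a in parts5) {
    for (b in parts5) {
      expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
      expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
    }
  }
  a4 <- c(1, 1, 2, 2)
  b4 <- c(1, 2, 1, 2)
  expect_equal(nmi(a4, b4), oracle_nmi(a4, b4))
  expect_equal(ari(a4, b4), oracle_ari(a4, b4))
})

test_that("NMI/ARI agree with oracles on sampled 6-item partitions", {
  parts6 <- all_partitions(6)
  set.seed(1)
  idx <- sample(length(parts6), 40)
  for (i in idx) {
    for (j in sample(length(parts6), 12)) {
      a <- parts6[[i]]; b <- parts6[[j]]
      expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
      expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
    }
  }
})

test_that("NMI/ARI edge conventions and invariances hold", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 1), c(1, 2, 3)), 0)      # zero-entropy convention
  expect_equal(ari(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_error(nmi(1:3, 1:4), "equal length")

  # symmetry and label-renaming invariance under random relabelings
  set.seed(2)
  for (rep in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(nmi(a, b), nmi(b, a))
    expect_equal(ari(a, b), ari(b, a))
    ra <- sample(100, 4)[a]  # injective relabeling
    expect_equal(nmi(ra, b), nmi(a, b))
    expect_equal(ari(ra, b), ari(a, b))
  }
})

test_that("ARI is centred at zero for independent labelings", {
  set.seed(3)
  vals <- vapply(1:1000, function(i) {
    ari(sample(1:3, 60, replace = TRUE), sample(1:3, 60, replace = TRUE))
  }, 0)
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("k-means protocol recovers blobs, nulls shuffled labels, is stable", {
  bl <- blobs_fixture()
  km <- kmeans_protocol(bl$coords, bl$labels, repeats = 50, seed = 1)
  expect_gte(km$nmi_mean, 0.99)
  expect_equal(km$repeats, 50)
  expect_equal(nrow(km$values), 50)

  set.seed(4)
  shuffled <- sample(bl$labels)
  km0 <- kmeans_protocol(bl$coords, shuffled, repeats = 20, seed = 1)
  expect_lte(km0$nmi_mean, 0.05)

  # mean is stable across master seeds (within 2 sd bands)
  means <- vapply(1:5, function(s)
    kmeans_protocol(bl$coords, bl$labels, repeats = 20, seed = s)$nmi_mean, 0)
  expect_lt(max(means) - min(means),
            2 * max(km$nmi_sd, 1e-3) + 1e-8)
  expect_error(kmeans_protocol(bl$coords[1:2, ], 1:3), "match")
})

test_that("kNN nested CV is perfect on blobs and chance-level on noise", {
  bl <- blobs_fixture()
  kn <- knn_protocol(bl$coords, bl$labels, seed = 1)
  expect_equal(kn$accuracy, 1.0)
  expect_equal(kn$f1, 1.0)
  expect_length(kn$fold_k, 5)

  set.seed(5)
  coords <- matrix(stats::rnorm(500 * 3), 500, 3)
  labels <- rep(1:5, each = 100)
  kn0 <- knn_protocol(coords, labels, seed = 1)
  expect_lt(abs(kn0$accuracy - 0.2), 3 * sqrt(0.2 * 0.8 / 500))
})

test_that("inner-CV ties select the smallest neighbour count", {
  choose_k <- latentbench:::choose_k
  expect_equal(choose_k(c(3, 7), c(0.9, 0.9)), 3)
  expect_equal(choose_k(c(7, 3), c(0.9, 0.9)), 3)   # order-independent
  expect_equal(choose_k(c(1, 3, 5), c(0.1, 0.8, 0.8)), 3)
  expect_error(knn_protocol(matrix(0, 10, 2), rep(1:2, 5),
                            k_grid = integer(0)), "k_grid")
})

test_that("inner tuning is a pure function of the outer-training data", {
  # overlapping clouds so the tuned neighbour count is non-trivial
  set.seed(11)
  coords <- rbind(matrix(stats::rnorm(60 * 3), 60, 3),
                  matrix(stats::rnorm(60 * 3, mean = 1.2), 60, 3))
  labels <- factor(rep(1:2, each = 60))
  k_grid <- c(1, 5, 9)
  kn <- knn_protocol(coords, labels, k_grid = k_grid, seed = 9)

  # replay the protocol's RNG stream to rebuild the first outer fold and its
  # inner folds, then recompute the selection using training data only
  set.seed(9)
  fold <- latentbench:::make_folds(labels, 5)
  tr <- which(fold != 1)
  inner <- latentbench:::make_folds(labels[tr], 3)
  acc <- vapply(k_grid, function(kk) {
    ok <- 0L
    for (g in 1:3) {
      itr <- tr[inner != g]
      ite <- tr[inner == g]
      p <- class::knn(coords[itr, ], coords[ite, ], labels[itr], k = kk)
      ok <- ok + sum(p == labels[ite])
    }
    ok / length(tr)
  }, 0)
  expect_equal(kn$fold_k[1], latentbench:::choose_k(k_grid, acc))
})

test_that("silhouette matches hand computations and its invariances", {
  # interleaved 1-D points 0,2,4,6 labeled ABAB, by hand:
  # ends (0 and 6): a = 4, b = (2+6)/2 = 4 -> s = 0
  # middles (2 and 4): a = 4, b = (2+2)/2 = 2 -> s = (2-4)/4 = -1/2
  # mean = -1/4
  coords <- matrix(c(0, 2, 4, 6), 4, 1)
  labels <- c("A", "B", "A", "B")
  expect_equal(avg_silhouette(coords, labels), -1 / 4)

  # two tight distant pairs: s ~ 1
  c2 <- rbind(c(0, 0), c(0, 1e-4), c(10, 10), c(10, 10 + 1e-4))
  expect_equal(avg_silhouette(c2, c(1, 1, 2, 2)), 1, tolerance = 1e-4)

  bl <- blobs_fixture()
  s <- avg_silhouette(bl$coords, bl$labels)
  expect_true(s >= -1 && s <= 1)
  # rigid rotation + translation invariance (5-D rotation in first 2 axes)
  th <- 0.7
  rot <- diag(5)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- bl$coords %*% rot + 3
  expect_equal(avg_silhouette(moved, bl$labels), s, tolerance = 1e-10)

  # singleton classes score zero: points 0,1 (class 1) and 2 (singleton):
  # s(0) = (2 - 1)/2, s(1) = (1 - 1)/1, s(2) = 0 -> mean 1/6
  expect_equal(avg_silhouette(matrix(c(0, 1, 2), 3, 1), c(1, 1, 2)), 1 / 6)
  expect_error(avg_silhouette(matrix(0, 3, 1), rep(1, 3)), "two classes")
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(6)
  coords <- matrix(stats::rnorm(80 * 4), 80, 4)
  labels <- sample(1:4, 80, replace = TRUE)
  ours <- avg_silhouette(coords, labels)
  ref <- mean(cluster::silhouette(labels, stats::dist(coords))[, 3])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("evaluate_embedding flattens to a tidy one-row report", {
  bl <- blobs_fixture(n_per = 25)
  emb <- latent_embedding(bl$coords, "pca", list(out_dim = 5))
  rep <- evaluate_embedding(emb, bl$labels, dataset_id = "blobs",
                            kmeans_repeats = 10, seed = 1)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1)
  expect_equal(df$method, "pca")
  expect_true(all(c("kmeans_nmi", "knn_accuracy", "silhouette") %in%
                    names(df)))
  expect_gte(df$kmeans_nmi, 0.99)
})
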