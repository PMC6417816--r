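test_that("parameter validation rejects malformed configurations", {
  expect_error(simulation_params(mean_shape = -1), "strictly positive")
  expect_error(simulation_params(outlier_prob = 1.5), "probabilities")
  expect_error(simulation_params(n_groups = 10, n_cells = 5), "n_groups")
  expect_error(
    simulation_params(n_groups = 2, group_probs = c(0.6, 0.6)), "sum to 1")
  expect_error(assign_groups(10, numeric(0)), "non-empty")
})

test_that("gene means follow the gamma prior and outlier flagging rates", {
  p <- simulation_params(n_genes = 100000, mean_shape = 0.6, mean_rate = 0.3,
                         outlier_prob = 0, seed = 1)
  set.seed(1)
  gm <- simulate_gene_means(p)
  expect_false(any(gm$outlier))
  # gamma expectation shape/rate = 2.0
  expect_equal(mean(gm$means), 2.0, tolerance = 0.02)

  p2 <- simulation_params(n_genes = 10000, outlier_prob = 0.5, seed = 1)
  set.seed(2)
  gm2 <- simulate_gene_means(p2)
  frac <- mean(gm2$outlier)
  sd3 <- 3 * sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(frac - 0.5), sd3)
  # outlier means are median * lognormal factor, so they dominate
  expect_gt(min(gm2$means[gm2$outlier]) /
              stats::median(gm2$means[!gm2$outlier]), 1)
})

test_that("group assignment matches the multinomial model and is seeded", {
  set.seed(3)
  lab <- assign_groups(5000, rep(0.2, 5))
  counts <- tabulate(lab, 5)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(5000 * 0.2 * 0.8)))

  lab1 <- assign_groups(100, c(1))
  expect_true(all(lab1 == 1))

  set.seed(9); a <- assign_groups(500, rep(0.25, 4))
  set.seed(9); b <- assign_groups(500, rep(0.25, 4))
  expect_identical(a, b)
})

test_that("label frequencies pass a chi-square goodness-of-fit screen", {
  probs <- c(0.1, 0.2, 0.3, 0.4)
  rejections <- sum(vapply(1:20, function(s) {
    set.seed(s)
    lab <- assign_groups(5000, probs)
    stats::chisq.test(tabulate(lab, 4), p = probs)$p.value < 0.001
  }, logical(1)))
  expect_lte(rejections, 1)
})

test_that("DE factors hit the configured fraction of gene-group pairs", {
  means <- rep(1, 20000)
  set.seed(4)
  de <- apply_group_de(means, n_groups = 3, de_prob = 0.1)
  for (k in 1:3) {
    frac <- mean(de$de[, k])
    expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
  }
  # unperturbed entries keep the base mean
  expect_true(all(de$group_means[!de$de] == 1))

  de0 <- apply_group_de(means[1:100], 4, de_prob = 0)
  expect_equal(de0$group_means, matrix(1, 100, 4))

  # degenerate lognormal: factors collapse to 1 (or its inverse, also 1)
  set.seed(5)
  de1 <- apply_group_de(means[1:100], 2, de_prob = 1, de_fac_loc = 0,
                        de_fac_scale = 1e-9)
  expect_equal(de1$group_means, matrix(1, 100, 2), tolerance = 1e-6)
})

test_that("counts are Poisson around the library-scaled profile", {
  p <- simulation_params(n_genes = 1, n_cells = 20000, n_groups = 1,
                         lib_loc = log(50), lib_scale = 1e-12, seed = 1)
  set.seed(6)
  cs <- simulate_counts(matrix(5, 1, 1), rep(1, 20000), p)
  # single gene: profile sums to the gene itself, so each cell expects L = 50
  expect_equal(mean(cs$counts), 50, tolerance = 3 * sqrt(50 / 20000) / 50)
  # lib_scale ~ 0 means identical expected totals
  expect_lt(diff(range(cs$lambda)), 1e-6)

  # a gene with zero mean everywhere stays all-zero
  gm <- rbind(c(0, 0), c(3, 4))
  p2 <- simulation_params(n_genes = 2, n_cells = 100, n_groups = 2, seed = 1)
  set.seed(7)
  cs2 <- simulate_counts(gm, rep(1:2, 50), p2)
  expect_true(all(cs2$counts[1, ] == 0))
})

test_that("logistic dropout hits low-expression entries harder", {
  n <- 10000
  lam <- rbind(rep(0.5, n), rep(50, n))
  set.seed(8)
  counts <- matrix(stats::rpois(2 * n, lam), 2, n)
  set.seed(9)
  out <- apply_dropout(counts, lam, dropout_mid = 1, dropout_shape = -1)
  expect_true(all(out <= counts))
  zero_low <- mean(out[1, ] == 0)
  zero_high <- mean(out[2, ] == 0)
  expect_gt(zero_low, zero_high)
  # dropout disabled leaves the generated counts untouched
  p <- simulation_params(n_genes = 50, n_cells = 40, n_groups = 2,
                         dropout_enabled = FALSE, seed = 2)
  ds <- generate_dataset(p)
  expect_identical(ds$counts, generate_dataset(p)$counts)
})

test_that("generate_dataset honours shape, label range and determinism", {
  p <- simulation_params(n_genes = 2000, n_cells = 500, n_groups = 5,
                         outlier_prob = 0.1, seed = 11)
  ds1 <- generate_dataset(p)
  ds2 <- generate_dataset(p)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$labels, ds2$labels)
  expect_equal(dim(ds1$counts), c(2000, 500))
  expect_true(all(ds1$labels %in% 1:5))
  expect_true(all(ds1$counts >= 0))
  expect_true(all(ds1$counts == round(ds1$counts)))
})

test_that("strong DE produces recoverable groups; no DE produces none", {
  ds <- easy_dataset(n_cells = 400, n_genes = 300)
  pca <- embed_pca(tpm_normalize(ds$counts, log = TRUE), out_dim = 20)
  km <- kmeans_protocol(pca, ds$labels, repeats = 20, seed = 1)
  expect_gt(km$nmi_mean, 0.9)

  # null calibration: without DE or outliers, labels carry no information
  null_nmi <- vapply(1:3, function(s) {
    p0 <- simulation_params(n_genes = 200, n_cells = 200, n_groups = 4,
                            outlier_prob = 0, de_prob = 0, seed = s)
    d0 <- generate_dataset(p0)
    pc <- embed_pca(tpm_normalize(d0$counts, log = TRUE), out_dim = 10)
    kmeans_protocol(pc, d0$labels, repeats = 10, seed = s)$nmi_mean
  }, 0)
  expect_lte(mean(null_nmi), 0.05)
})

test_that("group separation increases with DE factor strength", {
  sil <- sapply(c(0.3, 0.8, 1.5), function(fl) {
    mean(vapply(1:5, function(s) {
      p <- simulation_params(n_genes = 200, n_cells = 200, n_groups = 3,
                             de_prob = 0.3, de_fac_loc = fl,
                             de_fac_scale = 0.4, seed = s)
      ds <- generate_dataset(p)
      pca <- embed_pca(tpm_normalize(ds$counts, log = TRUE), out_dim = 10)
      avg_silhouette(pca, ds$labels)
    }, 0))
  })
  expect_true(all(diff(sil) > 0))
})

test_that("the default simulation design is the documented 40-run manifest", {
  design <- simulation_design()
  expect_equal(nrow(design), 40)
  expect_equal(sum(design$swept == "n_cells"), 10)
  expect_equal(range(design$n_groups), c(5, 15))
  expect_equal(range(design$outlier_prob[design$swept == "outlier_prob"]),
               c(0.1, 0.5))
  expect_false(any(duplicated(design$id)))
})

test_that("dataset round-trips through the MTX/TSV container", {
  ds <- generate_dataset(simulation_params(n_genes = 60, n_cells = 30,
                                           n_groups = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_identical(back$labels, ds$labels)
  expect_equal(back$params$n_genes, 60)
})
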