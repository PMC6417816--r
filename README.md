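# latentbench

Hyperparameter-sensitivity benchmarking of variational-autoencoder (VAE)
latent spaces for single-cell RNA-seq.

## The problem

Projecting a genes × cells count matrix into a low-dimensional latent space
is the first step of most scRNA-seq analyses. VAEs are a popular nonlinear
choice, but their performance depends on tuning choices — network depth,
first-layer width, learning rate, batch size, epochs — far more than is
usually reported. `latentbench` is for method developers and reviewers who
want that dependence measured rather than asserted. It provides:

* a **seeded gamma-Poisson simulator** of labeled scRNA-seq counts
  (cell groups, expression outliers, lognormal library sizes, optional
  logistic dropout) emulating the Splatter hierarchy;
* a **Tybalt-style VAE** — encoder with 0–2 rectifier hidden layers
  producing the mean and log-variance of a 20-dimensional Gaussian code, a
  mirrored sigmoid decoder, trained with Adam on binary cross-entropy plus
  the closed-form KL term
  `KL(N(mu, sigma^2) || N(0, I)) = sum_j (mu_j^2 + sigma_j^2 - log sigma_j^2 - 1) / 2`,
  with a compiled training loop and a bit-compatible pure-R reference loop;
* **baselines** (PCA, t-SNE, UMAP, optional external-ZIFA adapter) behind
  the same embedding interface;
* **three evaluation protocols** against the ground-truth labels: repeated
  k-means (k = true number of groups, 50 independently seeded k-means++
  runs) scored by NMI and ARI; nested cross-validated kNN accuracy (5-fold
  outer, 3-fold inner sweep over the neighbour count); and average
  silhouette width;
* a **grid-search harness** that sweeps every (dataset × configuration)
  cell, scores failed/collapsed runs as NMI 0 instead of dropping them,
  resumes from a plain-text ledger, and extracts best/worst combinations
  per depth.

The headline result the benchmark reproduces: on one and the same
well-separated simulated dataset, a three-layer VAE swings from perfect
cell-type recovery (NMI = 1) to a completely collapsed, label-free latent
space (NMI = 0) across a modest tuning grid, while the two-layer model
stays robust in the same range.

## Worked example

```r
library(latentbench)

# a small 5-group dataset with strong differential expression
params <- simulation_params(n_genes = 300, n_cells = 400, n_groups = 5,
                            outlier_prob = 0.1, de_prob = 0.3,
                            de_fac_loc = 1.2, seed = 7)
ds <- generate_dataset(params)
ds
#> labeled_dataset: 300 genes x 400 cells, 5 groups, 6.1% zeros

# embed with PCA and with a two-layer VAE, score both
pca <- embed_pca(tpm_normalize(ds$counts, log = TRUE), out_dim = 20)
evaluate_embedding(pca, ds$labels, dataset_id = "demo", seed = 1)
#> eval_report [demo / pca]: kmeans NMI 0.963 (ARI 0.923), kNN acc 1.000, silhouette 0.548

zo  <- zero_one_scale(tpm_normalize(ds$counts))
cfg <- vae_config(depth = 2, first_hidden_dim = 100, learning_rate = 1e-3,
                  batch_size = 50, epochs = 60, seed = 1)
fit <- train_vae(build_vae(cfg, nrow(zo$values)), zo)
emb <- encode_cells(fit, zo)
evaluate_embedding(emb, ds$labels, dataset_id = "demo", seed = 1)
#> eval_report [demo / vae]: kmeans NMI 0.997 (ARI 0.995), kNN acc 1.000, silhouette 0.917
```

The k-means NMI is the probability-weighted information overlap between the
50-run clusterings of the latent space and the true groups (1 = perfect
recovery, 0 = no label information); the silhouette measures how much
tighter cells sit within their own group than next to the nearest other
group.

The tuning sweep itself:

```r
bench <- tuning_benchmark(master_seeds = 1:3)   # ~10 min on one CPU
bench$summary
#>  master_seed depth best_nmi worst_nmi spread n_failed
#>            1     2    1.000     0.973  0.027        0
#>            1     3    1.000     0.000  1.000        0
#>            2     2    1.000     0.980  0.020        0
#>            2     3    1.000     0.422  0.578        0
#>            3     2    1.000     0.987  0.013        0
#>            3     3    1.000     0.000  1.000        0
```

Each row is one independent simulate-and-sweep replicate (1200 cells × 400
genes, 5 groups): the best and worst mean k-means NMI across the 16-cell
tuning grid for that depth. The three-layer worst rows at 0.000 are
latent-space collapses — every cell encoded to the same point.

## Notes

* The simulator's defaults are "splatter-like" conventions
  (`inst/extdata/splatter_like_defaults.yaml`), overridable per call.
* The methods vignette (`vignettes/latentbench-methods.Rmd`) documents the
  generative model, the protocols, the scaled benchmark conditions and the
  known limitations, including why the two-layer worst configurations stay
  benign at this scale.
* ZIFA is supported only through a user-supplied external adapter and is
  skipped cleanly when absent.
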