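# hgcomplex

Protein complex prediction from protein sequences and the higher-order
topology of a protein–protein interaction (PPI) network.

## What it does, and for whom

Most complex-prediction tools mine dense subgraphs of the PPI network and
ignore what the proteins *are*. `hgcomplex` is for computational
biologists who want both signals: it fuses conjoint-triad (CT) sequence
features with clique-level network structure through a hypergraph
variational autoencoder (HGVAE), scores candidate subunit sets with a
feed-forward classifier, and mines novel complexes from the network with
a seed–expand–merge search. A synthetic planted-complex benchmark
generator makes the whole pipeline testable without any external
downloads.

## The model in brief

* **CT encoding.** The 20 residues map to 7 physicochemical classes; a
  sliding window of 3 counts class triads, giving a normalized
  $7^3 = 343$-dimensional frequency vector per protein (matrix $X$).
* **Hypergraph.** Each maximal clique (size ≥ 3) of the PPI network is a
  hyperedge; the binary incidence matrix $H$ has $H_{ik}=1$ iff protein
  $i$ is in clique $k$. Propagation uses the normalized operator
  $A = D_v^{-1/2} H W D_e^{-1} H^T D_v^{-1/2}$.
* **HGVAE.** Two hypergraph-convolution layers emit a Gaussian latent per
  protein ($\mu_i$, $\sigma_i$; sampled as $z_i = \mu_i + \sigma_i \odot
  \epsilon_i$); attention pooling builds hyperedge embeddings $e_k$; an
  inner-product decoder reconstructs $\hat H_{ij} =
  \mathrm{sigmoid}(z_i \cdot e_j)$; the loss is positive-weighted binary
  cross-entropy plus the closed-form KL to the standard-normal prior.
* **Classifier.** A complex embedding is the average of its members'
  latents; a 4-layer network with batch norm and dropout returns the
  probability that a set forms a complex, trained against 5× random
  negatives whose sizes follow the positive size distribution.
* **Detection.** Every PPI edge seeds a greedy expansion that adopts the
  best-scoring neighbor while scores exceed the threshold α and keep
  improving; overlapping candidates (neighborhood affinity > β) are then
  merged or removed in score order.
* **Evaluation.** Neighborhood affinity
  $\mathrm{NA}(p,b) = |p \cap b|^2/(|p||b|)$ at the 0.25 threshold gives
  precision/recall/F1; the intersection matrix gives
  $\mathrm{Acc} = \sqrt{\mathrm{Sn}\times\mathrm{PPV}}$; classifier
  quality is AUROC/AUPRC over resampled negatives.

## Worked example

```r
library(hgcomplex)
bm <- generate_benchmark(n_nodes = 300, n_complexes = 30, seed = 101)
res <- complex_prediction_pipeline(
  bm$network, bm$catalog, bm$planted,
  hgvae = hgvae_config(hidden_dim = 128, latent_dim = 32, proj_dim = 32,
                       epochs = 200, learning_rate = 5e-3),
  classifier = classifier_config(epochs = 200),
  detection = detection_config(),
  seed = 101)

nrow(res$predicted)
#> [1] 112
evaluate_complexes(res$predicted, bm$planted)
#> # A tibble: 1 × 9
#>   precision recall    f1    sn   ppv   acc n_matched_predicted n_matched_known
#>       <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>               <int>           <int>
#> 1     0.955  0.933 0.944 0.726 0.857 0.789                 107              28
#> # ℹ 1 more variable: na_threshold <dbl>
```

Of 112 predicted complexes, 107 match a planted complex at neighborhood
affinity ≥ 0.25 (precision 0.955) and 28 of the 30 planted complexes are
recovered (recall 0.933); the complex-wise accuracy
$\sqrt{Sn \times PPV}$ is 0.789. `autoplot(res$fit)` shows the HGVAE
training trace, and `plot_size_distribution(planted = bm$planted,
predicted = res$predicted)` compares size distributions on log–log axes.

Real data enter through plain-text formats: `read_fasta()`,
`read_edge_list()` (two-column TSV), `read_complex_sets()` (one complex
per line), `read_abundance()` (TSV matrix). A thin command-line wrapper
with `simulate`, `pipeline`, `evaluate` and `perturb` subcommands lives at
`inst/cli/hgcomplex.R`.

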