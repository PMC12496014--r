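# mvsrt — multiview denoising for spatially resolved transcriptomics

Spatially resolved transcriptomics (SRT) platforms — barcode-based (10x
Visium) and imaging-based (STARmap, osmFISH) — measure gene expression of
spots or cells together with their tissue coordinates, and often an H&E
histology image.  The expression readout is noisy: additive technical
noise, dropout (false zeros from capture inefficiency), and
spot-to-spot heterogeneity obscure the spatial-domain structure that
downstream analyses depend on.

`mvsrt` denoises SRT data by treating each modality as a *view* — expression
Y⁽ᵉ⁾, spatial coordinates Y⁽ˢ⁾, morphology Y⁽ᵐ⁾ — and learning spot features
that are consistent across all of them.  It is aimed at analysts who want a
denoised expression matrix and latent spot features as a preprocessing step
before spatial-domain clustering and marker-gene discovery.

## The model

1. **Heterogeneous data transformation.**  Expression is smoothed with a
   graph low-pass (Laplacian) filter, X⁽ᵉ⁾ = Hᵗ Y⁽ᵉ⁾ with
   H = D̃^(−1/2)(A + I)D̃^(−1/2) over the spatial KNN graph (t = 2 by
   default).  The spatial and morphology views are each reduced to a binary
   symmetric KNN affinity matrix, A⁽ˢ⁾ and A⁽ᵐ⁾.

2. **Multiview feature learning.**  Two independent MLP encoders map X⁽ᵉ⁾
   to latent branches Z⁽¹⁾ = φ₁(X⁽ᵉ⁾) and Z⁽²⁾ = φ₂(X⁽ᵉ⁾) + ε, where
   ε ~ N(0, σ²) is a Gaussian perturbation redrawn every epoch
   (contrastive augmentation).  A decoder reconstructs the input from the
   fused feature Z = (Z⁽¹⁾ + Z⁽²⁾)/2, and the latent affinity
   A = Ẑ⁽¹⁾ Ẑ⁽²⁾ᵀ (row-normalized) is pulled toward the view affinities.
   Full-batch Adam minimizes

       L = ‖X⁽ᵉ⁾ − D(Z)‖² + α‖A − A⁽ˢ⁾‖² + β‖A − A⁽ᵐ⁾‖².

   Without histology, β = 0 and the morphology term is omitted exactly.

3. **Denoising and downstream analysis.**  X̂⁽ᵉ⁾ = D(Z) from a
   perturbation-free pass is the denoised expression.  Spatial domains come
   from K-means on Z; evaluation uses MSE against ground truth (simulations),
   ARI against labels, and silhouette / Davies-Bouldin without labels.
   Marker genes are called per domain with one-vs-rest Wilcoxon rank-sum
   tests, Benjamini-Hochberg FDR, and detection / |log2FC| / FDR filters.

A multiview simulator with retained ground truth (shared clustered latent
structure, spatially contiguous domains, Gaussian noise sweep, dropout,
cluster merging) supports benchmarking; see the methods vignette
(`vignettes/multiview-denoising.Rmd`) for what it does and does not emulate.

## Worked example

```r
library(mvsrt)

sim <- simulate_multiview(sim_config(n_spots = 300, n_genes = 200,
                                     n_clusters = 6, noise_var = 0.5, seed = 0))
sim$dataset
#> srt_dataset: 300 spots x 200 genes
#>   morphology: 128 features
#>   truth labels: 6 domains
#>   normalized: TRUE

res <- denoise_pipeline(sim$dataset, model_config(epochs = 150, seed = 0))
res$model
#> trained_model: input dim 200 , latent 64 , 150 epochs
#>   loss: 65894.9 -> 7606.85

evaluate_mse(sim$truth$clean_expression, as.matrix(sim$dataset$expression))
#> [1] 100.7957       # observed vs clean
evaluate_mse(sim$truth$clean_expression, res$denoised)
#> [1] 41.55166       # denoised vs clean: error more than halved

domains <- identify_domains(res$latent, k = 6, seed = 0)
evaluate_clustering(domains, truth = sim$truth$labels, features = res$latent$Z)
#> evaluation_report:
#>   ari: 0.9299
#>   silhouette: 0.5559
#>   davies_bouldin: 0.6118
```

The denoised matrix recovers the clean profiles far better than the raw
observation (MSE 41.6 vs 100.8), and K-means on the learned features
recovers the six simulated spatial domains with ARI 0.93.

Real data enters through `load_visium()` (Space Ranger directory layout,
v1/v2 position files, gzipped variants) or `load_tables()` (generic
spots × genes CSV/TSV plus coordinates and optional morphology features),
followed by `filter_genes()`, `normalize_log()`, and optionally
`banksy_augment()` before `denoise_pipeline()`.  Morphology features can be
precomputed or extracted from an in-memory raster with
`extract_morphology()` (pluggable extractor; a deterministic fallback
ships with the package).

## Command line

A single entry point with subcommands (installed at `exec/mvsrt` inside the
package library, or call `mvsrt::run_cli()` directly):

```sh
Rscript -e 'mvsrt::run_cli()' simulate --n-spots 300 --n-genes 200 --out sim_out
Rscript -e 'mvsrt::run_cli()' denoise --expr sim_out/expression.csv \
    --coords sim_out/coords.csv --morph sim_out/morphology.csv \
    --normalized true --out dn_out
Rscript -e 'mvsrt::run_cli()' cluster --z dn_out/Z.csv --k 6 \
    --truth sim_out/labels.tsv --out cl_out
```

Every run writes its fully resolved configuration next to its outputs and
is byte-reproducible given the same seed.

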