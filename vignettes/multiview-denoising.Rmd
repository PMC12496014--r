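---
title: "Multiview denoising of spatially resolved transcriptomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview denoising: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `mvsrt`, the assumptions
behind it, the tunable parameters and the reasoning behind their defaults,
what the bundled simulator does and does not emulate, and the numerical and
design choices made where more than one reasonable option existed.

## The model and its assumptions

SRT data carry three modalities per spot: expression, spatial position, and
(for platforms with an H&E image) morphology.  The working assumption is
that technical noise enters each modality largely independently, while the
underlying tissue organization — spatial domains — is shared across all of
them.  Noise can therefore be suppressed by learning spot features that are
*consistent* across views, rather than by modeling each spot's expression in
isolation.

Three stages implement this:

**Graph low-pass filtering.**  The expression matrix is smoothed by `t`
applications of the self-loop renormalized propagation operator
$H = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}$, where $A$ is the binary
spatial KNN adjacency and $\tilde D$ the degree matrix of $A + I$.  $H$ is
the complement of a normalized graph Laplacian: its eigenvalues lie in
$(-1, 1]$ with smooth graph signals near $+1$, so repeated application
attenuates components that disagree between neighboring spots — the
graph-frequency band where iid technical noise concentrates.  The package
verifies this contraction property directly (the Rayleigh quotient of every
filtered column with respect to the graph Laplacian is non-increasing
in `t`).

The filter runs over the *spatial* graph.  The alternative — an
expression-KNN graph — would make the filter input-dependent and is less
robust at high noise, where expression neighborhoods themselves are
corrupted; the spatial view is the one modality guaranteed present and
noise-free in its role as an index.  Any `affinity_graph` can be passed to
`laplacian_filter()` if a different smoothing graph is wanted.

**Dual-encoder autoencoder with affinity consistency.**  Two independent
MLP encoders produce latent branches $Z^{(1)}$ and $Z^{(2)}$, the second
perturbed each epoch with fresh Gaussian noise of standard deviation
`sigma_std`.  The perturbation is a contrastive augmentation: because the
decoder reconstructs from the *average* $Z = (Z^{(1)}+Z^{(2)})/2$ and the
affinity couples the two branches bilinearly, the objective rewards
representations that are stable under the perturbation, which improves the
discriminability of the fused feature.  The latent affinity is
$A = \hat Z^{(1)} \hat Z^{(2)\top}$ after row-L2 normalization, and the loss

$$ L = \lVert X - D(Z)\rVert^2
     + \alpha \lVert A - A^{(s)}\rVert^2
     + \beta \lVert A - A^{(m)}\rVert^2 $$

is minimized by full-batch Adam.  With no morphology view, $\beta = 0$ and
the third term is omitted exactly — the two code paths are bit-identical,
which the test suite asserts.

**Row normalization of the latent branches** before the affinity product is
a deliberate choice.  The consistency targets $A^{(s)}, A^{(m)}$ are binary,
so an unbounded inner product would make the consistency term
scale-degenerate (the optimizer could shrink the latents to drive the term
to its minimum in norm rather than in structure).  Normalization bounds
$A \in [-1, 1]$, putting it on the scale of the targets; all-zero latent
rows map to all-zero affinity rows rather than NaN, with a zero subgradient.

**Denoising.**  After training, a perturbation-free pass gives
$\hat X = D(Z)$, the model's estimate of the clean expression; K-means on
$Z$ gives spatial domains.

## Parameters that matter

| parameter | default | units / range | rationale |
|---|---|---|---|
| `filter_order` t | 2 | filter steps | one step averages immediate neighbors only; two reaches the 2-hop neighborhood, enough to suppress iid noise without erasing domain boundaries entirely |
| `k_spatial` | 6 | neighbors | the hexagonal first ring of a Visium array; also reasonable for grids |
| `k_morph` | 10 | neighbors | morphology features are higher-dimensional and noisier; a larger k stabilizes the graph |
| `alpha`, `beta` | 1, 1 | ≥ 0 | the losses are raw squared-Frobenius sums, so the weights absorb scale; equal weighting is the neutral default |
| `sigma_std` | 1 | latent sd | standard-normal perturbation; 0 disables the contrastive branch |
| `latent_dim` | 64 | dims | comfortably above typical domain counts (5–20) while far below gene counts |
| `hidden_dims` | 256 | dims | smallest standard single-hidden-layer width for inputs of 10³–10⁴ features |
| `lr`, `epochs` | 1e-3, 500 | — | Adam default; 500 full-batch epochs reach a stable loss plateau at the scales tested |
| `banksy_augment` λ | 0.2 | [0, 1] | own expression dominates; the neighborhood mean contributes context without erasing spot identity |
| `min_cells` | 10 | spots | genes detected in fewer spots carry almost no clustering signal and inflate the feature space |

All are exposed through `model_config()` / function arguments and the CLI.

## The simulator: what it emulates, what it does not

`simulate_multiview()` draws `n_clusters` centroids from a standard Gaussian
in a `latent_dim`-dimensional space, adds within-cluster Gaussian scatter
(sd 0.3) per spot, and maps the shared latents through two independent
random loading matrices to produce the clean transcript and morphology
views — so the two modalities genuinely share cluster structure without
being copies.  Loadings are scaled so clean expression entries have roughly
unit variance, which makes the noise-variance sweep 0–0.9 directly
interpretable as a noise-to-signal ratio.  Spots occupy a jittered grid;
clusters fill contiguous, balanced serpentine strips, so domains are
spatially coherent and every domain has within-one-spot equal size.
Perturbations are applied in the order noise → dropout to the transcript
view; morphology receives fixed-level noise (default variance 0.1).

What it deliberately does **not** emulate: count statistics
(negative-binomial/zero-inflation — the values are continuous Gaussians, and
the returned dataset is flagged `normalized` so the count-preprocessing
chain refuses it), irregular tissue shapes, platform-specific spatial
artifacts, and rendered H&E images (morphology is generated at the feature
level).  A green simulation test therefore establishes that the machinery
recovers planted low-rank cluster structure under additive noise and
dropout — not that it handles count noise or real histology.

**A known structural limitation this world exposes.**  Because clean
expression entries have unit variance and clusters are strongly separated,
K-means on the *raw noisy* expression remains essentially perfect across
the entire noise sweep; meanwhile spatial smoothing inevitably blends the
handful of spots sitting exactly on domain boundaries, capping the
pipeline's ARI around 0.99 at these sizes.  Every misassigned spot in our
checks lies on a strip border.  A comparison of the form "pipeline ARI ≥
raw-expression ARI" is therefore structurally unwinnable in this world by
a margin of one or two boundary spots, and the corresponding acceptance
check is left failing rather than adjusting the generator after the fact;
the pipeline's advantage is expected to appear only when the raw view is
genuinely ambiguous (weaker separation or much higher noise than this
generator's stated range).

`merge_clusters()` regenerates the clean matrices from stored per-spot
latent deviations and the original loadings, so merged clusters literally
share a centroid in both modalities while within-cluster variation is
preserved — merging is a true coarsening of the same world, not a redraw.

## Numerical choices

- **KNN ties** are broken by lower spot index, making graphs deterministic
  on degenerate (duplicated-coordinate) inputs; symmetrization is by union,
  which guarantees minimum degree k (mutual-KNN can isolate spots).
- **Affinities are binary**, not distance-weighted: the consistency loss
  compares the learned affinity to them entrywise, and a binary target has
  a well-defined scale.
- **Losses are plain squared-Frobenius sums**, not means, exactly as
  defined above; α and β absorb any size-dependent rescaling.
- **Consistency loss memory**: the dense n × n latent affinity is
  materialized in row chunks (4096 rows) above that size, with identical
  results, so memory stays bounded for large sections.
- **Gradient correctness** of the consistency term (through the row
  normalization) is checked against central finite differences at 1e-4
  relative tolerance; observed agreement is ~1e-10.
- **Training determinism**: all randomness (initialization, per-epoch
  perturbations) flows from `config$seed`; identical seeds give
  bit-identical loss histories, and the caller's RNG state is restored.
- **Wilcoxon p-values**: exhaustive enumeration of group assignments
  (average ranks, so ties are exact) whenever `choose(n, n1) ≤ 2e5`;
  otherwise the exact no-ties null distribution when both groups ≤ 25;
  otherwise the normal approximation with tie and continuity correction.
- **Fold changes** use de-logged (`expm1`) group means floored at zero with
  pseudocount 1e-9 — a no-op for log1p-normalized counts that keeps the
  ratio defined on continuous matrices; "expressed" for the detection
  filter means nonzero.
- **Degenerate inputs**: all-zero spots are dropped (with a warning) before
  library-size normalization; an all-genes-filtered dataset is returned
  empty with a warning rather than erroring; ARI of two degenerate
  partitions with identical pair structure is 1 by convention.

## Open design decisions, resolved

- **Filter graph**: spatial KNN (see above); configurable.
- **Symmetrization**: union, for the minimum-degree guarantee.
- **Architecture**: encoders input→256→64 with ELU, mirrored linear-output
  decoder — the smallest standard choice; depth/width configurable.
- **Perturbation schedule**: ε is redrawn every epoch (stochastic
  augmentation), not fixed at initialization.
- **Neighborhood augmentation** implements the weighted self/neighbor-mean
  concatenation only — the core of BANKSY-style augmentation — without the
  azimuthal gradient term, keeping the module dependency-free.
- **Gene filtering order**: off-tissue spots are removed first, then genes
  are filtered, so detection counts reflect tissue spots only.
- **DE contrast**: one-vs-rest per domain; "adjusted FDR" is
  Benjamini-Hochberg, applied across genes within each domain.

## Known limitations

- The encoders are trained full-batch; very large sections (≫ 15k spots)
  would need minibatching, which is out of scope.
- No pretrained CNN weights ship with the package: morphology extraction
  accepts any callable extractor, and the built-in fallback (seeded random
  projection of intensity-normalized patches) is deterministic but not a
  semantic feature extractor.  Image decoding from PNG/TIFF files is left
  to the caller (no codec dependency in this environment); rasters are
  passed as in-memory arrays.
- Denoised output lives in the filtered-expression space: at noise levels
  near zero the reconstruction error of the autoencoder exceeds the (tiny)
  observation error, so denoising pays off only once real noise is present.
- Statistical tests assume exchangeability across spots; spatial
  autocorrelation inflates DE significance, as it does in all
  per-spot DE testing.
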