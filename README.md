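# spaFuse

Multi-view graph convolutional clustering of spatial transcriptomics
sections.

## The problem

Spatial transcriptomics assays (10x Visium, Stereo-seq, STARmap, ...)
measure a gene expression profile at every capture spot together with the
spot's position in the tissue. A central analysis step is **spatial
domain identification**: partitioning the spots into contiguous regions
with coherent expression — cortical layers, tumour compartments,
anatomical structures. Expression-only clustering (k-means, Louvain on
PCA) fragments such regions because it ignores where the spots are;
methods that use the two information sources jointly recover them far
better.

## The method

spaFuse learns one embedding per *view* of the data and fuses them:

1. **Two graphs.** A *spatial* graph connects spots closer than a radius
   `r` (Euclidean, strict inequality; default 700 in the input's
   coordinate units), and a *feature* graph connects each spot to its
   `k = 20` most cosine-similar spots (union-symmetrized). Both are
   normalized as `D^{-1/2}(A + I)D^{-1/2}`.
2. **Per-view GCN encoders.** A single graph-convolution layer per view
   maps expression `X` to embeddings `Z^(i)`.
3. **Implicit contrastive learning.** A per-view variational graph
   autoencoder (VGAE) models each spot as a latent Gaussian
   `N(mu_n, diag(sigma_n^2))` trained to reconstruct the view's adjacency
   via an inner-product decoder. Samples from that posterior are
   *implicit augmentations*: an InfoNCE loss pulls each anchor `z_n`
   toward its own posterior samples and apart from the other anchors in a
   batch (temperature `tau = 0.5`, `M = 5` samples/anchor), sharpening
   the embeddings without hand-designed graph perturbations.
4. **Attention fusion.** A learned vector scores each spot's two view
   embeddings; a softmax yields per-spot view weights and the fused
   embedding is their convex combination.
5. **Deep embedded clustering.** Student's-t soft assignments `Q` against
   k-means-initialized centroids are sharpened into a target `P`
   (refreshed every `T = 50` iterations) and the backbone minimizes
   `alpha * KL(P || Q) + beta * L_contrastive` with Adam (lr 0.003,
   weight decay 0.001), stopping when fewer than `delta = 0.1%` of
   labels change between refreshes.

Evaluation utilities implement the adjusted Rand index, normalized
mutual information, and Moran's I spatial autocorrelation (for scoring
spatially variable genes), and a synthetic layered-tissue generator
makes the whole pipeline testable offline.

## Worked example

```r
library(spaFuse)

# a synthetic cortex-like section: 2000 spots, 6 laminar domains,
# 200 genes, 10 markers per domain
ds <- simulate_st(sim_spec(seed = 1))
pp <- preprocess_st(ds, n_hvg = NULL)
pp$report
#> preprocess_report:
#>   spots removed: 0
#>   genes removed: 1
#>   HVGs kept:     199
#>   steps:         filter_genes -> log1p -> libsize_norm

fit <- fit_spafuse(pp$dataset, C = 6, cfg = st_config(seed = 1))
fit
#> spafuse_fit: 2000 spots, 6 domains (ablation: full)
#>   converged at iteration 600
#>   domain sizes: 350 299 367 349 286 349

ari(fit$labels, ds$labels)   # agreement with the planted domains
#> [1] 0.9602585
nmi(fit$labels, ds$labels)
#> [1] 0.9545225
```

For comparison, k-means on the normalized expression alone reaches an
ARI of about 0.6 on the same section — the spatial view and the
iterative refinement contribute the rest. `run_ablation()` quantifies
the contribution of each component (`wo_F` drops the feature view,
`wo_S` the spatial view, `wo_A` replaces attention by mean fusion), and
`morans_i_per_gene()` ranks genes by spatial autocorrelation:

```r
svg <- plant_svg(ds, pattern = "band", amplitude = 3)
g   <- build_spatial_graph(svg$coords, r = 150)
head(morans_i_per_gene(svg, g), 3)
#>                 gene_id  morans_i
#> svg_planted svg_planted 0.6109124
#> gene_0059     gene_0059 0.3118297
#> gene_0023     gene_0023 0.3099036
```

A thin command-line interface (`inst/cli/spafuse.R`) exposes `fit`,
`simulate`, `evaluate` and `svg-score` subcommands over the same
functions.

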