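# fcgradients

Functional-connectivity **gradient analysis of a seed region**, with the
downstream analyses that turn a gradient map into an interpretable
hierarchy: relation to intrinsic geometry, winner-take-all network
parcellation, meta-analytic term decoding, and a partial-least-squares
(PLS) association between the gradient and spatially sampled gene
expression, followed by gene-set over-representation analysis.

The package is aimed at neuroimaging researchers who have voxelwise
resting-state BOLD data (NIfTI, MNI space) for a seed region and want a
tested, reproducible implementation of the full gradient-to-transcriptome
pipeline — and at method developers, who can exercise every stage against a
synthetic-data generator that plants known structure.

## The method

Given group-concatenated, per-subject z-scored BOLD time courses, the
pipeline:

1. **Connectivity.** Computes the seed-to-brain functional connectivity
   matrix: Pearson r between every seed voxel and every target (cerebrum)
   voxel, Fisher z-transformed (z = artanh r).
2. **Sparsification.** Per seed-voxel row, zeroes negative connections and
   keeps only the top 10% of the remaining values (configurable; 20%/30%
   sensitivity sweeps supported).
3. **Affinity.** Cosine similarity between all pairs of sparsified rows,
   giving a positive symmetric affinity matrix W.
4. **Diffusion-map embedding.** With D = diag(rowSums(W)), forms the
   density-normalized W' = D^-α W D^-α (α = 0.5), row-normalizes it into a
   Markov matrix P, and eigendecomposes P. Component k's per-voxel
   coordinate is λ_k ψ_k; the *dominant gradient* is component 1, the axis
   explaining the greatest connectivity variance
   (λ_1 / Σ_j λ_j over positive non-trivial eigenvalues).
5. **Geometry.** Pearson correlation of the dominant gradient with the
   Euclidean distance from its peak voxel, tested by shuffling gradient
   values across voxels (5000 permutations, two-sided on |r|), per
   hemisphere.
6. **Networks.** Winner-take-all assignment of each seed voxel to the
   canonical network whose mean time course it correlates with most
   strongly; subdivisions summarised and ranked along the gradient.
7. **Behavioral terms.** The gradient is cut into 10 rank-based decile
   masks; each term z-map's mean z per mask forms its profile, terms with
   max bin mean > 2.3 are retained and ordered by a positive-part centre
   of mass.
8. **Transcriptomics.** Tissue samples are mapped onto the gradient via
   3 mm spheres; PLS component 1 (weights w ∝ Xᶜᵀyᶜ, scores Xᶜw) links
   expression to the gradient; significance by sample-shuffle permutation;
   per-gene loadings (Pearson r between gene and scores) define PLS+ /
   PLS− gene sets (top 25% of each sign, floor rule).
9. **Enrichment.** Fisher's exact over-representation of PLS+ / PLS− genes
   in annotation sets (GMT), Benjamini–Hochberg corrected, against the
   analyzed gene panel as background.

## Worked example

On the default synthetic world (200 seed voxels whose latent hierarchy runs
along the y axis, 1000 network-labeled target voxels, 3 subjects):

```r
library(fcgradients)
world   <- make_connectivity_world(seed = 42)
seed_ts   <- standardize_and_concatenate(world$per_subject_seed, world$seed_grid)
target_ts <- standardize_and_concatenate(world$per_subject_target, world$target_grid)

grad <- run_gradient_pipeline(seed_ts, target_ts)
print(grad)
#> <gradient_set> 200 voxels, 10 components (alpha = 0.5)
#>   dominant gradient variance explained: 12.0%
cor(dominant_gradient(grad), world$truth$latent, method = "spearman")
#> [1] 0.9990534

geo <- gradient_geometry(grad, hemisphere = "both", n_perm = 5000, seed = 43)
print(geo$L)
#> <geometry_test> r = -0.9907, p_perm <0.0002 (5000 permutations)

panel <- make_expression_panel(world, seed = 43)
pls <- pls_gradient_association(panel$panel, grad, n_perm = 5000, seed = 44)
print(pls)
#> <pls_association> 25 samples x 600 genes
#>   component-1 score-gradient r = 0.9924, p_perm = 0.0002 (5000 permutations)
#>   PLS+: 74 genes, PLS-: 75 genes
```

The Spearman correlation shows the dominant gradient recovering the planted
latent axis almost perfectly; the geometry test shows the gradient falling
off with distance from its peak (a strongly negative r, permutation p below
the 1/5000 resolution floor); the PLS fit links the 25-sample expression
panel to the gradient with the planted tracking genes carrying the
association.

`run_demo("somedir", seed = 42)` runs everything end to end — simulation,
gradient, geometry, parcellation, decoding, PLS, enrichment — writing TSV/
NIfTI outputs and a checksummed `manifest.json`. A thin command-line
wrapper with `simulate` / `run` / `demo` subcommands is installed at
`inst/cli/gradients.R`.

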