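---
title: "Seed-region connectivity gradients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-region connectivity gradients: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgradients)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the numerical
conventions fixed where the method literature leaves them open, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The gradient model

The object of study is the internal functional organization of a seed
region (the motivating case is the angular gyrus, a multimodal
inferior-parietal area; nothing in the code is specific to it). Each seed
voxel is characterized by its connectivity fingerprint: the Fisher
z-transformed Pearson correlation of its group-level BOLD time course with
every voxel of the rest of the cerebrum. Voxels whose fingerprints change
gradually across the region trace a *functional gradient* — a
low-dimensional axis of connectivity change — which is estimated by
diffusion-map embedding:

1. per row of the connectivity matrix, negative values are zeroed and only
   the largest `retain_fraction` of entries kept (default 0.10);
2. the affinity between voxels i and j is the cosine similarity of their
   sparsified rows, giving a symmetric non-negative matrix $W$ with unit
   diagonal;
3. with $D = \mathrm{diag}(W\mathbf{1})$, the density-normalized affinity
   is $W' = D^{-\alpha} W D^{-\alpha}$ and the Markov matrix
   $P = D'^{-1} W'$, $D' = \mathrm{diag}(W'\mathbf{1})$;
4. the eigenvectors $\psi_k$ of $P$ (computed through the symmetric
   conjugate $D'^{1/2} P D'^{-1/2}$, which guarantees a real spectrum),
   excluding the trivial constant eigenvector at $\lambda = 1$, give the
   embedding; component $k$'s coordinate is $\lambda_k \psi_k$.

The anisotropy parameter $\alpha \in [0,1]$ controls how strongly the
sampling density of the underlying manifold influences the embedding
($\alpha = 0$ maximal, $\alpha = 1$ none); $\alpha = 0.5$ is the standard
choice for brain connectivity data and the package default. Component 1 —
the *dominant gradient* — is the axis along which connectivity varies most.

Assumptions worth keeping in mind: the affinity graph must be connected
(the package refuses to embed a graph with repeated unit eigenvalues and
suggests densifying, i.e. raising `retain_fraction`); correlations are
computed on per-subject z-scored, concatenated series, so between-subject
amplitude differences are deliberately discarded; and negative
connectivity is treated as absence of connection, not as dissimilarity.

### Numerical conventions

Fixed, documented choices where the gradient literature states none:

* **Diffusion time**: coordinates are scaled by $\lambda_k$ (one-step,
  $t = 1$). Downstream analyses are rank- or correlation-based, so this
  choice does not affect them.
* **Variance explained**: $\lambda_k / \sum_j \lambda_j$ over all positive
  non-trivial eigenvalues. Conventions differ across packages; printed
  percentages are comparable only within a convention. (For this reason no
  claim is made of reproducing any particular published variance-explained
  percentage.)
* **Eigenvector sign**: flipped so each component's skewness is positive;
  if |skewness| < 1e-12, so that the maximum-|value| voxel is positive.
  Eigenvector signs are arbitrary; a deterministic rule makes reruns
  bitwise identical.
* **Correlation clipping**: r is clipped to ±(1 − 1e-7) before artanh, so
  degenerate perfect correlations stay finite.
* **Constant time series** (e.g. voxels outside the acquisition box) are
  zeroed with a warning and their correlations set to 0 rather than NaN.
* **z-scoring** uses the population (n) denominator.
* **Sparsification ties** at the row cutoff retain the lower target index.
* **Retained components**: 10 by default; only component 1 is analyzed
  further.

## Geometry, networks, terms

**Geometry.** The dominant gradient is correlated (Pearson) with each
voxel's Euclidean distance in mm from the gradient's peak voxel, per
hemisphere. Significance comes from shuffling the gradient values across
voxels (default 5000 permutations). The null comparison is two-sided on
|r|: a literal "null r greater than observed r" rule would yield p ≈ 1
for any negative observed correlation, which is plainly not the intent of
such a test; the magnitude rule is the evident one and is what the package
implements. When no null draw reaches |r|, the p-value is reported as
`< 1/n_perm`. Euclidean distance underestimates true cortical (geodesic)
distance where gyri fold — surface-based distance is out of scope.

**Winner-take-all parcellation.** Each seed voxel is assigned to the
canonical network (e.g. a seven-network labeling resampled to BOLD space)
whose mean time course it correlates with most strongly. Network means are
computed over *target* voxels only, so a seed voxel is never correlated
with a mean containing itself (self-correlation would inflate
assignments). Ties go to the lowest network index with a warning;
zero-variance voxels are reported as `unassigned`. Networks that win no
voxel are reported with n = 0 rather than dropped — real parcellations
routinely lack some subdivision (e.g. a limbic one) within a small seed.

**Term decoding.** The gradient is divided into 10 rank-based, equal-count
decile masks (value-based percentiles could empty a bin under duplicated
values; rank-based bins cannot). A term's profile is its mean z per mask;
a term is retained when its *maximum bin mean* exceeds the threshold
(default 2.3, strict inequality). The threshold is stated in the source
methodology only as "z-statistic > 2.3" without saying which statistic;
the max-over-bins mean is the only term-level statistic the profile
affords, so that is the documented rule. For visualization ordering, each
term gets a positive-part centre of mass
$\sum_b b\,\max(\text{profile}_b, 0) / \sum_b \max(\text{profile}_b, 0)$ —
a deterministic formula that reproduces the usual staircase arrangement.

## The transcriptomic association

Expression input is a processed sample × gene table (tab-delimited:
`sample_id`, `x`, `y`, `z` in MNI mm, then genes) of the kind produced by
standard atlas-processing pipelines; probe-level processing is out of
scope. Each sample's gradient value is the mean over seed voxels whose
centre lies within a closed 3 mm ball around the sample's coordinate;
samples with no voxel in radius are dropped with a warning.

Only the first PLS component is used, and for a univariate response it has
an exact closed form: the weight vector is
$w = X_c^\top y_c / \lVert X_c^\top y_c \rVert$ and the gene scores are
$X_c w$ (equivalent to the NIPALS/SIMPLS first component; no deflation is
needed). The score sign is aligned so the score–gradient correlation is
non-negative. Gene columns are centred but *not* variance-scaled by
default — atlas-style expression tables arrive already normalized — and a
`scale = TRUE` switch enables unit-variance scaling. Significance is
assessed by shuffling samples (default 5000 permutations), one-sided on
the sign-aligned correlation with a `>=` comparison at the observed value.

Per-gene *loadings* are the Pearson correlations between each gene's
expression and the scores. Genes are split by loading sign and the top
`floor(0.25 × n)` of each sign pool (descending |loading|) form the PLS+
and PLS− sets — the floor rule reproduces the canonical
1988 → 497 / 3025 → 756 arithmetic for a 5013-gene panel.

**Enrichment.** PLS+ and PLS− lists are tested against annotation sets
(GMT or comma-list format; precomputed cell-type or developmental-stage
lists are accepted as ordinary sets) with two-sided Fisher's exact tests
(minimum-likelihood convention, the dominant convention of enrichment
portals), Benjamini–Hochberg corrected. The background universe is the
analyzed gene panel, not the genome: enrichment must be conditional on
what could have been selected. FDR families are kept separate per query
set and per annotation file, mirroring per-panel reporting. The odds ratio
is the sample odds ratio with a Haldane 0.5 correction when a cell is
zero, and each set's *rich factor* is `n_overlap / n_set_in_background`.

## The synthetic-data generator

The generator exists so every stage can be tested against known truth
without any data download. It plants a single latent hierarchy axis in
[0, 1]:

* Seven network sources (visual 0.05, sensorimotor 0.20, DAN 0.35, VAN
  0.50, limbic 0.65, FPN 0.80, DMN 0.95 on the latent axis) emit unit-sd
  white signals. A voxel at latent $\ell$ has series
  $\sum_k e^{-(\ell - c_k)^2 / 2\sigma_c^2}\, s_k(t) + \sigma_n\,\epsilon$,
  with coupling width $\sigma_c = 0.1$ and noise $\sigma_n = 1$ (i.e.
  signal-to-noise 1 against the nearest source). Connectivity therefore
  decays smoothly with latent separation, which is precisely the structure
  the gradient model assumes.
* Seed voxels (default 200, 100 per hemisphere in mirrored 2×25×2 blocks
  on a 3 mm grid) take their latent from the y axis, with small
  within-slab increments so every voxel is unique while the latent stays
  essentially spatial (|r| ≥ 0.99 with y). Target voxels (default 1000)
  are grouped into the seven networks with latents jittered ±0.07 around
  each centre — so the DMN-like subdivision sits at one gradient extreme
  and visual/sensorimotor-like ones at the other, the configuration the
  parcellation recovery tests assert.
* The expression panel (default 25 samples at random seed-voxel
  coordinates, 600 genes, 10% tracking) models a tracking gene as
  $\pm\beta\, z(\ell) + \sigma\,\epsilon$ with $\beta = 1$, $\sigma = 0.5$,
  where $z(\ell)$ is the latent standardized across the drawn samples.
  $\beta$ is thus a *standardized* effect size in noise-sd units — the
  usual convention — giving per-gene |loading| ≈ 0.9 at the defaults; on
  the raw [0, 1] scale the same numbers would mean signal-sd 0.29 against
  noise 0.5 and tracking genes could not dominate the loading ranks.
* Term maps are Gaussian bumps on the latent axis (width 0.1 ≈ one decile
  bin, amplitude 5, noise 0.1); annotation sets include one planted set
  drawing half its members from positive-tracking genes.

Sizes were chosen so the full pipeline — including the 5000-permutation
tests — runs in seconds on one CPU while keeping the few-samples /
many-genes regime (25 × 600) that makes the PLS permutation test
non-trivial. Every generator is a pure function of its seed.

What the generator does **not** emulate: hemodynamic autocorrelation,
spatial smoothness of fMRI noise, inter-subject variability, scanner
drift, atlas donor structure, or realistic gene-gene correlation beyond
the shared latent. Passing recovery tests therefore demonstrates
correctness of the algorithms under the stated generative model, not
performance on real data.

## Pipeline, demo and determinism

`run_all()` chains the stages from one configuration (YAML or
`default_run_config()`), skips stages whose inputs are absent (a run
without an expression table simply ends at decoding), aborts naming the
failing stage otherwise, and writes a `manifest.json` with the
configuration, derived seeds and an md5 checksum of every output file —
reruns of an identical configuration are bitwise identical.
`run_demo()` simulates the default world and runs everything; it uses 500
permutations per test as its demo-scale setting (the analysis defaults
remain 5000). Optional global-signal regression (`gsr: true`) removes each
subject's mean series from every voxel before standardization, supporting
the usual sensitivity analysis; the package's confound interface is
general-purpose least squares residualization, and full nuisance
pipelines (motion models, filtering, normalization) are assumed done
upstream.

## Known limitations

* Group-level gradients only; no individual-level embedding or alignment
  (Procrustes) across datasets.
* Euclidean, not geodesic, distances in the geometry analysis.
* Single-component PLS; no bootstrap standard errors on loadings.
* Rank-based deciles make decoding invariant to monotone gradient
  transforms but discard within-bin gradient detail.
* The variance-explained convention is one of several in circulation;
  compare percentages only within a convention.
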