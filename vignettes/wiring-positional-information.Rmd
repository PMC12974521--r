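---
title: "Extracting wiring positional information from a connectome and spatial gene expression"
author: "wiringPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting wiring positional information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Sperry's chemoaffinity theory holds that axons locate their targets by
matching graded chemical labels between source and target tissue. wiringPI
operationalizes this idea at the whole-brain mesoscale: it assumes that a
small number of *wiring positional information* (wiring PI) gradients — each a
linear combination of regional gene-expression levels — govern which region
pairs connect. For a directed connection from region $r_s$ to region $r_t$,

$$
\mathrm{PI}_s(r_s) = \sum_d a_d\, x_d(r_s), \qquad
\mathrm{PI}_t(r_t) = \sum_d b_d\, x_d(r_t),
$$

where $x_d(r)$ is the (dimension-reduced) expression of feature $d$ at region
$r$. Connections are assumed to form preferentially where source and target
PI values are similar, so over the $N$ observed connections the paired values
$\mathrm{PI}_s(r_{s_n})$ and $\mathrm{PI}_t(r_{t_n})$ should correlate. The
weight pairs $(a^{(i)}, b^{(i)})$ are therefore estimated by canonical
correlation analysis (CCA) on the $N \times D$ matrices $X_s$ and $X_t$ whose
rows are the reduced expression vectors of each connection's source and
target: successive canonical pairs maximize the Pearson correlation of the
paired variates subject to unit variance and orthogonality to earlier
variates of the same side.

The estimated gradients support three downstream analyses:

1. **Reconstruction.** The squared PI distance
   $d_{PI}(r_s, r_t) = \sum_{k \le K} (\mathrm{PI}^{(k)}_s(r_s) -
   \mathrm{PI}^{(k)}_t(r_t))^2$ scores every directed region pair;
   thresholding it reconstructs a binary connectome, evaluated by ROC/AUC
   against the observed one and against a physical-distance baseline.
2. **Gene screening.** Genes whose spatial expression pattern resembles a PI
   gradient map (centered cosine similarity) are ranked, with significance
   from spatially-constrained surrogate maps.
3. **Null benchmarking.** Four connectome randomizations (global, within-MR
   block, distance-constrained, degree-constrained) and one
   expression randomization quantify how much of the extracted structure is
   attributable to chance, geometry, topology, or spatial autocorrelation
   alone.

### Assumptions

* The connectome is binary and directed; edge weights are deliberately not
  modelled (binarization keeps regions statistically comparable, at the cost
  of discarding projection strength).
* Only *inter*-major-region (inter-MR) cells are analyzable: within-MR,
  short-range connectivity is excluded by an explicit eligibility mask, and
  every downstream computation (CCA pairs, ROC universe, null models) works
  on that fixed cell set.
* Wiring PI is linear in the reduced expression features. Nonlinear label
  codes are out of scope.
* The adult expression atlas is treated as a proxy for the developmental
  gradients that wired the brain; the method is correlational throughout.

## Pipeline parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_components_pca` | 50 | dimensions | summarizes redundant spatial expression patterns and suppresses measurement noise before CCA |
| `n_components_cca` | 5 | components | the leading components carry the strongly correlated structure; later ones are dominated by noise |
| `k_used` | 5 | components | dPI uses the same top components, unweighted |
| `test_fraction` | 0.2 | proportion of eligible cells | held-out validation of correlations and AUC |
| `n_splits` | 10 | repeats | averages over hold-out draws |
| `ridge` | 0 | covariance units | plain CCA; N (thousands of connections) far exceeds D = 50. A positive ridge is required (and enforced) when N ≤ D |
| `knn` | 6 | neighbours | spatial weights for Moran's I |
| screening `M` | 999 | surrogates | p-value floor 1/(M+1) = 0.001 |

Expression is z-scored per gene (mean 0, sample SD 1 across regions) before
PCA, making both PCA and the cosine screening scale-free; genes with zero
variance are rejected rather than silently dropped. PCA scores are *not*
re-standardized before CCA — CCA is affine-invariant, so this is a
presentation choice only.

### Hold-out semantics

"Hold-out" partitions the eligible *cells* of the connection matrix (directed
region pairs, connected and unconnected alike), not the regions: CCA consumes
pairs, and a cell split keeps every region's expression in training while
still scoring out-of-sample pairs. Training canonical correlations are
evaluated on the held-out connected cells with the training weights and
training centering constants frozen; reconstruction AUC is evaluated on the
held-out cells only. A region-level split would additionally test
generalization to unseen regions, but conflates that harder question with
the wiring-rule question asked here.

### Determinism

Every randomized operation takes an explicit seed; per-replicate and
per-gene seeds are derived from a master seed through a recorded
counter-based derivation (`deriveSeeds()`), and the global RNG stream of the
calling session is always restored. CCA component signs are fixed by
correlating each source variate positively with the first reduced dimension;
PCA signs by making each component's largest-magnitude loading positive.

## The synthetic chemoaffinity generator

`simulateChemoaffinityData()` produces an atlas, expression matrix and
connectome with known ground truth. Its defaults are the package's reference
study conditions and mirror the mouse mesoscale setting: 213 regions in 13
major regions, 763 genes, edge density 0.05 over the eligible cells (about
2,100 inter-MR connections).

* **Atlas.** MR = spatially separated centroid cluster (cluster centres
  uniform in a 10-unit cube, within-cluster SD 0.8), so the eligibility mask
  and physical distances have realistic block structure.
* **Gradients.** Each of the `kStar = 3` planted components is a pair of
  standardized Gaussian-process draws (squared-exponential kernel) over the
  centroids, with decreasing length-scales (8, 4, 2 units): component 1
  varies at the whole-brain scale, component 3 within blocks. Successive
  maps are orthogonalized — planted components are distinct positional axes —
  which keeps them identifiable by CCA; source and target maps of a
  component share a cross-correlation of 0.5 by default. With
  `basis = "latent"` the process runs over random latent coordinates instead
  of the centroids, decoupling the wiring rule from geometry; this is how
  the package demonstrates that dPI reconstruction is not distance in
  disguise.
* **Expression.** Every gene is a random $N(0,1)$-weighted mixture of all
  planted maps plus i.i.d. noise (SD 0.3 against unit-variance maps) — the
  linear-mixture premise of the PI model, with the mixing matrix recorded.
* **Connectome.** Eligible cells connect with probability
  $1/(1 + e^{\beta (d_{PI} - \tau)})$, $\beta = 20$, with $\tau$ calibrated
  by bisection to the target density. Component weights in the generating
  $d_{PI}$ decrease (1 → 0.5), giving the planted components distinct
  association strengths — with equal strengths CCA would only be identified
  up to rotation within the planted subspace. `beta = Inf` gives the exact
  hard-threshold limit.

**What the generator does not emulate:** measurement noise structure of in
situ hybridization data, hemispheric asymmetries, non-linear label codes,
weighted or reciprocal connectivity biases, and realistic anatomy. Passing
tests on synthetic data therefore demonstrate correctness of the estimation
machinery under the model's own assumptions, not that the model is true of
any real brain.

## Spatially-constrained surrogates

Gene screening needs a null that preserves each gene map's spatial
autocorrelation (otherwise smooth genes look significant against smooth
gradients by construction). `makeSurrogates()` uses variogram matching:
permute the map, smooth the permutation with a family of distance-decaying
Gaussian kernels, keep the kernel whose variogram (on distance-quantile
bins) best matches the original map's, and rescale to the original mean and
variance. Three details matter for calibration, all adopted after the naive
procedure proved miscalibrated in simulation:

* candidate maps are rescaled to the target variance *before* the variogram
  comparison — smoothing shrinks variance, and the fit must judge shape, not
  scale;
* the kernel family includes permutation-admixture ("nugget") kernels
  $(1-a)K_b + aI$ and the pure permutation itself, so partially smooth and
  unstructured maps are representable;
* one kernel is selected per map by minimizing the mean variogram error over
  the whole permutation ensemble (`fit = "ensemble"`), and a structured
  kernel is adopted only when it beats the pure permutation's error by more
  than 5%. Per-surrogate selection overfits variogram noise; without the
  parsimony margin, roughly one in seven unstructured maps acquires spurious
  smoothness, visibly deflating small p-values.

With these choices, surrogates of spatially unstructured maps are exact
permutations (exactly calibrated p-values), and surrogate Moran's I of smooth
maps tracks the original far better than permutation alone. Calibration for
*strongly* autocorrelated null genes remains approximate: in simulation the
false-positive rate at $\alpha = 0.05$ can reach ~0.1 for very smooth genes
on clustered geometries. Moran spectral randomization would be a natural
alternative for users who need exact preservation of a weighted-graph
autocorrelation statistic.

Screening p-values are two-sided on $|$similarity$|$ (strong negative
similarity is as interesting as positive — gradients are sign-arbitrary) and
reported raw, with a Benjamini–Hochberg column appended as a convenience.

## Null models

All four connectome randomizers operate on the eligible cell universe and
conserve their constraint set exactly: total edge count (global), every
ordered MR-block count (local), per-distance-quantile-bin counts
(`nBins = 10`, distance-constrained), and both degree sequences
(degree-constrained, directed double-edge swaps with 10 attempts per edge;
failed proposals are skipped). Replicate failures inside an ensemble are
recorded per row, never dropped. The expression null replaces every gene by
one variogram-matched surrogate of itself, independently across genes —
cross-gene covariance is intentionally destroyed, which is the point of the
control: it asks whether gradients as good as the originals can be rebuilt
from expression patterns that only share the originals' spatial smoothness.

## Numerical choices and degenerate inputs

* CCA is solved by symmetric whitening (eigendecomposition) of both
  within-set covariances followed by an SVD of the whitened cross-covariance;
  a rank-deficient covariance with `ridge = 0` is an error instructing the
  user to set a ridge, not a silent pseudo-inverse.
* ROC/AUC uses the tie-corrected rank statistic (ties credit 0.5) and a
  threshold sweep over all distinct scores with infinite endpoints; the two
  agree to numerical precision, and both are tested against an exhaustive
  pairwise oracle.
* Correlations on degenerate strata (zero variance, fewer than 3 cells) are
  reported as `NA` markers, never coerced to 0.
* Variogram bins are distance quantiles; empty bins are `NA` and excluded
  from surrogate fitting.
* Missing expression values are rejected at read time; no imputation rule is
  offered.

## Problem sizes used by the test suite

The statistical tests run at deliberately desk-scale sizes chosen as the
smallest at which the checked contrasts are unambiguous: reference-condition
recovery and hierarchy checks use the full 213-region, 763-gene generator
over 20 seeds; screening calibration uses 80 regions, 200 null genes and
199 surrogates per gene; null-ensemble calibration uses 50–100 replicates.
All tests and the acceptance script are deterministic given their seeds.

## Known limitations

* Surrogate calibration is approximate for strongly autocorrelated null
  maps (see above).
* The locally randomized model conditions on the MR partition supplied with
  the atlas; with a poor partition, "local" and "global" structure are not
  cleanly separated.
* Degree-constrained rewiring explores the degree-preserving graph space by
  Markov swaps; 10 attempts per edge relocates well over half of the edges
  on sparse graphs but is not an exact uniform sample of that space.
* dPI weights retained components equally; a canonical-correlation-weighted
  variant is exposed (`componentWeights` in the generator, rho-weighting
  left to the user at analysis time) but not the default, since the equal
  weighting matches the plain squared-Euclidean reading of the
  reconstruction rule.
* With equal planted component strengths, recovered components are
  identified only up to rotation within the planted subspace; the reference
  generator avoids this deliberately.
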