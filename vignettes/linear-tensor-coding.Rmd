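---
title: "Linear tensor coding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear tensor coding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcoding)
```

## The modeling problem

Appearance atlases for volumetric medical images must be learned from very
few samples: an organ database may hold twenty scans of several million
voxels each. Vectorizing the volumes and running PCA estimates a covariance
of rank at most the sample count and ignores the spatial organization of
the data. Multilinear models avoid both problems by operating on the
volumes as 3rd-order tensors, learning structure per mode.

`ltcoding` implements two such models over an ensemble of co-registered,
same-shape volumes $\mathcal{A}_i \in \mathbb{R}^{I_1 \times I_2 \times
I_3}$, $i = 1, \dots, M$, plus the texture-modeling and classification
layers that sit on top of them. Both models center the data at the
ensemble mean $\mathcal{M}$ first; everything below acts on
$\bar{\mathcal{A}}_i = \mathcal{A}_i - \mathcal{M}$.

### The multilinear subspace baseline (GND-PCA)

`fit_gndpca()` fits one column-orthonormal factor matrix per mode,
$U^{(n)} \in \mathbb{R}^{I_n \times J_n}$, shared by the whole ensemble,
and one core tensor per sample:
$$
\bar{\mathcal{A}}_i \approx \mathcal{B}_i \times_1 U^{(1)} \times_2 U^{(2)}
\times_3 U^{(3)}, \qquad
\mathcal{B}_i = \bar{\mathcal{A}}_i \times_1 U^{(1)\top} \times_2
U^{(2)\top} \times_3 U^{(3)\top}.
$$
Minimizing the summed squared reconstruction error is equivalent to
maximizing the captured energy $S' = \sum_i \lVert \mathcal{B}_i
\rVert^2$. There is no closed-form joint solution, but with all other
modes fixed the optimal $U^{(n)}$ consists of the leading $J_n$
eigenvectors of $\sum_i C_{i(n)} C_{i(n)}^\top$, where $C_{i(n)}$ is the
mode-$n$ unfolding of the sample projected through the other modes'
transposed factors. The fit alternates these exact per-mode updates, so
$S'$ is non-decreasing by construction — a property the test suite asserts
on every fit.

### Linear tensor coding

The cores of the subspace model are not statistically independent across
entries and give no per-basis handle for interpretation or selection. The
coding model instead builds an ordered dictionary of unit-norm *rank-one*
basis tensors $\mathcal{B}_j = u^{(1)}_j \circ u^{(2)}_j \circ
u^{(3)}_j$ by greedy deflation:

1. fit the rank-$(1,1,1)$ subspace model to the current residuals (the
   same alternating iteration, retaining one vector per mode);
2. form $\mathcal{B}_j$ from those unit vectors;
3. set each sample's coefficient $c_{ij} = \langle \text{residual}_i,
   \mathcal{B}_j \rangle$ — for unit factors this equals the chain of
   mode products with $u^{(n)\top}_j$, and both routes are computed and
   compared in the tests;
4. deflate $\text{residual}_i \leftarrow \text{residual}_i - c_{ij}
   \mathcal{B}_j$ and repeat.

Deflation along a unit direction satisfies
$\lVert r \rVert^2 = c^2 + \lVert r - c\,\mathcal{B} \rVert^2$
per sample and step, so the summed residual norm can only decrease.
Extraction stops when $\sum_i \lVert \text{residual}_i \rVert \le r$
(`threshold_r`; with `relative = TRUE` the sum is measured relative to the
centered input, which is the scale-free form we recommend), when
`max_bases` is reached, or when the residual hits the rounding-noise floor
($10^{-12}$ of its initial value), at which point further "bases" would
fit arithmetic noise and the dictionary is truncated.

With `max_bases = 1` the two models agree exactly — same factors, same
reconstruction — which the acceptance tests check to $10^{-10}$.

Greedy rank-one deflation does **not** produce mutually orthogonal bases
in general, and previously extracted bases are never revisited.
Consequently `encode()` is defined as the same *sequential* deflation used
during fitting, not as independent inner products against each basis; the
two would differ whenever bases overlap. Held-out volumes are encoded by
the identical procedure, which is what makes leave-one-out classification
with per-fold refitting possible.

## Tunable parameters

* `core_ranks` (GND-PCA): retained rank per mode, $1 \le J_n \le I_n$. For
  full-resolution organ volumes a core around $20 \times 20 \times 3$
  retains the leading structure of the two in-plane modes and the much
  shorter through-plane mode; toy problems use $(2,2,2)$–$(3,3,2)$.
* `max_bases` (LTC): dictionary budget. The default, 1200, is the budget
  appropriate for $256 \times 256 \times 79$ volumes; the synthetic
  studies in this package use 5–25.
* `threshold_r` / `relative`: residual stopping rule, see above. Default 0
  (budget-limited fitting), since an absolute residual threshold is
  dataset-scale dependent.
* `tol` ($10^{-9}$, relative change of $S'$) and `max_sweeps` (50) control
  the alternating iteration. With the HOSVD-style initialization below,
  well-separated spectra converge in a handful of sweeps; the cap only
  matters near degenerate eigenvalues, where any member of the eigenspace
  gives the same captured energy.
* Classification: linear-kernel SVM with `cost = 1` and KNN with `k = 3` —
  deliberately plain defaults for 20-sample problems, exposed in
  `loo_classify()`. Features are z-scored inside each fold using
  training-fold statistics, because coding coefficients span orders of
  magnitude across bases and both classifiers are scale-sensitive.
* `select_bases(k)`: ranks by $|r|$, the absolute point-biserial
  correlation between a coefficient column and the $\pm 1$ labels — an
  anti-correlated basis separates the classes exactly as well as a
  correlated one. Ties break toward the lower (earlier-extracted) basis
  index. An alternative normalization occasionally seen in print, with
  denominator $\sqrt{\sum_i (c_i - \bar{c})^2 (l_i - \bar{l})^2}$, is
  available behind `literal = TRUE` for comparison; it is not a
  correlation (it is not bounded by 1) and is never used by the package
  itself.

## Numerical conventions

* **Unfolding.** `unfold(x, n)` places the mode-$n$ fibers as columns,
  enumerating the remaining modes in their original column-major order;
  `fold()` is its exact inverse. Every algorithm here is invariant to this
  choice; the brute-force oracles in the tests pin it down.
* **Sign conventions.** Eigenvectors (and therefore basis factors) are
  flipped so their largest-magnitude entry is positive, making fits
  reproducible across linear-algebra backends. An alternative rule —
  orienting each basis so its coefficients have non-negative sample
  mean — is vacuous here: after mean-centering, each basis's coefficients
  sum to exactly zero (the deflation preserves $\sum_i \text{residual}_i =
  0$), so their mean is identically zero.
* **Eigendecomposition.** The per-mode update eigendecomposes the
  accumulated $I_n \times I_n$ covariance (symmetric, small) rather than
  taking an SVD of the wide stacked unfolding — equivalent, and memory
  stays bounded by mode sizes rather than voxel counts.
* **Initialization.** Factors start from the leading eigenvectors of each
  mode's covariance of the centered data (the HOSVD truncation):
  deterministic, cheap, and close to the fixed point in practice.
* **Degenerate inputs.** Non-finite voxels, shape mismatches, empty
  ensembles, ranks exceeding mode sizes, single-class label vectors and
  constant coefficient columns are all rejected with specific errors;
  leave-one-out folds whose training half is single-class are skipped
  with a warning and excluded from the denominator.
* **Texture synthesis.** Coefficient statistics use the sample ($n-1$)
  standard deviation. The admissible band for a swept coefficient,
  $|\tilde{c} - m_k| \le 2\lambda_k$, is centered at the training mean
  $m_k$ by default; since $m_k = 0$ on centered training coefficients, the
  zero-centered variant (`center = "zero"`) coincides with it on any model
  fitted with mean subtraction. Out-of-band values are clamped with a
  warning, or rejected with `strict = TRUE`.

## The synthetic generator

`generate_ensemble()` draws, deterministically per seed,
$$
\mathcal{A}_i = \mathcal{M} + \textstyle\sum_j c_{ij} \mathcal{B}_j +
\varepsilon_i,
$$
with a smooth separable mean texture (raised-cosine bump, amplitude 100,
mimicking the interior-bright profile of a registered organ), planted
unit-norm rank-one bases whose per-mode factors are mutually orthogonal
(QR of seeded Gaussian matrices), shared coefficients
$c_{ij} \sim N(0, (\text{coef\_scale} \cdot \text{decay}^j)^2)$,
class-linked coefficients $N(l_i \cdot \text{effect}/2, \text{sd}^2)$ for
labels $l_i = \pm 1$, and i.i.d. Gaussian voxel noise. Defaults — 20
samples of $16 \times 16 \times 8$, five shared bases with decay 0.7 at
scale 10, two class bases with effect 2 and within-class sd 0.1, noise sd
0.1 — emulate a two-class, 10-per-group organ database at desk scale.

Per-mode orthogonality of the planted factors is a deliberate idealization:
it makes the planted structure exactly recoverable by greedy deflation, so
recovery tests have a well-defined ground truth. Real organ textures offer
no such guarantee — greedy extraction on real data yields overlapping bases
and the sequential encoding above is then essential. The generator also
does not simulate registration error, intensity non-uniformity, or
non-Gaussian lesion statistics; passing the recovery and classification
tests therefore demonstrates correctness of the algorithms under their own
assumptions, not clinical performance.

### The buried-discriminant benchmark

The classification study in the test suite and acceptance script uses 10
seeded ensembles of 20 samples at $22 \times 22 \times 22$: twenty
nuisance bases (decay 0.92, scale 10) and two class-linked bases with
effect 1.5, within-class sd 0.4 and voxel noise sd 0.2. The shape is the
smallest cube that can host 22 per-mode-orthogonal factors. The class
parameters are chosen so that the class-coefficient variance
($\approx 0.72$) ranks below every nuisance variance (smallest
$\approx 3.6$) — the discriminative bases are extracted *last* and their
signal is diluted when all 22 coefficients feed the classifier — while
their label correlation ($\approx 0.86$ in expectation) towers over the
nuisance correlations ($\lvert r \rvert \lesssim 0.45$ at $M = 20$), so
correlation-based selection finds them reliably. This reproduces, at desk
scale, the regime that motivates basis selection: variance-ordered
extraction is the wrong order for discrimination. The chance-level control
applies the same pipeline to ensembles with no class-linked structure and
arbitrary balanced labels.

For this benchmark the representation is fitted once per ensemble and
leave-one-out is applied to the classifier (the pooled protocol); both
arms of the comparison — all coefficients versus selected ones — share the
features, so the comparison is symmetric with respect to any optimism from
pooling. `classification_experiment()` defaults to the stricter
`fold_mode = "refit"`, which refits the dictionary *and* the selection
inside every fold and encodes the held-out volume with the fold's model;
it is exercised in the unit tests at smaller problem sizes, where its
cost (one dictionary fit per fold) is negligible.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: algebra oracles on tensors up to $5 \times 6 \times 7$ (a hundred
seeded cases), model fits at $8 \times 7 \times 6$ to $16 \times 16 \times
8$ with 6–20 samples, and the classification benchmark above. These sizes
were chosen so the full suite completes in about a minute while every
assertion still probes the same code paths a $256 \times 256 \times 79$
ensemble would exercise; nothing in the implementation is specialized to
small shapes, and memory scales linearly in voxels × samples.

## Known limitations

* Greedy deflation is locally optimal per step with no joint refitting;
  it can split or rotate non-orthogonal planted structure, and offers no
  global optimality guarantee.
* The dictionary is ensemble-specific: there is no out-of-ensemble mean or
  basis adaptation, and encoding assumes the new volume is registered to
  the training frame.
* Coefficient Gaussianity is an assumption of the texture model, not a
  property the fit enforces; heavy-tailed coefficient distributions make
  the $\pm 2\lambda$ band unreliable.
* NIfTI affines are ignored (a warning is issued when they are
  non-trivial): volumes must be resampled to a common grid upstream.
* The classifiers are deliberately minimal; the package's claim is about
  the representation and selection, not about classifier engineering.
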