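# ltcoding

Statistical texture modeling of co-registered volumetric images by **linear
tensor coding** (LTC): a greedy rank-one tensor decomposition that represents
every volume in an ensemble as the mean texture plus a linear combination of
shared unit-norm rank-one basis tensors. The package also provides the
multilinear-subspace baseline **GND-PCA** (generalized N-dimensional PCA, a
Tucker model shared across the ensemble), a Gaussian texture model over the
learned coefficients, correlation-driven selection of class-discriminative
bases, leave-one-out SVM / KNN classification, a seeded synthetic-ensemble
generator, NIfTI dataset I/O, model persistence and a command-line interface.

It is aimed at researchers building appearance atlases from small ensembles
of shape-normalized medical volumes (tens of samples, millions of voxels),
where classical vector PCA overfits and voxel-level texture carries the
diagnostic signal.

## The model

A volume is a 3rd-order tensor 𝒜ᵢ ∈ ℝ^{I₁×I₂×I₃}. GND-PCA fits one
column-orthonormal factor matrix U⁽ⁿ⁾ ∈ ℝ^{Iₙ×Jₙ} per mode, shared across
the centered ensemble, by alternating per-mode eigendecompositions so that

    𝒜ᵢ ≈ ℳ + ℬᵢ ×₁ U⁽¹⁾ ×₂ U⁽²⁾ ×₃ U⁽³⁾,   ℬᵢ = (𝒜ᵢ − ℳ) ×₁ U⁽¹⁾ᵀ ×₂ U⁽²⁾ᵀ ×₃ U⁽³⁾ᵀ,

maximizing the captured energy Σᵢ‖ℬᵢ‖². LTC instead extracts unit-norm
rank-one bases greedily: at step j it fits the rank-(1,1,1) model to the
current residuals, forms ℬⱼ = u⁽¹⁾∘u⁽²⁾∘u⁽³⁾, takes each sample's
coefficient cᵢⱼ = ⟨residualᵢ, ℬⱼ⟩ and deflates, stopping when
Σᵢ‖residualᵢ‖ falls to a threshold r (or a basis budget). Every sample is
then

    𝒜ᵢ = ℳ + Σⱼ cᵢⱼ ℬⱼ + residual.

With a single basis, LTC coincides with rank-(1,1,1) GND-PCA. Treating each
coefficient column as Gaussian with mean mₖ and standard deviation λₖ gives
a generative texture model (`synthesize_volume()` sweeps one coefficient
within ±2λₖ). For two-class ensembles (labels −1/+1), each basis is scored
by the point-biserial Pearson correlation between its coefficients and the
labels; the top-k bases by |r| feed a leave-one-out SVM / KNN.

## Worked example

```r
library(ltcoding)
spec  <- synth_spec(seed = 1)          # 20 volumes, 16x16x8, two classes
gen   <- generate_ensemble(spec)
model <- fit_ltc(gen$samples, max_bases = 7)
model
#> Linear tensor coding model: shape (16x16x8), 7 basis/bases
#>   residual norm sum: 188.043 -> 88.0428 (20 sample(s))

reconstruction_quality(model, gen$samples, c(0, 1, 3, 5, 7))
#>   n_bases correlation
#> 1       0   0.9999568
#> 2       1   0.9999719
#> 3       3   0.9999856
#> 4       5   0.9999900
#> 5       7   0.9999910

sel <- select_bases(model$coefficients, gen$labels, k = 3)
round(sel$correlations, 3)
#> [1]  0.085 -0.265 -0.159  0.080  0.086  0.994  0.990
sel$selected
#> [1] 6 7 2

loo_classify(model$coefficients[, sel$selected], gen$labels, "svm")$accuracy
#> [1] 1
```

The residual-norm sum drops from 188.0 to 88.0 over seven bases (what
remains is voxel noise plus unextracted structure); the normalized
correlation between original and reconstructed volumes rises monotonically
with the basis count (it starts near 1 here because the shared mean texture
dominates the synthetic volumes). The two planted class-linked bases are
recovered as bases 6 and 7 with label correlations 0.994 and 0.990, and
classifying on the three selected coefficients is perfect in leave-one-out,
while the first, variance-dominant bases carry almost no class signal —
the motivation for selecting bases by label correlation rather than by
extraction order.

The same pipeline is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ltcoding", package = "ltcoding"))')
Rscript "$CLI" synth --shape 16,16,8 --n 20 --seed 1 --out data/
Rscript "$CLI" fit-ltc --input data/ --max-bases 7 --out model.rds
Rscript "$CLI" select --model model.rds --labels data/labels.csv --k 3
Rscript "$CLI" classify --input data/ --labels data/labels.csv \
    --max-bases 7 --select-k 3 --fold-mode refit
```

All subcommands are bitwise reproducible given `--seed`.

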