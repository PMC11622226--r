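---
title: "Memory-bounded incremental PCA for MSI datacubes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-bounded incremental PCA for MSI datacubes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msipca)
```

## The problem

Principal component analysis is the workhorse first step of mass spectrometry
imaging (MSI) analysis: a peak-picked MSI dataset is a matrix of pixels
(spectra) by mass peaks, and its leading principal components summarise the
chemically distinct regions of the sample. Modern instruments produce cubes
with hundreds of millions of pixels; a dense PCA needs the whole centred
matrix in RAM, which fails long before that point. `msipca` computes the same
decomposition *out of core*: the cube stays on disk as a flat binary file,
and the fit streams fixed-size batches of spectra through a rank-limited SVD
update, so peak resident memory scales with the batch size — never with the
number of spectra.

## The datacube format

A cube is two files: `<name>.bin`, a flat row-major sequence of
little-endian 32-bit IEEE-754 floats (one spectrum per row, one peak per
column), and `<name>.json`, a sidecar with `n_spectra`, `n_peaks`, the peak
m/z axis, and the region layout (each region a `width x height` pixel grid
with a row offset, so multi-image datasets concatenate cleanly). The binary
file is therefore exactly `n_spectra * n_peaks * 4` bytes, an invariant
checked every time a cube is opened; a mismatch means truncation.

Byte order is fixed little-endian and declared in the sidecar. Float32 is
the storage precision throughout (cube, scores, loadings); arithmetic in R
is double precision, and the running accumulators described below are kept
in double deliberately — single-precision accumulation of row counts and
sums breaks down beyond tens of millions of rows, exactly the regime this
package targets.

Centroided imzML can be imported with `convert_imzml()`: each centroid is
summed into the peak window `mz +/- tolerance`; a centroid inside two
overlapping windows goes to the nearer centre (ties to the lower index),
and the overlap is reported.

## The incremental fit

The model state after seeing `N` spectra is: the running mean `mu` and
accumulated squared deviations `m2` per peak (combined batch-by-batch with
the Chan pairwise-update formulas), and a rank-`k` factorisation
`(s, V)` — singular values and orthonormal loading rows. Each batch `X`
(`d` rows) is processed as:

1. centre by the *batch* mean: `X_c = X - mu_b`;
2. form the mean-correction row `c = sqrt(N d / (N + d)) (mu - mu_b)`,
   which accounts for the drift between the running and batch means;
3. stack `A = [diag(s) V ; X_c ; c]` and take a thin SVD
   (first batch: `A = X_c`, which must have at least `k` rows);
4. keep the top-`k` singular values and right singular vectors.

This is the sequential Karhunen-Loeve update: with `k` equal to the number
of peaks it is exact (up to roundoff) regardless of batching, and with
`k < F` it tracks the dominant subspace. Explained variance is
`s_i^2 / (N - 1)`; its ratio divides by the total variance
`sum(m2) / (N - 1)`, so at `k = F` the ratios sum to one. A deterministic
sign convention (largest-magnitude loading entry made positive, ties to the
lower peak index) makes runs comparable; comparisons additionally sign-align
per component because PCA signs are arbitrary.

Scores are produced by a second streaming pass: per batch,
`(X - mu) V^T` is written at the matching row offset of an on-disk float32
matrix. With `concurrency > 1` groups of batches are computed in forked
workers and written sequentially in row order, so the output is bitwise
identical to a sequential run while memory grows only with the concurrency
level.

### Batch size

The default batch size is **19 x the number of peaks**, clipped to the
number of spectra. The multiplier balances SVD throughput (larger batches
amortise the decomposition) against resident memory (the stack is
`(k + d + 1) x F`); it is exposed as a parameter, and any choice gives the
same answer — the test suite checks that singular values agree to 1e-3
relative across batch sizes from `F` to the whole cube. Per batch the work
is `O(d F^2)` and the footprint `O(d F)` values. If the requested batch
size is below `k`, only the first batch is enlarged to `k` rows so the
initial SVD is feasible.

### Degenerate inputs and numerical choices

* Zero-variance cube: all singular values are 0 and the variance ratios are
  defined as 0, not NaN.
* Ties in singular values: SVD output order is kept (values are already
  nonincreasing); no extra re-sorting.
* The last partial batch is processed as-is; the stack always has at least
  `k + 1` rows, so the update stays well-posed.
* r-squared between loading vectors is the squared Pearson correlation —
  symmetric and scale-free; a zero-variance vector makes it undefined and
  it is reported as missing, never as 0.

## Comparators

Two baselines calibrate accuracy claims. `exact_pca()` is the deliberately
naive dense SVD of the centred in-memory matrix — it shares the model shape
and sign convention, so models are directly comparable. `subsampled_pca()`
fits the same dense PCA on a uniform without-replacement sample of 6.5% of
the pixels (the fraction is a parameter) and centres all pixels with the
subsample mean when transforming. The comparison toolkit reports
per-component sign-aligned MSE and r-squared, grouped means over components
1-10 / 11-20 / 21-30, pixelwise score differences as percent of the
reference component's range, and basis-independent principal angles.

## The synthetic generator

`generate_datacube()` plants known structure:
`X = b + sum_i lambda_i u_i v_i^T + sigma eps`, with orthonormal loadings
`v_i`, zero-mean unit-norm spatially smooth score patterns `u_i`
(low-frequency cosine fields per region, centred and orthonormalised), a
geometric singular spectrum `lambda_i = lambda0 gamma^(i-1)`, and i.i.d.
Gaussian noise. Defaults are chosen once to emulate a strong-contrast
peak-picked MSI image: `noise_sd = 50` (ion-count scale), baseline
`b = 3 sigma` so intensities are mostly positive (values may still go
negative — PCA does not need nonnegativity, and clipping would distort the
planted covariance), and `lambda0 = 30 sigma (sqrt(m) + sqrt(n))`, i.e. a
leading component 30 times above the noise singular-value edge. Noise is
generated in fixed 8192-row blocks, so a cube is bit-reproducible from its
seed at any size.

What the generator does *not* emulate: correlated (Poisson-like) noise,
isotope patterns, peak-picking artefacts, or nonnegativity of real
intensities. Passing tests therefore demonstrate algorithmic correctness on
low-rank-plus-noise data, not robustness to every property of real spectra.

## Validation workflow and problem sizes

The test suite validates the fit against dense oracles at sizes chosen to
run comfortably on one CPU: hand-computable 4 x 2 cases, 200 x 10 batched
updates against a dense SVD, and a 50,000 x 100 cube (rank 15,
`gamma = 0.7`, seed 42) on which the mean sign-aligned r-squared of the
first ten incremental loading vectors against exact PCA must be at least
0.999. Property checks (batch-size robustness, variance conservation at
`k = F`, orthonormality, reconstruction, planted-subspace recovery at high
SNR, subsampled-PCA error strictly above the incremental fit's over five
seeds, bitwise concurrency identity) run on 4,000 x 25 cubes.

Memory instrumentation (`mem_profile()`, `bench_fit_memory()`) samples a
forked child's resident set at 15 ms intervals and reports peak minus the
resting baseline. Absolute numbers are hardware- and allocator-dependent, so
the flatness of fit memory across cube sizes is reported as an informational
benchmark rather than asserted in CI; the out-of-core *contract* — the
reader holds one batch at a time and releases it before the next — is
structural in `iter_batches()`.

## Rendering

`rgb_composite()` maps components 1-3 to red/green/blue with per-component
min-max scaling over the whole dataset (one colourbar per figure, not per
region; an optional percentile clip is available but off by default),
rounds half-up to 8-bit channels, and places pixels on each region's
row-major grid. `difference_heatmap()` renders percent-of-range score
differences with a diverging scale centred at zero.

## Known limitations

* Profile-mode (non-centroided) data is out of scope; cubes arrive
  peak-picked.
* No whitening, randomised-SVD variant, or single-row online updates.
* `exact_pca()` intentionally does not trap out-of-memory conditions — it
  is the naive baseline.
* The imzML reader covers centroided continuous/processed files with
  float32/float64 arrays; compressed binary arrays are not supported.
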