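---
title: "Enhancing single-cell Hi-C contact maps: model, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing single-cell Hi-C contact maps: model, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single-cell Hi-C experiment yields, per chromosome, a symmetric
matrix of contact counts between fixed genomic bins (40 kb here).
Because one cell contributes at most two copies of each locus, these
matrices are extremely sparse — typically under 5% of the contacts a
bulk experiment would see — and the sparsity hides exactly the
features one wants to read off: TAD blocks along the diagonal, loops,
and the distance decay of contact frequency. `schicenh` treats map
enhancement as a paired image-restoration problem: given a
low-coverage map, predict the high-coverage map of the same cell.

## Model

**Generator.** A shape-preserving residual network on 40 × 40 patches:
a 3×3 convolution lifts the single channel to 256 feature channels; 32
residual blocks follow, each `conv → ReLU → conv → ×res_scale → add
input`; a post-residual 3×3 convolution is joined to the stem output
by a global skip connection; a 3×3 head returns to one channel.
Two choices matter and are tested as architectural contracts:

- *No batch normalization in the generator.* Contact maps have highly
  variable intensity statistics per patch; normalizing them away hurts
  restoration, and the residual scaling below makes it unnecessary.
- *Residual scaling 0.1.* Each block's contribution is damped before
  the skip addition, which keeps very deep stacks stable early in
  training. `res_scale = 0` degenerates every block to the identity —
  a property the test suite uses to verify the wiring.

The global skip connection is not forced by the block design; we
enable it by default (`generator_config(global_skip = TRUE)`) because
the stem output is an excellent initial estimate of the answer in a
restoration problem and the trunk then only needs to learn the
correction. It is a config switch, so ablation needs no code change.

**Discriminator.** A standard image-GAN classifier: 3×3 stem (64
channels) with leaky ReLU (slope 0.2), seven blocks of `conv → batch
norm → leaky ReLU` with kernel pattern 4,3,4,3,4,3,3, stride 2 at the
4×4 blocks, channel width doubling entering blocks 2, 4 and 6 (widths
64,128,128,256,256,512,512), then a 3×3 head whose sigmoid output is
averaged spatially into one probability per patch. The width/stride
schedule follows the usual super-resolution GAN discriminator; the
description we implement fixes the kernel pattern and block count, and
the doubling schedule is the conventional completion consistent with
them.

**Losses.** The generator minimizes

```
L_G = l_MSE + alpha * l_VGG + beta * l_TV + gamma * l_AD
```

- `l_MSE`: mean squared difference between generated and target
  patches — the workhorse term.
- `l_VGG`: mean squared difference between feature representations of
  both patches under a fixed extractor. The package default is a
  fixed-seed random-convolution stack
  (`feature_extractor_random()`): random convolutional features are a
  standard training-free perceptual feature map, fully deterministic
  and self-contained; the identity extractor reduces this term exactly
  to `l_MSE` and is used as an algebraic test.
- `l_TV = 2*psi*(hTV + wTV)/F`: squared first differences along rows
  and columns (normalized by `C*(H-1)*W` and `C*H*(W-1)`), suppressing
  high-frequency speckle.
- `l_AD = 1 - mean(D(generated))`: the adversarial term.

Weights `alpha = 0.006`, `beta = 2e-8` (with `psi = 1`), and
`gamma = 0.001` are the conventional magnitudes used by
super-resolution GANs for these three auxiliary terms; they are
config-exposed, not hard-coded. Since `beta` and `psi` both scale the
TV term, they are redundant in effect; both are exposed because they
enter the formula at different places. The discriminator minimizes
`BCE(real, 1) + BCE(fake, 0)` with probabilities clipped at `1e-7`
before logarithms.

**Training.** Per step, one discriminator update is followed by one
generator update (1:1 schedule), both with Adam
(`learning_rate = 1e-4` at full scale, betas 0.9/0.999). Validation
SSIM is computed each epoch on assembled enhanced validation maps, and
the checkpoint keeps the epoch with the best value — validation data
is used for model selection, nothing else. All-zero target patches
are *kept* by default: single-cell maps are mostly zeros, and dropping
empty patches would bias the model toward dense regions
(`train_config(drop_empty_patches = TRUE)` reverses this). One model
is trained per down-sampling ratio.

## Data pipeline

- **Down-sampling** draws `Binomial(c, r)` per upper-triangle count —
  exactly the distribution of keeping each read pair independently
  with probability `r`. It preserves symmetry and integrality, is
  mass-decreasing, and `r = 1` is the identity.
- **Normalization** clips at the 99.9th percentile of the non-zero
  entries (R's default `type = 7` quantile interpolation; never below
  1) and divides by that cap, storing the cap for inversion. The cap
  is fitted once on the pooled training HR maps and shared by every
  map in a run; the checkpoint records it. The exact reference
  preprocessing this emulates is only loosely specified upstream, so
  the percentile rule is our documented choice: it gives bounded
  [0, 1] inputs, is robust to single hot pixels, and inverts exactly
  below the cap.
- **Patching** anchors `patch_size × patch_size` tiles at multiples of
  `stride` (row-major), zero-padding edge tiles. Training uses
  `stride = patch_size` (non-overlapping); inference may use a smaller
  stride, and overlapping predictions are averaged per cell. An
  optional `band_bins` filter keeps only near-diagonal tiles for long
  chromosomes. Assembly trims the padding, averages overlaps,
  symmetrizes by `(M + t(M))/2`, and is the exact inverse of cropping
  at `stride = patch_size`. Negative network outputs survive assembly
  and are clamped to zero when the normalization is inverted.
- **I/O**: single-resolution cooler files (HDF5 layout with
  `chroms/bins/pixels/indexes`, upper-triangle pixels, 0-based
  half-open bins) via rhdf5, and a plain triplet-text format
  (`#chrom/#resolution/#nbins` header plus `bin_i bin_j count` lines)
  for anything human-readable. Stored triangles are mirrored, not
  averaged, because cooler stores the upper triangle only. Raw counts
  are used as stored; balancing weights are out of scope.

## Synthetic data: what it emulates and what it does not

`simulate_intensity()` builds an expected contact surface from three
ingredients observed in real maps: power-law distance decay
`(|i−j|+1)^−d`, block-wise TAD enrichment, and point loops with a
one-bin halo whose excess over baseline halves at Chebyshev distance
one (a width-one loop would vanish at 40 kb sparsity). The surface is
normalized over the upper triangle and `sample_reads()` draws integer
counts multinomially, so total coverage is exact and cell-to-cell
variability comes only from sampling noise. The diagonal is included
in the sampling support (real single-cell maps carry self-ligation
counts); `include_diagonal = FALSE` removes it.

Reference conditions used by the benchmark and the tests: 200 bins
(8 Mb at 40 kb), decay exponent 1.0, TAD boundaries at bins
40/80/120/160 with enrichment 3, loops at (30, 70) and (110, 150) with
strength 5, and 2e5 read pairs per cell — numbers chosen once to give
single-cell-like sparsity (~5 reads per retained cell at ratio 0.1)
while remaining CPU-friendly.

What the generator does *not* model: inter-chromosomal contacts, A/B
compartments, cell-cycle structure, distance-dependent noise
correlations, or any biological cell-to-cell heterogeneity beyond
resampling. Passing the end-to-end benchmark therefore shows the
implementation learns and transfers the planted structure under
realistic sparsity; it is not evidence about performance on real GEO
data, which requires full-scale training.

## Evaluation conventions

- **PSNR** uses peak 1 on [0, 1]-normalized maps, i.e.
  `−10·log10(MSE)`. This convention reproduces published
  PSNR↔MSE pairings for this task within their printed rounding
  (plus a small allowance because published rows average several
  chromosomes); the test suite carries that consistency check with
  the published table as a fixture.
- **SSIM** uses the standard Gaussian window (11 bins, sigma 1.5) and
  constants `C1 = 0.01²`, `C2 = 0.03²`; local moments come from the
  same convolution engine as the networks and are checked against a
  direct per-window oracle.
- **SNR** is `sum(target) / ||x − target||` (Euclidean norm of the
  residual). The superscript in the usual formula is typographically
  ambiguous; the squared-denominator reading is exposed via
  `squared_denominator = TRUE`.
- **Insulation score**: mean of the `w × w` square crossing the
  diagonal at each bin, normalized as `log2(raw / chromosome mean)` —
  standard insulation practice; minima mark TAD boundaries. Bins
  within `w` of either end or with empty windows are masked. Profiles
  are compared by the L2 norm over jointly valid bins. The window
  defaults to 10 bins (400 kb at 40 kb), a common TAD-scale choice.
- **Concordance**: both maps are row-normalized to random-walk
  transition matrices, raised to the `t`-th power (default `t = 3`),
  rescaled to unit mass and compared by `1 − L1/2`. This is
  a GenomeDISCO-style score — the same random-walk smoothing idea —
  but not bit-compatible with the released tool.

## Numerical choices and degenerate inputs

- Convolutions are exact im2col + BLAS matrix products
  (RcppArmadillo); forward/backward passes are verified against naive
  loops and central finite differences in the test suite.
- Batch normalization uses biased variance and `eps = 1e-5`; BCE
  probabilities are clipped at `1e-7`.
- Weight initialisation is He-normal, deterministic given the seed;
  every stochastic step (simulation, thinning, initialisation, batch
  shuffling) goes through seeds derived from one master seed, so runs
  are bitwise reproducible on one CPU thread.
- All-zero maps: `fit_scale` falls back to cap 1 with a warning;
  `concordance_score` refuses all-zero inputs (no walk exists);
  `sample_reads(…, 0)` returns an all-zero map.
- Equal maps: PSNR and SNR return `Inf` as the documented sentinel.
- Non-finite training losses abort with the offending step rather than
  silently diverging.

## Problem sizes

The shipped benchmark (`synthetic_benchmark()`, also driven by
`scripts/acceptance.R`) trains the reduced configuration — 2 residual
blocks, 16 feature channels, discriminator stem 16, batch 16, 10
epochs = 460 generator steps — on 30 synthetic cells and evaluates 10
held-out cells. These sizes were chosen as the smallest configuration
at which the adversarially trained model consistently beats the
down-sampled baseline on SSIM, PSNR and insulation L2; the run takes
about five minutes on a single CPU. The full-scale configuration (32
blocks, 256 channels) is exercised structurally (parameter counts,
shapes) but not trained in the test suite.

## Known limitations

- The perceptual term uses random convolutional features, not learned
  ones; with `alpha` at its small default this mostly acts as a
  multi-scale smoothness prior.
- The random-walk concordance of enhanced maps can score marginally
  below the raw down-sampled baseline even when image metrics and TAD
  recovery improve: thinning is unbiased, so after row-normalization
  and smoothing the sparse map is already close to the target in L1,
  while the generator's slight over-smoothing costs a little mass
  placement accuracy. The benchmark reports both numbers.
- Training is single-threaded CPU; full-scale (32-block, 256-channel)
  training of real chromosomes is out of reach here and unconfigured.
- No ICE/KR balancing, no multi-resolution cooler output, no
  inter-chromosomal contacts.
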