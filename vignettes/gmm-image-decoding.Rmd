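---
title: "Decoding perceived images with Gaussian mixture priors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding perceived images with Gaussian mixture priors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gmmdecode` reconstructs viewed images from per-trial brain response vectors
by inverting a linear Gaussian encoding model under a Gaussian-mixture image
prior, optionally steering the mixture weights with category probabilities
decoded from a second, higher-level response set ("semantic gating"). This
vignette is the package's own account of the model, the choices made where
the design was genuinely open, and what the synthetic test bed does and does
not establish.

## 1. The generative model

For an image `x` (a length-`p` pixel vector, row-major flattening of an
`H × W` grid) and a response vector `y` over `q` voxels:

* **Likelihood.** `y = B'x + ε`, `ε ~ N(0, Σ)`, `Σ = diag(σ²₁, …, σ²_q)`.
  The mapping is assumed context-independent: the same `B` for every
  category.
* **Prior.** `P(x) = Σ_c π_c N(x; m_c, R_c)` over `C` mixture components,
  each representing a semantic category or a data-driven cluster.

Both factors are Gaussian in `x`, so the cluster-conditional posterior is
Gaussian with closed-form moments. Writing `D = BΣ⁻¹B'`,
`U_c = (I + R_cD)⁻¹`, `Q_c = U_cR_c`, `f̄(y) = BΣ⁻¹y`:

* posterior mean: `n_c(y) = Q_c f̄(y) + U_c m_c`;
* responsibility: `log P(c|y) = log π_c + ½ log det U_c + ½ f̄'Q_c f̄ −
  ½ m_c'DU_c m_c + f̄'U_c m_c + const`, with the constant removed by
  log-sum-exp normalization;
* reconstruction: `x*(y) = Σ_c w_c(y) n_c(y)`, `w_c ∝ P(c|y)^{1/T}`.

Two structural points are worth emphasizing. First, `R_c` is **never
inverted**: component covariances are `1/N_c` moment estimates of image sets
whose size can be far below `p`, so they are routinely singular, and the
`U_c`/`Q_c` formulation keeps them admissible. (The push-through identity
`(I + RD)⁻¹R = R(I + DR)⁻¹` guarantees the same posterior as the
information form whenever `R_c` happens to be invertible; the test suite
checks both.) Second, the temperature: `T = 1` gives the standard
responsibility-weighted average; as `T → 0` the reconstruction is the
posterior mean of the single most probable cluster. **Hard assignment is the
default** because category-conditional means are sharp while
responsibility-weighted averages blur competing categories together; the
tempered variant remains available through `temperature =`.

## 2. Fitting the encoding model

Per voxel, `β̂ᵢ` minimizes the l2-penalized least squares loss, i.e.
`β̂ᵢ = (X'X + λᵢI)⁻¹X'yᵢ` (Tikhonov form; the penalty is not scaled by the
trial count). All grid solutions come from one SVD of `X`:
`β̂(λ) = V diag(dⱼ/(d²ⱼ + λ)) U'y`.

Choices that were open and how they were settled:

* **Penalty grid.** `L = 30` penalties whose effective degrees of freedom
  `df(λ) = Σⱼ d²ⱼ/(d²ⱼ + λ)` are evenly spaced on `[rank(X)/L, rank(X)]`.
  Each `λ` is found by monotone bisection to `|df − target| < 1e-6`.
  Singular values below `max(d)·1e-12` count as zero for the rank.
* **Cross-validation.** `K = 5` folds, stratified by stimulus category when
  labels are available (per-fold label counts within one of exact
  proportionality), plain shuffled folds otherwise; the partition is seeded
  and shared between penalty selection and noise estimation. `λ̂ᵢ` minimizes
  the variance of the held-out residuals concatenated across folds, with
  ties broken toward the **larger** penalty (more regularization).
* **Variance estimator.** "Variance" of the concatenated residual vector is
  the population variance after removing its mean. Mean-centered rather than
  raw second moments because a systematic offset in held-out predictions is
  bias, not noise; population (divide by count) rather than `n − 1` because
  the residual vector is a concatenation, not a sample of independent
  replicates.
* **Response standardization.** Responses are z-scored per voxel with
  training-set moments *inside* `fit_encoding_model()`; the same affine
  transform is stored on the model and applied to test responses at decode
  time. The voxel filter `σ̂²ᵢ ≤ 0.99` only makes sense on unit-variance
  responses: a voxel whose cross-validated residual variance is
  indistinguishable from its total variance carries no stimulus information.
  The threshold is configurable (`voxel_variance_threshold`); an empty
  selection is an error instructing the user to relax it.
* `σ̂²ᵢ` below machine epsilon (noiseless fits) is floored at machine
  epsilon with a warning, keeping `Σ⁻¹` finite.

## 3. Building the prior

All prior images are normalized before moments are taken: one global
min-max rescale to `[0, 1]` over the whole set, then each image scaled to
unit Euclidean norm. Among the plausible conventions (per-pixel z-scoring,
per-image min-max, …) the global-min-max + unit-norm combination was chosen
because it preserves relative contrast across images while removing
per-image energy differences, and it is idempotent. The min-max parameters
are stored and **the identical transform is applied to train and test
stimuli** — mixing normalization conventions between prior and stimuli
silently rescales `R_c` relative to `D` and biases the responsibilities.

* **Supervised.** One component per label; mean and `1/N_c` covariance of
  that label's images; `label_table` is the identity.
* **Unsupervised.** K-means (Euclidean, seeded k-means++ initialization,
  Lloyd iterations, best of 10 restarts by within-cluster sum of squares);
  `m_c` is the centroid, `R_c` the member covariance. Empty-cluster restarts
  are re-seeded; clusters that still end empty are dropped with a warning
  and the weights renormalized. Singleton or rank-zero components get
  `R_c = τI` with `τ = 1e-6 ×` the mean per-pixel variance, purely for
  log-determinant stability. The per-cluster label frequency table estimates
  `P(l|c)` and enables the category read-out
  `P(l|y) = Σ_c P(c|y)P(l|c)` for unsupervised decoding.
* **Weights.** `π_c = 1/C` by default for both constructions (the decoder is
  meant to infer the category from the response, not from prior imbalance);
  `weights = "empirical"` switches to `N_c/N`.

## 4. Semantic gating

`P(c|z)` is an over-parameterized multinomial logistic model (one weight
vector per class, no reference class), fit by maximizing
`(1/N) Σ log P(cⱼ|zⱼ) − λ Σ_k ‖γ_k‖₁` with coordinate descent (glmnet).
Intercepts are unpenalized — the l1 penalty resolves the softmax
identifiability for the weights, and intercepts are additionally reduced to
zero mean, which changes nothing observable. The penalty is chosen by
10-fold stratified cross-validation maximizing held-out log-likelihood on a
20-point grid log-spaced three decades down from the smallest
all-zero-weight penalty, ties toward the larger penalty. At decode time the
per-trial `log P(c|z)` simply replaces `log π_c` in the responsibility —
gating and the static prior weights are alternative values of the same term,
with no extra mixing parameter. Gating is intended for supervised category
priors; gating K-means clusters is possible through the same interface but
unsupervised splits are rarely balanced enough to estimate the logistic
model well.

## 5. Evaluation

* **SSIM** follows the standard windowed formulation: 11 × 11 Gaussian
  window (σ = 1.5), population window moments, `C1 = (0.01·d)²`,
  `C2 = (0.03·d)²` for data range `d`. Only fully interior windows
  contribute; images smaller than the window fall back to one uniform window
  over the whole image with a warning. The batch helper takes `d` from the
  range of the original images so reconstructions and originals share one
  scale. Identical images score exactly 1 (the numerator and denominator are
  computed so they are bit-identical in that case). Both the per-trial mean
  and the sum are reported — the sum grows with test-set size, so the mean
  is the comparable quantity across designs.
* **Classification** counts exact label matches; supervised decoding uses
  the winning component, unsupervised decoding the `P(l|y)` argmax. The
  uniform chance level is `1/n_categories` — e.g. 4% under an extended
  25-letter prior.
* **Baselines.** (i) Pixel baseline: ridge regression from standardized
  responses to mean-centered pixel values (an implicit intercept, so a
  totally uninformative response predicts the training mean image), with the
  same df-grid/CV machinery as the encoding model, roles swapped. (ii) Class
  baseline: the gating machinery applied to the low-level responses.

## 6. The synthetic test bed

`generate_dataset()` emulates the generative structure the decoder assumes,
at desk scale:

* **Images.** Up to eight deterministic binary glyph templates (bars, cross,
  diagonals, ring, square, checkerboard) on a 12 × 12 grid (`p = 144`);
  instances are toroidally shifted by ±1 pixel and perturbed with Gaussian
  pixel noise (sd 0.08), clipped to `[0, 1]`. Six categories, 200 prior
  images per category, 300 training and 60 test trials by default. Glyph
  pairs overlap partially (cross vs bars), giving realistic category
  confusability. Toroidal shifts keep image energy constant across
  instances.
* **Responses.** Normalization is estimated on the prior set, applied to
  train/test stimuli, and responses are simulated from the *normalized*
  images: `Y = XB + ε` with Gaussian receptive-field columns in `B` (width 2
  px, unit norm) and per-voxel noise sd set to `sd(signal)/2` — a per-voxel
  SNR of 2 (`response_snr`, overridable as an absolute sd via
  `response_noise`). Simulating in normalized space keeps the linear model
  exact in the space where decoding happens; per-image unit-norm scaling is
  not a global linear map, so simulating from raw pixels would introduce a
  model mismatch that is no part of what the decoder claims to handle.
* **Gating responses.** `z = snr·e(label) + N(0, I)` with fixed random class
  embeddings `e` (entries `N(0, 1/q')`, near-orthogonal in expectation);
  `gating_snr = 3` by default, 0 makes `z` uninformative.
* The gating comparison in the acceptance suite runs at `response_snr = 0.4`
  (ambiguous low-level responses) with `gating_snr = 3`, and a control at
  `gating_snr = 0`; these conditions were fixed as part of the study design.

**What passing tests show — and don't.** The simulator realizes exactly the
model class the decoder assumes: linear forward mapping, diagonal Gaussian
noise, category-structured image distribution. Success on it demonstrates
correct inference and implementation, not robustness to the ways real fMRI
deviates from the model: no hemodynamic dynamics or temporal autocorrelation,
no voxel-noise correlations, no nonlinearity, no retinotopic spatial
structure beyond random receptive fields, and glyphs are far more
homogeneous within category than handwriting. Real-data performance claims
require real data.

## 7. Numerical choices, in one place

* `U_c` via a factorized solve of `(I + R_cD)`; `log det U_c` from the
  (always positive for PSD `R_c`, `D`) determinant of the same matrix;
  `Q_c` symmetrized after the solve.
* All per-cluster matrices are cached once per decoder state; per-trial cost
  is `O(C·p²)`.
* Log responsibilities floored at −745 before exponentiation (the smallest
  exponent that survives `exp` in double precision).
* Argmax ties (responsibilities, predicted classes) break toward the lowest
  index, deterministically.
* Every stochastic step (fold shuffling, K-means initialization, simulator
  draws) takes an explicit integer seed and restores the caller's RNG state;
  fixed seed implies bit-identical models, priors and decodings.
* TSV interchange uses `%.17g`, which round-trips doubles exactly; model and
  prior payloads therefore live in TSV, with shapes/masks/configuration in
  JSON sidecars. Files index clusters and trials 0-based; in-memory R
  structures are 1-based as usual.
* Test-suite problem sizes: closed-form oracles run at `p ≤ 4`, `q ≤ 6`,
  `C ≤ 3` (100+ random instances); the quadrature cross-check at `p = 2` on
  a 321-point grid per axis; end-to-end checks on the default 12 × 12 /
  200-voxel bundle with 10 repeats where clustering or gating variability
  matters. A full-scale run (56 × 56 images, thousands of prior images) uses
  the same code paths; only the covariance algebra grows to `p × p = 3136²`.

## 8. Known limitations

* The decoder is exact only under the linear Gaussian likelihood; it has no
  mechanism for non-Gaussian noise or nonlinear encoding.
* Mixture components are moment-matched Gaussians; heavy-tailed or
  multi-modal within-category structure is approximated, and with very many
  clusters each component degenerates toward single prior exemplars.
* Unimodal (`C = 1`) decoding cannot produce category read-outs.
* The number of clusters `C` is not selected by the package; sweep it and
  compare (as `run_pipeline()` does).
* No posterior sampling or credible intervals — only means and component
  probabilities.
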