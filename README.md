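# gmmdecode

Bayesian reconstruction of perceived images from brain responses with a
Gaussian-mixture image prior and optional semantic gating.

## The problem

Given per-trial fMRI response vectors `y` recorded from a low-level visual
area while a subject views images `x` (e.g. handwritten characters), the goal
is to reconstruct the viewed image and to read out its semantic category.
`gmmdecode` implements a fully analytic hybrid Bayesian network for this
task:

- **Encoding model.** A linear Gaussian forward model per voxel,
  `y = B'x + ε`, `ε ~ N(0, Σ)` with `Σ = diag(σ²₁, …, σ²_q)`. Each voxel's
  weight vector is the ridge estimate `β̂ᵢ = (X'X + λᵢI)⁻¹X'yᵢ` (computed
  along the whole penalty path from one SVD). The penalty grid is placed by
  effective degrees of freedom `df(λ) = Σⱼ d²ⱼ/(d²ⱼ + λ)`, and per-voxel
  `λᵢ` and noise variance `σ̂²ᵢ` are chosen by stratified K-fold
  cross-validation of the held-out residual variance. On unit-variance
  responses, voxels with `σ̂²ᵢ ≤ 0.99` are kept for decoding.
- **Mixture prior.** `P(x) = Σ_c π_c N(x; m_c, R_c)`, with one component per
  category label (supervised) or per K-means cluster (unsupervised).
  Component moments are sample means and `1/N_c` covariances of the
  (normalized) prior images; singular `R_c` is fine because the decoder never
  inverts it.
- **Analytic inversion.** With `D = BΣ⁻¹B'`, `U_c = (I + R_cD)⁻¹`,
  `Q_c = U_cR_c` and `f̄(y) = BΣ⁻¹y`, the cluster-conditional posterior mean
  is `n_c(y) = Q_c f̄(y) + U_c m_c` and the cluster responsibility is

  ```
  log P(c|y) = log π_c + ½ log det U_c + ½ f̄'Q_c f̄ − ½ m_c'DU_c m_c + f̄'U_c m_c + const
  ```

  The reconstruction mixes `n_c(y)` with weights `∝ P(c|y)^{1/T}`; in the
  default hard mode (`T → 0`) it is the posterior mean of the most probable
  cluster.
- **Semantic gating.** Responses `z` from a higher-level area can replace the
  mixture weights: `P(c|z)` is an l1-penalized multinomial logistic model
  (penalty via 10-fold CV), and `log P(c|z)` substitutes `log π_c` above.
- **Evaluation.** Windowed SSIM (11×11 Gaussian, σ = 1.5) against the
  originals, classification accuracy (via cluster winners or the
  letter-probability read-out `P(l|y) = Σ_c P(c|y)P(l|c)`), chance levels,
  and two discriminative baselines: ridge regression straight from responses
  to pixels, and l1 multinomial logistic regression from responses to labels.

A seeded forward simulator (`generate_dataset()`) produces
category-structured glyph images, responses from a random receptive-field
forward model at a target per-voxel SNR, and category-informative gating
responses, so the entire pipeline runs and is tested end to end without any
external data.

## Worked example

```r
library(gmmdecode)

cfg <- run_config(
  synthetic    = synthetic_config(seed = 1),   # 6 glyph categories, 12x12 px,
  encoding     = encoding_config(seed = 1),    # 200 voxels, SNR 2
  unsupervised_C = c(2L, 6L, 20L), unsupervised_repeats = 3L,
  seed = 1)
res <- run_pipeline(cfg, verbose = FALSE)
print(res)
#>       variant  C ssim_mean  accuracy
#>      unimodal  1 0.8140404        NA
#>  unsupervised  2 0.8435555 0.3166667
#>         gated  6 0.9054076 1.0000000
#>    supervised  6 0.9054076 1.0000000
#>  unsupervised  6 0.9082399 0.8500000
#>  unsupervised 20 0.9795988 0.9055556
```

Reading the table: every multimodal variant reconstructs better (higher mean
SSIM over the 60 test trials) than the single-Gaussian *unimodal* prior, and
the gain grows as the prior is split more finely; at the true category count
(`C = 6`) the unsupervised K-means prior matches the supervised one. The
supervised decoder classifies all test trials correctly here, so gating the
categories from the higher-level responses cannot improve on it — the gating
advantage appears when the low-level responses are noisy (see the methods
vignette in `vignettes/`). Unimodal accuracy is `NA` by design: a
single-component prior carries no category information. Unsupervised
accuracy uses the `P(l|y)` read-out through each cluster's label frequencies.

Individual stages are exposed as ordinary functions
(`fit_encoding_model()`, `build_supervised_prior()`,
`build_unsupervised_prior()`, `fit_gating()`, `decode_batch()`,
`evaluate_reconstructions()`, …), and a thin command-line front end with the
same stages lives at `inst/cli/gmmdecode`
(`simulate`, `fit-encoding`, `build-prior`, `fit-gating`, `decode`,
`evaluate`, `run`).

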