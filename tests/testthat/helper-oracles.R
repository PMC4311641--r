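# Shared fixtures and independent oracle routines for the test suite.

# Random symmetric PSD matrix with controlled scale.
random_psd <- function(p, scale = 1, rank = p) {
  A <- matrix(rnorm(p * rank), p, rank)
  scale * tcrossprod(A) / rank
}

# Log density of N(x; mu, S) via Cholesky (independent of package code).
dmvnorm_log <- function(x, mu, S) {
  ch <- chol(S)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Random small decoding instance: encoding model over all-selected voxels
# plus a full-rank mixture prior, sized for closed-form oracles.
random_instance <- function(p, q, C, seed) {
  set.seed(seed)
  B <- matrix(rnorm(p * q), p, q)
  sigma2 <- runif(q, 0.3, 1.5)
  model <- structure(list(B = B, sigma2 = sigma2,
                          lambdas = rep(1, q),
                          selected = rep(TRUE, q),
                          center = rep(0, q), scale = rep(1, q),
                          grid = 1, folds = NULL, voxel_ids = paste0("v", 1:q),
                          grid_shape = c(1L, p),
                          config = encoding_config()),
                     class = "encoding_model")
  means <- matrix(rnorm(C * p), C, p)
  covs <- lapply(seq_len(C), function(i) random_psd(p, scale = runif(1, .5, 2)))
  w <- runif(C); w <- w / sum(w)
  prior <- structure(list(means = means, covariances = covs, weights = w,
                          label_table = NULL, normalization = NULL,
                          grid_shape = c(1L, p),
                          component_names = paste0("c", seq_len(C) - 1L)),
                     class = "mixture_prior")
  list(model = model, prior = prior,
       y = rnorm(q), B = B, sigma2 = sigma2)
}

# The default synthetic study bundle with its fitted encoding model, built
# once per test run and shared across files.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bundle <- generate_dataset(synthetic_config(seed = 7L))
      model <- fit_encoding_model(bundle$train_images, bundle$train_responses,
                                  encoding_config(seed = 7L))
      cache <<- list(bundle = bundle, model = model)
    }
    cache
  }
})
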