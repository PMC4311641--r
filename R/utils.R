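# Shared numerics and fold construction.

# log(sum(exp(x))) without overflow; -Inf entries are allowed.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Population variance of a vector after removing its mean.
var_pop <- function(x) {
  mean((x - mean(x))^2)
}

symmetrize <- function(m) (m + t(m)) / 2

#' Build a seeded K-fold partition of trials
#'
#' Trials are shuffled with the given seed and dealt into `n_folds` folds.
#' When `labels` are supplied the partition is stratified: each label's trials
#' are dealt separately so per-fold label counts stay within one of exact
#' proportionality.
#'
#' @param n Number of trials.
#' @param n_folds Number of folds (`>= 2`, `<= n`).
#' @param labels Optional length-`n` label vector for stratification.
#' @param seed Integer seed; the global RNG state is left untouched.
#'
#' @return Integer vector of length `n` with fold ids in `1..n_folds`.
#' @export
make_folds <- function(n, n_folds, labels = NULL, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n < n_folds) stop("need at least as many trials as folds")
  if (!is.null(labels) && length(labels) != n)
    stop("labels length does not match n")
  withr::with_seed(as.integer(seed), {
    fold <- integer(n)
    if (is.null(labels)) {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    } else {
      for (lv in unique(labels)) {
        idx <- which(labels == lv)
        # rotate the starting fold per stratum so small strata spread out
        start <- sample.int(n_folds, 1L)
        fold[idx[sample.int(length(idx))]] <-
          ((start - 1L + seq_along(idx) - 1L) %% n_folds) + 1L
      }
    }
    fold
  })
}

# Derive a stream of distinct sub-seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}
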