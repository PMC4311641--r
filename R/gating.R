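# Semantic gating: P(c|z) from higher-level-area responses by l1-penalized
# multinomial logistic regression (over-parameterized softmax, unpenalized
# intercepts constrained to zero mean). The fitted per-trial log P(c|z)
# replaces log pi_c in the decoder's responsibility computation.

new_gating_model <- function(intercepts, weights, penalty, class_order) {
  intercepts <- intercepts - mean(intercepts)   # softmax-invariant identifiability
  structure(list(intercepts = intercepts, weights = weights,
                 penalty = penalty, class_order = class_order),
            class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat("<gating_model> ", length(x$class_order), " classes, ",
      ncol(x$weights), " features, penalty = ", signif(x$penalty, 4),
      " (", sum(x$weights != 0), " nonzero weights)\n", sep = "")
  invisible(x)
}

#' Class probabilities from a gating model
#'
#' Softmax of `alpha_k + gamma_k' z`, computed through log-sum-exp.
#'
#' @param model A `gating_model`.
#' @param z Feature vector (length `q'`) or `N x q'` matrix.
#'
#' @return Simplex vector of length `K`, or `N x K` matrix.
#' @export
gating_probabilities <- function(model, z) {
  lw <- gated_log_weights(model, z)
  if (is.matrix(lw)) exp(lw) else exp(drop(lw))
}

#' Per-trial log gating probabilities
#'
#' Returns `log P(c|z)` for each trial, in the model's class order, suitable
#' for the `gating_log_weights` argument of [decode_batch()] (where it
#' replaces the mixture's `log pi_c`).
#'
#' @param model A `gating_model`.
#' @param z Feature vector or `N x q'` matrix.
#' @param prior Optional `mixture_prior`; when given, the model's class order
#'   must match the prior's component names.
#'
#' @return `N x K` matrix of log probabilities (or a length-`K` vector).
#' @export
gated_log_weights <- function(model, z, prior = NULL) {
  stopifnot(inherits(model, "gating_model"))
  single <- !is.matrix(z)
  Z <- if (single) matrix(z, 1) else as.matrix(z)
  if (ncol(Z) != ncol(model$weights))
    stop("z has ", ncol(Z), " features; model expects ", ncol(model$weights))
  if (!is.null(prior) &&
      !identical(as.character(model$class_order),
                 as.character(prior$component_names)))
    stop("gating class order does not match the prior's component order")
  eta <- sweep(Z %*% t(model$weights), 2, model$intercepts, "+")
  lw <- eta - apply(eta, 1, logsumexp)
  colnames(lw) <- model$class_order
  if (single) drop(lw) else lw
}

glmnet_multinomial <- function(Z, cl, lambda, maxit, thresh) {
  glmnet::glmnet(Z, cl, family = "multinomial", alpha = 1,
                 lambda = lambda, standardize = FALSE,
                 type.multinomial = "ungrouped",
                 maxit = maxit, thresh = thresh)
}

# Warm-start path descending into the target penalty.
path_into <- function(penalty) {
  if (penalty <= 0) return(NULL)
  sort(unique(penalty * 2^(8:0)), decreasing = TRUE)
}

#' Fit the semantic gating model
#'
#' Maximizes the l1-penalized multinomial log-likelihood
#' `(1/N) sum_j log P(c_j | z_j) - penalty * sum_k ||gamma_k||_1`
#' (intercepts unpenalized) by coordinate descent (glmnet). For a large
#' enough penalty all weights are exactly zero and the fitted probabilities
#' are the empirical class frequencies.
#'
#' @param Z `N x q'` matrix of higher-level responses.
#' @param classes Length-`N` class labels (at least two classes).
#' @param penalty Nonnegative l1 penalty.
#' @param max_iter Coordinate-descent iteration cap (default `1e5`).
#' @param tol Convergence threshold on the objective (default `1e-9`).
#'
#' @return A `gating_model`.
#' @export
fit_gating <- function(Z, classes, penalty, max_iter = 1e5, tol = 1e-9) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("Z contains non-finite values")
  cl <- factor(classes)
  if (nlevels(cl) < 2L) stop("need at least two classes")
  if (penalty < 0) stop("penalty must be nonnegative")
  lam <- path_into(penalty)
  fit <- if (is.null(lam)) {
    glmnet_multinomial(Z, cl, lambda = c(1e-3, 0), maxit = max_iter,
                       thresh = tol)
  } else {
    glmnet_multinomial(Z, cl, lambda = lam, maxit = max_iter, thresh = tol)
  }
  co <- stats::coef(fit, s = penalty, exact = FALSE)
  K <- nlevels(cl)
  qz <- ncol(Z)
  intercepts <- vapply(co, function(m) m[1, 1], numeric(1))
  weights <- t(vapply(co, function(m) as.numeric(m[-1, 1]), numeric(qz)))
  new_gating_model(intercepts, weights, penalty, levels(cl))
}

#' Penalized gating objective
#'
#' The quantity [fit_gating()] maximizes, evaluated at a given model:
#' mean log-likelihood minus `penalty` times the l1 norm of the weights.
#'
#' @param model A `gating_model`.
#' @param Z Feature matrix.
#' @param classes True class labels.
#' @param penalty Penalty at which to evaluate; defaults to the model's.
#'
#' @return Scalar objective value.
#' @export
gating_objective <- function(model, Z, classes, penalty = model$penalty) {
  lw <- gated_log_weights(model, as.matrix(Z))
  ll <- mean(lw[cbind(seq_len(nrow(lw)),
                      match(as.character(classes), model$class_order))])
  ll - penalty * sum(abs(model$weights))
}

#' Default l1 penalty grid for gating
#'
#' 20 points log-spaced over three decades down from the smallest penalty
#' that zeroes all weights (glmnet's `lambda_max`).
#'
#' @param Z Feature matrix.
#' @param classes Class labels.
#' @param n_points,decades Grid size and span.
#'
#' @return Decreasing penalty vector.
#' @export
gating_penalty_grid <- function(Z, classes, n_points = 20L, decades = 3) {
  cl <- factor(classes)
  lmax <- glmnet_multinomial(as.matrix(Z), cl, lambda = NULL,
                             maxit = 1e4, thresh = 1e-5)$lambda[1]
  10^seq(log10(lmax), log10(lmax) - decades, length.out = n_points)
}

#' Select the gating penalty by cross-validation
#'
#' K-fold (default 10) cross-validation maximizing the mean held-out
#' log-likelihood; ties are broken toward the larger penalty. Folds are
#' stratified by class.
#'
#' @param Z Feature matrix.
#' @param classes Class labels.
#' @param n_folds Number of folds (default 10).
#' @param penalty_grid Decreasing penalty vector; default
#'   [gating_penalty_grid()].
#' @param seed Seed for the fold partition.
#'
#' @return List with `penalty` (selected value) and `cv_loglik` (mean held-out
#'   log-likelihood per grid point).
#' @export
select_gating_penalty <- function(Z, classes, n_folds = 10L,
                                  penalty_grid = NULL, seed = 1L) {
  Z <- as.matrix(Z)
  cl <- factor(classes)
  N <- nrow(Z)
  if (N < n_folds) stop("need at least n_folds trials")
  if (is.null(penalty_grid)) penalty_grid <- gating_penalty_grid(Z, classes)
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)
  folds <- make_folds(N, n_folds, labels = as.character(cl), seed = seed)
  ll <- matrix(NA_real_, N, length(penalty_grid))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    fit <- glmnet_multinomial(Z[tr, , drop = FALSE], cl[tr],
                              lambda = penalty_grid, maxit = 1e5, thresh = 1e-8)
    pr <- predict(fit, Z[!tr, , drop = FALSE], s = penalty_grid,
                  type = "response")
    # pr: n_test x K x |grid|
    ci <- as.integer(cl[!tr])
    for (j in seq_along(penalty_grid)) {
      pj <- pr[, , j, drop = TRUE]
      pj <- matrix(pj, ncol = nlevels(cl))
      ll[!tr, j] <- log(pmax(pj[cbind(seq_len(nrow(pj)), ci)], 1e-300))
    }
  }
  mean_ll <- colMeans(ll)
  best <- min(which(mean_ll == max(mean_ll)))   # grid is decreasing: min index
  list(penalty = penalty_grid[best], cv_loglik = mean_ll,
       penalty_grid = penalty_grid)
}

#' Predicted classes from a gating model
#'
#' @param model A `gating_model`.
#' @param Z Feature matrix.
#'
#' @return Character vector of predicted class labels (argmax probability).
#' @export
predict_gating_classes <- function(model, Z) {
  lw <- gated_log_weights(model, as.matrix(Z))
  model$class_order[max.col(lw, ties.method = "first")]
}
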