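# Linear Gaussian encoding model: per-voxel ridge regression from pixels to
# responses, with the penalty grid placed by effective degrees of freedom and
# penalty/noise-variance selection by K-fold cross-validation.

#' Encoding model configuration
#'
#' @param n_folds Folds for cross-validated penalty selection (default 5).
#' @param grid_size Number of penalties on the effective-degrees-of-freedom
#'   grid (default 30).
#' @param voxel_variance_threshold Keep voxels whose cross-validated residual
#'   variance (on unit-variance responses) is at most this value; default 0.99.
#' @param seed Integer seed controlling the fold partition.
#'
#' @return A list of class `encoding_config`.
#' @export
encoding_config <- function(n_folds = 5L, grid_size = 30L,
                            voxel_variance_threshold = 0.99, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (grid_size < 2L) stop("grid_size must be >= 2")
  if (voxel_variance_threshold <= 0 || voxel_variance_threshold > 1)
    stop("voxel_variance_threshold must be in (0, 1]")
  structure(list(n_folds = as.integer(n_folds),
                 grid_size = as.integer(grid_size),
                 voxel_variance_threshold = voxel_variance_threshold,
                 seed = as.integer(seed)),
            class = "encoding_config")
}

check_design <- function(X, y = NULL) {
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  if (!is.null(y)) {
    if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
    if (!all(is.finite(y))) stop("response contains non-finite values")
  }
  invisible(TRUE)
}

#' Ridge regression solution for one response
#'
#' Solves `(X'X + lam I) beta = X'y` exactly. With `lam = 0` the normal
#' equations must be nonsingular.
#'
#' @param X Design matrix (`N x p`).
#' @param y Response vector of length `N`.
#' @param lam Nonnegative penalty.
#'
#' @return Coefficient vector of length `p`.
#' @export
fit_ridge <- function(X, y, lam) {
  X <- as.matrix(X)
  check_design(X, y)
  if (!is.finite(lam) || lam < 0) stop("lam must be a nonnegative number")
  if (lam == 0 && qr(X)$rank < ncol(X))
    stop("normal equations are singular at lam = 0; use a positive penalty")
  A <- crossprod(X)
  diag(A) <- diag(A) + lam
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop("normal equations are singular at lam = ", lam,
         "; use a positive penalty")
  drop(backsolve(ch, backsolve(ch, crossprod(X, y), transpose = TRUE)))
}

# Shrinkage factors d/(d^2 + lam); zero singular values contribute nothing
# (min-norm convention), but a zero singular value with lam = 0 means a
# singular system, checked by callers that promise fit_ridge semantics.
svd_shrink <- function(d, lam) {
  s <- numeric(length(d))
  nz <- d > 0
  s[nz] <- d[nz] / (d[nz]^2 + lam)
  s
}

#' Ridge solutions along a penalty grid via one SVD
#'
#' Computes `fit_ridge(X, y, lam)` for every `lam` in `grid` from a single
#' singular value decomposition of `X`.
#'
#' @param X Design matrix (`N x p`).
#' @param y Response vector of length `N`.
#' @param grid Nonempty vector of nonnegative penalties.
#'
#' @return `p x length(grid)` matrix; column `j` is the solution at `grid[j]`.
#' @export
fit_ridge_svd_path <- function(X, y, grid) {
  X <- as.matrix(X)
  check_design(X, y)
  if (length(grid) == 0L) stop("penalty grid is empty")
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("penalties must be finite and nonnegative")
  sv <- svd(X)
  tol <- max(sv$d) * 1e-12
  if (any(grid == 0) && any(sv$d <= tol))
    stop("normal equations are singular at lam = 0; use a positive penalty")
  uty <- crossprod(sv$u, y)
  vapply(grid, function(lam) drop(sv$v %*% (svd_shrink(sv$d, lam) * uty)),
         numeric(ncol(X)))
}

ridge_df <- function(d2, lam) sum(d2 / (d2 + lam))

#' Penalty grid placed by effective degrees of freedom
#'
#' Returns `L` penalties whose effective degrees of freedom
#' `df(lam) = sum_j d_j^2 / (d_j^2 + lam)` (with `d_j` the singular values of
#' `X`) are evenly spaced between `rank(X)` and `rank(X)/L`. Each penalty is
#' located by monotone bisection to `|df - target| < 1e-6`.
#'
#' @param X Design matrix with at least one nonzero singular value.
#' @param L Number of grid points (`>= 1`).
#'
#' @return Increasing vector of `L` nonnegative penalties.
#' @export
make_lambda_grid <- function(X, L) {
  X <- as.matrix(X)
  check_design(X)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  d <- svd(X, nu = 0, nv = 0)$d
  tol <- max(d) * 1e-12
  d2 <- d[d > tol]^2
  if (length(d2) == 0L) stop("X has no nonzero singular value")
  r <- length(d2)
  targets <- seq(r, r / L, length.out = L)
  lams <- vapply(targets, function(tg) {
    if (abs(tg - r) < 1e-9) return(0)
    lo <- 0
    hi <- 1
    while (ridge_df(d2, hi) > tg) hi <- hi * 2
    repeat {
      mid <- (lo + hi) / 2
      f <- ridge_df(d2, mid)
      if (abs(f - tg) < 1e-6 || (hi - lo) < 1e-12 * max(1, hi)) return(mid)
      if (f > tg) lo <- mid else hi <- mid
    }
  }, numeric(1))
  lams
}

# Held-out residuals for every grid penalty: one SVD per fold, all penalties
# and (optionally) many responses at once. Y is N x q; returns an N x q x L
# array of cross-validated residuals in original trial order.
cv_residuals <- function(X, Y, grid, folds) {
  N <- nrow(X)
  q <- ncol(Y)
  L <- length(grid)
  res <- array(NA_real_, c(N, q, L))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    te <- folds == k
    if (!any(te) || !any(tr)) stop("fold ", k, " has no trials")
    sv <- svd(X[tr, , drop = FALSE])
    uty <- crossprod(sv$u, Y[tr, , drop = FALSE])
    Xte <- X[te, , drop = FALSE]
    for (j in seq_len(L)) {
      B <- sv$v %*% (svd_shrink(sv$d, grid[j]) * uty)
      res[te, , j] <- Y[te, , drop = FALSE] - Xte %*% B
    }
  }
  res
}

#' Select a ridge penalty by cross-validated residual variance
#'
#' For each penalty in `grid`, fits on each fold's complement, collects the
#' held-out residuals across all folds, and returns the penalty minimizing the
#' population variance of the concatenated residual vector. Ties are broken
#' toward the larger penalty.
#'
#' @param X Design matrix (`N x p`).
#' @param y Response vector of length `N`.
#' @param grid Increasing vector of nonnegative penalties.
#' @param n_folds Number of folds.
#' @param seed Seed for the fold partition.
#' @param folds Optional precomputed fold ids (overrides `n_folds`/`seed`).
#'
#' @return List with `lambda` (selected penalty), `cv_variance` (per-grid-point
#'   residual variance) and `residuals` (`N x length(grid)` matrix of held-out
#'   residuals in trial order).
#' @export
select_lambda <- function(X, y, grid, n_folds = 5L, seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  check_design(X, y)
  if (is.null(folds)) folds <- make_folds(nrow(X), n_folds, seed = seed)
  res <- cv_residuals(X, cbind(y), grid, folds)[, 1, , drop = TRUE]
  res <- matrix(res, nrow = nrow(X))
  v <- apply(res, 2, var_pop)
  idx <- max(which(v == min(v)))
  list(lambda = grid[idx], cv_variance = v, residuals = res)
}

#' Cross-validated noise variance at a chosen penalty
#'
#' Variance of the concatenated held-out residuals at `lambda_hat`, using the
#' same fold partition (same seed) as the penalty selection.
#'
#' @inheritParams select_lambda
#' @param lambda_hat The selected penalty.
#'
#' @return Positive scalar; identically-constant residuals are floored at
#'   machine epsilon with a warning.
#' @export
estimate_noise <- function(X, y, lambda_hat, n_folds = 5L, seed = 1L,
                           folds = NULL) {
  X <- as.matrix(X)
  check_design(X, y)
  if (is.null(folds)) folds <- make_folds(nrow(X), n_folds, seed = seed)
  res <- cv_residuals(X, cbind(y), lambda_hat, folds)[, 1, 1]
  v <- var_pop(res)
  if (v < .Machine$double.eps) {
    warning("cross-validated residuals have (near-)zero variance; ",
            "flooring at machine epsilon")
    v <- .Machine$double.eps
  }
  v
}

#' Informative-voxel mask from noise variances
#'
#' @param sigma2 Estimated per-voxel noise variances (finite).
#' @param threshold Inclusive upper bound; voxels with `sigma2 <= threshold`
#'   are kept.
#'
#' @return Logical mask. Errors if no voxel survives.
#' @export
select_voxels <- function(sigma2, threshold) {
  if (any(!is.finite(sigma2))) stop("sigma2 contains non-finite values")
  mask <- sigma2 <= threshold
  if (!any(mask))
    stop("no voxel has sigma2 <= ", threshold,
         "; relax voxel_variance_threshold")
  mask
}

#' Fit the per-voxel ridge encoding model
#'
#' Responses are standardized per voxel (training mean 0, variance 1) and,
#' for each voxel, a penalty is chosen on an effective-degrees-of-freedom
#' grid by K-fold cross-validated residual variance; the cross-validated
#' variance at the chosen penalty is the voxel's noise variance, and voxels
#' with noise variance above `voxel_variance_threshold` are flagged
#' uninformative. Folds are stratified by image category when labels exist.
#'
#' @param train_images An [image_set()] (typically normalized, see
#'   [normalize_images()]).
#' @param train_responses A [response_set()] paired with `train_images`.
#' @param cfg An [encoding_config()].
#'
#' @return An object of class `encoding_model` with elements `B` (`p x q`
#'   coefficients on standardized responses), `sigma2`, `lambdas`, `selected`,
#'   the standardization `center`/`scale`, the penalty `grid`, `folds`,
#'   `grid_shape` and `config`.
#' @export
fit_encoding_model <- function(train_images, train_responses, cfg = encoding_config()) {
  stopifnot(inherits(train_images, "image_set"),
            inherits(train_responses, "response_set"))
  check_paired(train_images, train_responses)
  X <- train_images$data
  Y <- train_responses$data
  N <- nrow(X)
  q <- ncol(Y)

  center <- colMeans(Y)
  scale <- apply(Y, 2, stats::sd)
  if (any(scale == 0))
    stop("voxel(s) with zero response variance: ",
         paste(which(scale == 0)[1:min(5, sum(scale == 0))], collapse = ", "))
  Ys <- sweep(sweep(Y, 2, center), 2, scale, "/")

  folds <- make_folds(N, cfg$n_folds, labels = train_images$labels,
                      seed = cfg$seed)
  grid <- make_lambda_grid(X, cfg$grid_size)

  res <- cv_residuals(X, Ys, grid, folds)
  V <- matrix(NA_real_, q, length(grid))
  for (j in seq_along(grid)) {
    R <- res[, , j, drop = TRUE]
    R <- matrix(R, nrow = N)
    V[, j] <- colMeans(R^2) - colMeans(R)^2
  }
  idx <- vapply(seq_len(q), function(i) {
    vi <- V[i, ]
    max(which(vi == min(vi)))
  }, integer(1))
  lambdas <- grid[idx]
  sigma2 <- V[cbind(seq_len(q), idx)]
  floored <- sigma2 < .Machine$double.eps
  if (any(floored)) {
    warning(sum(floored), " voxel(s) with (near-)zero residual variance ",
            "floored at machine epsilon")
    sigma2[floored] <- .Machine$double.eps
  }

  sv <- svd(X)
  uty <- crossprod(sv$u, Ys)
  B <- matrix(0, ncol(X), q)
  for (j in unique(idx)) {
    cols <- which(idx == j)
    B[, cols] <- sv$v %*% (svd_shrink(sv$d, grid[j]) * uty[, cols, drop = FALSE])
  }

  selected <- select_voxels(sigma2, cfg$voxel_variance_threshold)
  structure(list(B = B, sigma2 = sigma2, lambdas = lambdas,
                 selected = selected, center = center, scale = scale,
                 grid = grid, folds = folds,
                 voxel_ids = train_responses$voxel_ids,
                 grid_shape = train_images$grid_shape, config = cfg),
            class = "encoding_model")
}

#' Apply the stored per-voxel standardization to responses
#'
#' @param model An `encoding_model`.
#' @param responses A [response_set()] or plain matrix over the same voxels
#'   (all `q`, in training order).
#'
#' @return Standardized numeric matrix.
#' @export
standardize_responses <- function(model, responses) {
  Y <- if (inherits(responses, "response_set")) responses$data else as.matrix(responses)
  if (ncol(Y) != length(model$center))
    stop("response set has ", ncol(Y), " voxels; model expects ",
         length(model$center))
  sweep(sweep(Y, 2, model$center), 2, model$scale, "/")
}

#' @export
print.encoding_model <- function(x, ...) {
  cat("<encoding_model> p = ", nrow(x$B), " pixels, q = ", ncol(x$B),
      " voxels (", sum(x$selected), " selected), ",
      length(x$grid), "-point penalty grid, ", x$config$n_folds,
      "-fold CV\n", sep = "")
  invisible(x)
}
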