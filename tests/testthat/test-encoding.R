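test_that("fit_ridge solves the penalized least-squares problem exactly", {
  set.seed(1)
  # orthonormal design, no penalty: projection identity
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  y <- rnorm(6)
  expect_equal(fit_ridge(Q, y, 0), drop(crossprod(Q, y)), tolerance = 1e-12)
  # zero response -> zero coefficients at any penalty
  expect_equal(fit_ridge(Q, rep(0, 6), 2.7), rep(0, 3))
  # random problem vs normal-equations oracle via a generic solver
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  beta <- fit_ridge(X, y, 0.5)
  oracle <- solve(crossprod(X) + 0.5 * diag(3), crossprod(X, y))
  expect_lt(max(abs(beta - drop(oracle))), 1e-10)
})

test_that("fit_ridge rejects singular and invalid inputs", {
  X <- cbind(1:4, (1:4) * 2)        # rank 1
  expect_error(fit_ridge(X, rnorm(4), 0), "singular")
  expect_silent(fit_ridge(X, rnorm(4), 0.1))
  expect_error(fit_ridge(matrix(c(1, NA, 1, 2), 2), rnorm(2), 1), "finite")
  expect_error(fit_ridge(matrix(rnorm(4), 2), rnorm(2), -1), "nonnegative")
})

test_that("SVD penalty path equals direct solves across random problems", {
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(rnorm(32), 8, 4)
    y <- rnorm(8)
    grid <- c(0.01, 0.1, 0.1, 1, 10)   # includes a duplicate
    path <- fit_ridge_svd_path(X, y, grid)
    direct <- vapply(grid, function(l) fit_ridge(X, y, l), numeric(4))
    expect_lt(max(abs(path - direct)), 1e-8)
    expect_identical(path[, 2], path[, 3])   # duplicate penalties
  }
  X <- matrix(rnorm(32), 8, 4)
  y <- rnorm(8)
  expect_equal(drop(fit_ridge_svd_path(X, y, 0.7)), fit_ridge(X, y, 0.7),
               tolerance = 1e-10)
})

test_that("ridge shrinkage is monotone in the penalty", {
  set.seed(3)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  grid <- c(0, 0.5, 2, 10, 100)
  norms <- apply(fit_ridge_svd_path(X, y, grid), 2, function(b) sqrt(sum(b^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("lambda grid hits evenly spaced effective degrees of freedom", {
  set.seed(4)
  # identity-like design: df(lambda) = p/(1+lambda), closed form
  X <- diag(5)
  lam <- make_lambda_grid(X, 4)
  targets <- seq(5, 5 / 4, length.out = 4)
  expect_equal(lam, 5 / targets - 1, tolerance = 1e-5)
  expect_equal(make_lambda_grid(X, 1), 0)   # df = rank at lambda = 0
  # random design vs dense lambda-scan oracle
  X <- matrix(rnorm(40), 10, 4)
  d2 <- svd(X)$d^2
  df_of <- function(l) sum(d2 / (d2 + l))
  lam <- make_lambda_grid(X, 4)
  targets <- seq(4, 1, length.out = 4)
  coarse <- 10^seq(-6, 6, length.out = 20000)
  for (j in 2:4) {
    # two-stage dense lambda scan: coarse over 12 decades, then fine locally
    ci <- which.min(abs(vapply(coarse, df_of, numeric(1)) - targets[j]))
    fine <- seq(coarse[max(1, ci - 1)], coarse[min(length(coarse), ci + 1)],
                length.out = 20000)
    dense <- fine[which.min(abs(vapply(fine, df_of, numeric(1)) - targets[j]))]
    expect_lt(abs(df_of(lam[j]) - df_of(dense)), 1e-5)
    expect_lt(abs(df_of(lam[j]) - targets[j]), 1e-6)
  }
  # df strictly decreasing along the (increasing) grid
  expect_true(all(diff(lam) > 0))
  expect_true(all(diff(vapply(lam, df_of, numeric(1))) < 0))
  expect_error(make_lambda_grid(matrix(0, 3, 2), 3), "nonzero singular")
})

test_that("fold partition covers trials and stratifies labels", {
  f <- make_folds(103, 5, seed = 9)
  expect_setequal(unique(f), 1:5)
  expect_length(f, 103)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  labs <- rep(c("a", "b", "c"), c(40, 35, 28))
  fs <- make_folds(103, 5, labels = labs, seed = 9)
  for (lv in unique(labs)) {
    counts <- table(factor(fs[labs == lv], levels = 1:5))
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_identical(make_folds(50, 5, seed = 3), make_folds(50, 5, seed = 3))
})

test_that("select_lambda minimizes CV residual variance with ties to larger penalties", {
  set.seed(5)
  X <- matrix(rnorm(40 * 5), 40, 5)
  beta <- rnorm(5)
  # noiseless linear response: zero residuals at lambda = 0
  sel <- select_lambda(X, drop(X %*% beta), c(0, 10), n_folds = 4, seed = 2)
  expect_identical(sel$lambda, 0)
  # argmin property on a noisy problem + independent CV re-implementation
  y <- drop(X %*% beta) + rnorm(40)
  grid <- make_lambda_grid(X, 6)
  folds <- make_folds(40, 5, seed = 11)
  sel <- select_lambda(X, y, grid, folds = folds)
  oracle_var <- vapply(seq_along(grid), function(j) {
    res <- numeric(40)
    for (k in 1:5) {
      tr <- folds != k
      bh <- solve(crossprod(X[tr, ]) + grid[j] * diag(5),
                  crossprod(X[tr, ], y[tr]))
      res[!tr] <- y[!tr] - X[!tr, ] %*% bh
    }
    mean((res - mean(res))^2)
  }, numeric(1))
  expect_equal(sel$cv_variance, oracle_var, tolerance = 1e-10)
  expect_identical(sel$lambda, grid[max(which(oracle_var == min(oracle_var)))])
  expect_true(all(sel$cv_variance >= min(oracle_var) - 1e-12))
  # reproducibility through the seed
  s1 <- select_lambda(X, y, grid, n_folds = 5, seed = 4)
  s2 <- select_lambda(X, y, grid, n_folds = 5, seed = 4)
  expect_identical(s1, s2)
})

test_that("estimate_noise recovers the residual variance scale", {
  set.seed(6)
  X <- matrix(rnorm(30 * 3), 30, 3)
  beta <- rnorm(3)
  expect_warning(v0 <- estimate_noise(X, drop(X %*% beta), 0, n_folds = 5,
                                      seed = 1), "floor")
  expect_identical(v0, .Machine$double.eps)
  # unit-variance pure-noise target: sigma2 near 1
  v <- vapply(1:5, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(500 * 4), 500, 4)
    y <- rnorm(500)
    y <- (y - mean(y)) / sd(y)
    estimate_noise(Xn, y, 50, n_folds = 5, seed = s)
  }, numeric(1))
  expect_true(all(abs(v - 1) < 0.15))
  # known noise level sigma = 0.5 -> variance in [0.2, 0.3]
  set.seed(77)
  Xn <- matrix(rnorm(500 * 5), 500, 5)
  y <- drop(Xn %*% rnorm(5)) + rnorm(500, 0, 0.5)
  lam <- select_lambda(Xn, y, make_lambda_grid(Xn, 10), seed = 3)$lambda
  v <- estimate_noise(Xn, y, lam, n_folds = 5, seed = 3)
  expect_gt(v, 0.2)
  expect_lt(v, 0.3)
})

test_that("voxel filter keeps informative voxels and rejects noise", {
  expect_identical(select_voxels(c(0.5, 0.99, 1.0), 0.99),
                   c(TRUE, TRUE, FALSE))
  expect_error(select_voxels(c(2, 2, 2), 0.99), "relax")
  # simulation: half signal, half pure-noise voxels, responses standardized
  rates <- vapply(1:5, function(s) {
    bundle <- generate_dataset(synthetic_config(
      n_prior_per_cat = 10L, n_train = 120L, n_test = 10L, n_voxels = 100L,
      seed = 300 + s))
    Y <- bundle$train_responses$data
    set.seed(400 + s)
    Y[, 51:100] <- matrix(rnorm(nrow(Y) * 50), nrow(Y), 50)  # kill signal
    m <- fit_encoding_model(bundle$train_images,
                            response_set(Y),
                            encoding_config(seed = s))
    c(signal = mean(m$selected[1:50]), noise = mean(!m$selected[51:100]))
  }, numeric(2))
  expect_gt(mean(rates["signal", ]), 0.95)
  expect_gt(mean(rates["noise", ]), 0.40)
})

test_that("encoding model recovers the true forward weights", {
  bundle <- generate_dataset(synthetic_config(
    grid_shape = c(8L, 8L), n_prior_per_cat = 20L, n_train = 400L,
    n_test = 10L, n_voxels = 50L, response_noise = 0.1, seed = 21L))
  model <- fit_encoding_model(bundle$train_images, bundle$train_responses,
                              encoding_config(seed = 21L))
  cors <- vapply(seq_len(50), function(i)
    cor(model$B[, i], bundle$truth$B[, i]), numeric(1))
  expect_gt(mean(cors), 0.8)
})

test_that("encoding fit is deterministic given the seed and matches the single-voxel path", {
  bundle <- generate_dataset(synthetic_config(
    n_prior_per_cat = 10L, n_train = 80L, n_test = 10L, n_voxels = 12L,
    seed = 31L))
  cfg <- encoding_config(grid_size = 8L, seed = 31L)
  m1 <- fit_encoding_model(bundle$train_images, bundle$train_responses, cfg)
  m2 <- fit_encoding_model(bundle$train_images, bundle$train_responses, cfg)
  expect_identical(m1[c("B", "sigma2", "lambdas", "selected")],
                   m2[c("B", "sigma2", "lambdas", "selected")])
  # q = 1 reduces to the explicit per-voxel operations with the same folds
  X <- bundle$train_images$data
  y <- bundle$train_responses$data[, 3]
  ys <- (y - mean(y)) / sd(y)
  sel <- select_lambda(X, ys, m1$grid, folds = m1$folds)
  expect_equal(sel$lambda, m1$lambdas[3])
  expect_equal(var_pop_oracle <- min(sel$cv_variance), m1$sigma2[3],
               tolerance = 1e-12)
  expect_equal(fit_ridge(X, ys, sel$lambda), m1$B[, 3], tolerance = 1e-8)
})
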