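# Reconstruction quality: windowed SSIM, classification accuracy with chance
# levels, and two discriminative baselines (response -> pixel ridge, and
# response -> class l1 multinomial logistic regression).

gaussian_kernel_1d <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g / sum(g)
}

# Banded matrix mapping a length-n signal to its (n - size + 1) valid
# weighted sums: separable convolution via two matrix products.
band_matrix <- function(n, g) {
  size <- length(g)
  m <- matrix(0, n, n - size + 1L)
  for (j in seq_len(n - size + 1L)) m[j:(j + size - 1L), j] <- g
  m
}

# Weighted local means over all fully-interior windows.
local_stats <- function(img, Kr, Kc) t(Kr) %*% img %*% Kc

#' Structural similarity index (SSIM) between two images
#'
#' Mean over sliding windows of
#' `(2 mu_a mu_b + C1)(2 s_ab + C2) / ((mu_a^2 + mu_b^2 + C1)(s_a^2 + s_b^2 + C2))`
#' with weighted window moments, an 11 x 11 Gaussian window with sd 1.5, and
#' `C1 = (k1 d)^2`, `C2 = (k2 d)^2` for data range `d`. Only windows fully
#' inside the image contribute; images smaller than the window fall back to a
#' single uniform window over the whole image (with a warning).
#'
#' @param a,b Numeric matrices of identical shape.
#' @param window Window side length (odd, default 11).
#' @param sigma Gaussian window sd (default 1.5).
#' @param k1,k2 Stability constants (defaults 0.01, 0.03).
#' @param data_range Dynamic range of the data; defaults to the range of the
#'   two images jointly. Must be positive.
#'
#' @return SSIM value in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 data_range = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("images differ in shape")
  if (is.null(data_range)) data_range <- diff(range(a, b))
  if (!is.finite(data_range) || data_range <= 0)
    stop("data_range must be positive")
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  if (nrow(a) < window || ncol(a) < window) {
    warning("image smaller than the SSIM window; using one uniform window")
    mu_a <- mean(a); mu_b <- mean(b)
    s_a <- mean(a^2) - mu_a^2
    s_b <- mean(b^2) - mu_b^2
    s_ab <- mean(a * b) - mu_a * mu_b
    return(((2 * mu_a * mu_b + C1) * (2 * s_ab + C2)) /
             ((mu_a^2 + mu_b^2 + C1) * (s_a + s_b + C2)))
  }
  g <- gaussian_kernel_1d(window, sigma)
  Kr <- band_matrix(nrow(a), g)
  Kc <- band_matrix(ncol(a), g)
  mu_a <- local_stats(a, Kr, Kc)
  mu_b <- local_stats(b, Kr, Kc)
  s_a <- local_stats(a * a, Kr, Kc) - mu_a^2
  s_b <- local_stats(b * b, Kr, Kc) - mu_b^2
  s_ab <- local_stats(a * b, Kr, Kc) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_a + s_b + C2)
  mean(num / den)
}

row_to_image <- function(v, grid_shape) {
  matrix(v, grid_shape[1], grid_shape[2], byrow = TRUE)
}

#' Per-trial SSIM between reconstructions and originals
#'
#' @param reconstructions `N x p` matrix of reconstructed images.
#' @param originals `N x p` matrix or [image_set()] of original images.
#' @param grid_shape `(H, W)`; taken from `originals` when it is an image set.
#' @param data_range Shared dynamic range; defaults to the originals' range.
#' @param ... Passed to [ssim()].
#'
#' @return Numeric vector of per-trial SSIM values.
#' @export
ssim_batch <- function(reconstructions, originals, grid_shape = NULL,
                       data_range = NULL, ...) {
  if (inherits(originals, "image_set")) {
    grid_shape <- originals$grid_shape
    originals <- originals$data
  }
  if (is.null(grid_shape)) stop("grid_shape required for plain matrices")
  if (nrow(reconstructions) != nrow(originals))
    stop("trial counts differ")
  if (is.null(data_range)) data_range <- diff(range(originals))
  vapply(seq_len(nrow(originals)), function(j) {
    ssim(row_to_image(reconstructions[j, ], grid_shape),
         row_to_image(originals[j, ], grid_shape),
         data_range = data_range, ...)
  }, numeric(1))
}

#' Classification counts and accuracy
#'
#' @param predicted_labels,true_labels Equal-length label vectors.
#'
#' @return List with `n_correct`, `n_trials`, `accuracy`.
#' @export
classification_report <- function(predicted_labels, true_labels) {
  if (length(predicted_labels) == 0L) stop("empty label vectors")
  if (length(predicted_labels) != length(true_labels))
    stop("label vectors differ in length")
  n_correct <- sum(as.character(predicted_labels) == as.character(true_labels))
  list(n_correct = n_correct, n_trials = length(true_labels),
       accuracy = n_correct / length(true_labels))
}

#' Uniform-guess chance level
#'
#' @param n_categories Number of categories (`>= 1`).
#'
#' @return `1 / n_categories` (e.g. 0.04 for the 25-letter extended prior).
#' @export
chance_level <- function(n_categories) {
  if (n_categories < 1) stop("n_categories must be >= 1")
  1 / n_categories
}

#' Discriminative pixel baseline: ridge regression from responses to pixels
#'
#' Predicts pixel values directly from responses with the same
#' cross-validated ridge machinery as the encoding model, roles swapped:
#' responses (standardized by their training moments) form the design matrix
#' and each pixel is a regression target.
#'
#' @param train_responses,train_images Paired training [response_set()] /
#'   [image_set()] (images typically normalized).
#' @param test_responses Test [response_set()].
#' @param cfg An [encoding_config()] (threshold is ignored; no voxel filter).
#'
#' @return `N_test x p` matrix of predicted pixel values.
#' @export
discriminative_pixel_baseline <- function(train_responses, train_images,
                                          test_responses,
                                          cfg = encoding_config()) {
  check_paired(train_images, train_responses)
  Y <- train_responses$data
  center <- colMeans(Y)
  scale <- apply(Y, 2, stats::sd)
  scale[scale == 0] <- 1
  Zs <- sweep(sweep(Y, 2, center), 2, scale, "/")
  pix_center <- colMeans(train_images$data)
  Xpix <- sweep(train_images$data, 2, pix_center)  # implicit intercept
  folds <- make_folds(nrow(Zs), cfg$n_folds, labels = train_images$labels,
                      seed = cfg$seed)
  grid <- make_lambda_grid(Zs, cfg$grid_size)
  res <- cv_residuals(Zs, Xpix, grid, folds)
  p <- ncol(Xpix)
  V <- matrix(NA_real_, p, length(grid))
  for (j in seq_along(grid)) {
    R <- matrix(res[, , j, drop = TRUE], nrow = nrow(Zs))
    V[, j] <- colMeans(R^2) - colMeans(R)^2
  }
  idx <- vapply(seq_len(p), function(i) max(which(V[i, ] == min(V[i, ]))),
                integer(1))
  sv <- svd(Zs)
  uty <- crossprod(sv$u, Xpix)
  B <- matrix(0, ncol(Zs), p)
  for (j in unique(idx)) {
    cols <- which(idx == j)
    B[, cols] <- sv$v %*% (svd_shrink(sv$d, grid[j]) * uty[, cols, drop = FALSE])
  }
  Zt <- sweep(sweep(test_responses$data, 2, center), 2, scale, "/")
  sweep(Zt %*% B, 2, pix_center, "+")
}

#' Discriminative class baseline: l1 multinomial logistic on responses
#'
#' Predicts class labels directly from the (low-level) responses using the
#' gating machinery: penalty chosen by cross-validation, then an l1-penalized
#' multinomial logistic fit.
#'
#' @param train_responses Training [response_set()].
#' @param train_labels Training labels.
#' @param test_responses Test [response_set()].
#' @param n_folds CV folds for the penalty (default 10).
#' @param seed Fold seed.
#'
#' @return Character vector of predicted labels for the test trials.
#' @export
discriminative_class_baseline <- function(train_responses, train_labels,
                                          test_responses, n_folds = 10L,
                                          seed = 1L) {
  Z <- train_responses$data
  sel <- select_gating_penalty(Z, train_labels, n_folds = n_folds, seed = seed)
  model <- fit_gating(Z, train_labels, sel$penalty)
  predict_gating_classes(model, test_responses$data)
}

#' Evaluation report for a set of reconstructions
#'
#' Bundles per-trial SSIM (sum and mean) and, when labels are supplied,
#' classification counts, accuracy and the chance level.
#'
#' @param reconstructions `N x p` matrix.
#' @param originals [image_set()] (or matrix plus `grid_shape`).
#' @param predicted_labels,true_labels Optional label vectors.
#' @param grid_shape Needed when `originals` is a plain matrix.
#'
#' @return List of class `eval_report`.
#' @export
evaluate_reconstructions <- function(reconstructions, originals,
                                     predicted_labels = NULL,
                                     true_labels = NULL, grid_shape = NULL) {
  s <- ssim_batch(reconstructions, originals, grid_shape = grid_shape)
  rep <- list(ssim = s, ssim_sum = sum(s), ssim_mean = mean(s),
              n_trials = length(s))
  if (!is.null(predicted_labels) && !is.null(true_labels)) {
    cr <- classification_report(predicted_labels, true_labels)
    rep$n_correct <- cr$n_correct
    rep$accuracy <- cr$accuracy
    rep$chance <- chance_level(length(unique(true_labels)))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n_trials, " trials | SSIM sum ",
      round(x$ssim_sum, 3), ", mean ", round(x$ssim_mean, 3), sep = "")
  if (!is.null(x$accuracy))
    cat(" | accuracy ", round(100 * x$accuracy, 1), "% (chance ",
        round(100 * x$chance, 1), "%)", sep = "")
  cat("\n")
  invisible(x)
}
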