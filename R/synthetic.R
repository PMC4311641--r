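# Seeded forward simulator with the statistical structure the decoder
# assumes: category-structured images (glyph templates plus shift/pixel
# noise), a linear Gaussian forward model y = B'x + eps with diagonal noise,
# and higher-level responses z carrying category information.

#' Synthetic dataset configuration
#'
#' Defaults emulate, at desk scale, a six-category character-decoding study:
#' 12 x 12 images, 200 prior images per category, 300 training and 60 test
#' trials, 200 voxels with per-voxel SNR 2, and 50 informative gating voxels.
#'
#' @param grid_shape Image grid `(H, W)`.
#' @param n_categories Number of glyph categories (max 8).
#' @param n_prior_per_cat Prior images per category.
#' @param n_train,n_test Training/test trial counts (spread over categories).
#' @param n_voxels Low-level voxel count `q`.
#' @param n_gating_voxels Higher-level voxel count `q'`.
#' @param pixel_jitter Pixel noise sd added to templates.
#' @param shift_range Max toroidal shift in pixels (each axis).
#' @param rf_width Gaussian receptive-field width (pixels) of the forward
#'   model.
#' @param response_snr Target per-voxel signal-to-noise sd ratio; the noise sd
#'   is set to `sd(signal)/response_snr` per voxel from the training signal.
#' @param response_noise Optional absolute per-voxel noise sd overriding
#'   `response_snr`.
#' @param gating_snr Scale of the class embedding in `z` relative to its
#'   unit-variance noise.
#' @param seed Master seed; all sub-streams derive from it.
#'
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(12L, 12L), n_categories = 6L,
                             n_prior_per_cat = 200L, n_train = 300L,
                             n_test = 60L, n_voxels = 200L,
                             n_gating_voxels = 50L, pixel_jitter = 0.08,
                             shift_range = 1L, rf_width = 2,
                             response_snr = 2, response_noise = NULL,
                             gating_snr = 3, seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              n_categories = as.integer(n_categories),
              n_prior_per_cat = as.integer(n_prior_per_cat),
              n_train = as.integer(n_train), n_test = as.integer(n_test),
              n_voxels = as.integer(n_voxels),
              n_gating_voxels = as.integer(n_gating_voxels),
              pixel_jitter = pixel_jitter, shift_range = as.integer(shift_range),
              rf_width = rf_width, response_snr = response_snr,
              response_noise = response_noise, gating_snr = gating_snr,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_categories", "n_prior_per_cat", "n_train",
                         "n_test", "n_voxels", "n_gating_voxels")])
  if (any(counts < 1)) stop("all counts must be positive")
  if (cfg$pixel_jitter < 0 || cfg$gating_snr < 0)
    stop("noise/SNR parameters must be nonnegative")
  structure(cfg, class = "synthetic_config")
}

flatten_image <- function(m) as.vector(t(m))   # row-major

#' Deterministic binary category templates
#'
#' Up to eight built-in glyphs on the grid: horizontal bar, vertical bar,
#' cross, diagonal, anti-diagonal, ring, filled square, checkerboard. Pairwise
#' distinct by construction.
#'
#' @param n_categories Number of templates (1-8).
#' @param grid_shape `(H, W)`.
#'
#' @return `n_categories x p` binary matrix with glyph names as row names and
#'   `grid_shape` attached as an attribute.
#' @export
make_templates <- function(n_categories, grid_shape = c(12L, 12L)) {
  if (n_categories < 1L || n_categories > 8L)
    stop("between 1 and 8 built-in glyph templates are available")
  H <- grid_shape[1]; W <- grid_shape[2]
  th <- max(2L, H %/% 6L)                       # stroke thickness
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  mid_r <- (H + 1) / 2; mid_c <- (W + 1) / 2
  hbar <- (abs(rows - mid_r) < th / 2 + 0.5) & cols > 1 & cols < W
  vbar <- (abs(cols - mid_c) < th / 2 + 0.5) & rows > 1 & rows < H
  cross <- hbar | vbar
  dg <- abs((rows - 1) / (H - 1) - (cols - 1) / (W - 1)) * min(H, W) < th / 2 + 0.5
  adg <- abs((rows - 1) / (H - 1) - (W - cols) / (W - 1)) * min(H, W) < th / 2 + 0.5
  rad <- sqrt((rows - mid_r)^2 + (cols - mid_c)^2)
  ring <- rad >= 0.22 * min(H, W) & rad <= 0.40 * min(H, W)
  square <- abs(rows - mid_r) <= H / 5 & abs(cols - mid_c) <= W / 5
  checker <- ((rows - 1) %/% th + (cols - 1) %/% th) %% 2 == 0
  glyphs <- list(hbar = hbar, vbar = vbar, cross = cross, diag = dg,
                 adiag = adg, ring = ring, square = square, checker = checker)
  out <- t(vapply(glyphs[seq_len(n_categories)],
                  function(g) flatten_image(g * 1), numeric(H * W)))
  attr(out, "grid_shape") <- as.integer(grid_shape)
  out
}

toroidal_shift <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  m[((seq_len(H) - 1 - di) %% H) + 1, ((seq_len(W) - 1 - dj) %% W) + 1]
}

#' Sample category-structured images from templates
#'
#' Each instance is its category's template, toroidally shifted by up to
#' `shift_range` pixels on each axis, plus Gaussian pixel noise, clipped to
#' `[0, 1]`.
#'
#' @param templates Output of [make_templates()].
#' @param n_per_cat Instances per category (scalar or per-category vector).
#' @param pixel_jitter Pixel noise sd.
#' @param shift_range Max shift per axis (pixels).
#' @param seed Integer seed.
#'
#' @return A labelled [image_set()].
#' @export
sample_images <- function(templates, n_per_cat, pixel_jitter = 0.08,
                          shift_range = 1L, seed = 1L) {
  if (pixel_jitter < 0) stop("pixel_jitter must be nonnegative")
  gs <- attr(templates, "grid_shape")
  ncat <- nrow(templates)
  n_per_cat <- rep_len(n_per_cat, ncat)
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", ncat)
    for (ci in seq_len(ncat)) {
      tpl <- matrix(templates[ci, ], gs[1], gs[2], byrow = TRUE)
      rows[[ci]] <- t(vapply(seq_len(n_per_cat[ci]), function(j) {
        di <- if (shift_range > 0) sample(-shift_range:shift_range, 1L) else 0L
        dj <- if (shift_range > 0) sample(-shift_range:shift_range, 1L) else 0L
        img <- toroidal_shift(tpl, di, dj) +
          matrix(stats::rnorm(prod(gs), 0, pixel_jitter), gs[1], gs[2])
        flatten_image(pmin(pmax(img, 0), 1))
      }, numeric(prod(gs))))
    }
    image_set(do.call(rbind, rows), gs,
              labels = rep(rownames(templates), n_per_cat))
  })
}

#' Random Gaussian-receptive-field forward model
#'
#' Each voxel's weight vector is a Gaussian bump centered at a random grid
#' location with width `rf_width`, scaled to unit norm times `weight_scale`;
#' the per-voxel noise sd is constant at `noise_sd`.
#'
#' @param grid_shape `(H, W)`.
#' @param q Number of voxels.
#' @param rf_width Receptive-field width in pixels.
#' @param weight_scale Column scale after unit-norm normalization (0 gives a
#'   zero forward model).
#' @param noise_sd Per-voxel noise sd.
#' @param seed Integer seed.
#'
#' @return List with `B` (`p x q` weights) and `sigma` (length-`q` noise sds).
#' @export
make_forward_model <- function(grid_shape, q, rf_width = 2, weight_scale = 1,
                               noise_sd = 0.1, seed = 1L) {
  H <- grid_shape[1]; W <- grid_shape[2]
  p <- H * W
  rows <- flatten_image(matrix(seq_len(H), H, W))
  cols <- flatten_image(matrix(seq_len(W), H, W, byrow = TRUE))
  withr::with_seed(as.integer(seed), {
    B <- vapply(seq_len(q), function(i) {
      ci <- stats::runif(1, 1, H); cj <- stats::runif(1, 1, W)
      w <- exp(-((rows - ci)^2 + (cols - cj)^2) / (2 * rf_width^2))
      nrm <- sqrt(sum(w^2))
      if (nrm > 0) w <- w / nrm
      w * weight_scale
    }, numeric(p))
  })
  list(B = B, sigma = rep(noise_sd, q))
}

#' Simulate responses from the linear Gaussian forward model
#'
#' `Y = X B + eps` with `eps ~ N(0, diag(sigma^2))` independently per trial
#' and voxel.
#'
#' @param B `p x q` weight matrix.
#' @param sigma Length-`q` noise sds (0 allowed).
#' @param images [image_set()] providing `X`.
#' @param seed Integer seed.
#'
#' @return A [response_set()].
#' @export
simulate_responses <- function(B, sigma, images, seed = 1L) {
  X <- images$data
  if (ncol(X) != nrow(B)) stop("image pixel count does not match B")
  q <- ncol(B)
  sigma <- rep_len(sigma, q)
  withr::with_seed(as.integer(seed), {
    eps <- matrix(stats::rnorm(nrow(X) * q), nrow(X), q) *
      rep(sigma, each = nrow(X))
    response_set(X %*% B + eps)
  })
}

#' Random class embeddings for gating responses
#'
#' One random direction per class in `R^(q')`, entries `N(0, 1/q')` so the
#' embeddings are approximately unit length and mutually near-orthogonal.
#'
#' @param class_names Unique class identifiers.
#' @param q_prime Gating voxel count (`>= length(class_names)`).
#' @param seed Integer seed.
#'
#' @return `K x q'` matrix with class row names.
#' @export
make_class_embeddings <- function(class_names, q_prime, seed = 1L) {
  K <- length(class_names)
  if (q_prime < K) stop("q_prime must be at least the number of classes")
  withr::with_seed(as.integer(seed), {
    E <- matrix(stats::rnorm(K * q_prime, 0, 1 / sqrt(q_prime)), K, q_prime)
  })
  rownames(E) <- class_names
  E
}

#' Simulate category-informative higher-level responses
#'
#' `z = gating_snr * embedding(label) + N(0, I)`. With `gating_snr = 0` the
#' responses carry no category information.
#'
#' @param labels Per-trial class labels.
#' @param embeddings Class embedding matrix ([make_class_embeddings()]).
#' @param gating_snr Embedding scale.
#' @param seed Integer seed.
#'
#' @return A [response_set()].
#' @export
simulate_gating_responses <- function(labels, embeddings, gating_snr = 3,
                                      seed = 1L) {
  idx <- match(as.character(labels), rownames(embeddings))
  if (anyNA(idx)) stop("labels not covered by the embeddings")
  qp <- ncol(embeddings)
  withr::with_seed(as.integer(seed), {
    Z <- gating_snr * embeddings[idx, , drop = FALSE] +
      matrix(stats::rnorm(length(idx) * qp), length(idx), qp)
  })
  response_set(Z)
}

spread_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Generate a complete synthetic study bundle
#'
#' One call produces everything the pipeline needs: a normalized prior image
#' set, disjoint train/test stimulus sets pushed through the same
#' normalization, low-level responses simulated from the normalized images
#' under a random receptive-field forward model with per-voxel SNR
#' `response_snr`, gating responses for train and test, and the ground truth
#' (forward weights, noise sds, embeddings).
#'
#' @param cfg A [synthetic_config()].
#'
#' @return List of class `synthetic_bundle` with elements `prior`,
#'   `train_images`, `test_images` (normalized, labelled image sets),
#'   `train_responses`, `test_responses`, `train_gating`, `test_gating`,
#'   `truth`, `normalization` and `manifest`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- derive_seeds(cfg$seed, 9L)
  tpl <- make_templates(cfg$n_categories, cfg$grid_shape)
  prior_raw <- sample_images(tpl, cfg$n_prior_per_cat, cfg$pixel_jitter,
                             cfg$shift_range, seeds[1])
  train_raw <- sample_images(tpl, spread_counts(cfg$n_train, cfg$n_categories),
                             cfg$pixel_jitter, cfg$shift_range, seeds[2])
  test_raw <- sample_images(tpl, spread_counts(cfg$n_test, cfg$n_categories),
                            cfg$pixel_jitter, cfg$shift_range, seeds[3])
  nz <- normalize_images(prior_raw)
  train <- apply_normalization(train_raw, nz$params)
  test <- apply_normalization(test_raw, nz$params)

  fm <- make_forward_model(cfg$grid_shape, cfg$n_voxels, cfg$rf_width,
                           seed = seeds[4])
  signal <- train$data %*% fm$B
  sigma <- if (!is.null(cfg$response_noise)) {
    rep_len(cfg$response_noise, cfg$n_voxels)
  } else {
    pmax(apply(signal, 2, stats::sd), 1e-6) / cfg$response_snr
  }
  train_responses <- simulate_responses(fm$B, sigma, train, seeds[5])
  test_responses <- simulate_responses(fm$B, sigma, test, seeds[6])

  emb <- make_class_embeddings(sort(unique(train$labels)),
                               cfg$n_gating_voxels, seeds[7])
  train_gating <- simulate_gating_responses(train$labels, emb,
                                            cfg$gating_snr, seeds[8])
  test_gating <- simulate_gating_responses(test$labels, emb,
                                           cfg$gating_snr, seeds[9])

  structure(list(prior = nz$images, train_images = train, test_images = test,
                 train_responses = train_responses,
                 test_responses = test_responses,
                 train_gating = train_gating, test_gating = test_gating,
                 truth = list(B = fm$B, sigma = sigma, embeddings = emb),
                 normalization = nz$params,
                 manifest = unclass(cfg)),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", nrow(x$prior$data), " prior / ",
      nrow(x$train_images$data), " train / ", nrow(x$test_images$data),
      " test images (", x$manifest$grid_shape[1], "x",
      x$manifest$grid_shape[2], "), q = ", ncol(x$train_responses$data),
      ", q' = ", ncol(x$train_gating$data), "\n", sep = "")
  invisible(x)
}
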