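# Gaussian mixture image prior: built from a prior image set either per
# category label (supervised) or by K-means clustering (unsupervised).
# Cluster covariances are the 1/N_c moment estimators and are allowed to be
# singular: the decoder never inverts them.

new_mixture_prior <- function(means, covariances, weights, label_table,
                              normalization, grid_shape, component_names) {
  rownames(means) <- component_names
  structure(list(means = means, covariances = covariances, weights = weights,
                 label_table = label_table, normalization = normalization,
                 grid_shape = grid_shape, component_names = component_names),
            class = "mixture_prior")
}

#' Number of mixture components
#' @param prior A `mixture_prior`.
#' @return Integer count of components.
#' @export
n_components <- function(prior) nrow(prior$means)

#' @export
print.mixture_prior <- function(x, ...) {
  cat("<mixture_prior> ", n_components(x), " components over ",
      ncol(x$means), " pixels",
      if (!is.null(x$label_table))
        paste0(", label table over ", ncol(x$label_table), " categories"),
      "\n", sep = "")
  invisible(x)
}

#' Normalize an image set for prior construction and decoding
#'
#' Rescales pixel intensities to `[0, 1]` with one global min-max over the
#' whole set, then scales each image to unit Euclidean norm. The min-max
#' parameters are returned so that stimulus/test images can be pushed through
#' the identical transform with [apply_normalization()].
#'
#' @param images An [image_set()].
#'
#' @return List with `images` (normalized [image_set()]) and `params`
#'   (list `lo`, `hi`).
#' @export
normalize_images <- function(images) {
  stopifnot(inherits(images, "image_set"))
  lo <- min(images$data)
  hi <- max(images$data)
  if (hi - lo <= 0)
    stop("degenerate image set: all pixels equal (max == min)")
  params <- list(lo = lo, hi = hi)
  list(images = apply_normalization(images, params), params = params)
}

#' Apply stored image-normalization parameters
#'
#' @param images An [image_set()].
#' @param params Normalization parameters from [normalize_images()].
#'
#' @return Normalized [image_set()].
#' @export
apply_normalization <- function(images, params) {
  x <- (images$data - params$lo) / (params$hi - params$lo)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0))
    stop("image(s) with zero norm after min-max scaling: ",
         paste(utils::head(which(nrm == 0), 5), collapse = ", "))
  image_set(x / nrm, images$grid_shape, labels = images$labels)
}

component_moments <- function(data) {
  m <- colMeans(data)
  xc <- sweep(data, 2, m)
  list(mean = m, cov = crossprod(xc) / nrow(data))
}

#' Supervised mixture prior from labelled images
#'
#' One Gaussian component per category label: the component mean and
#' covariance are the sample moments (covariance divided by the component
#' size) of that category's images. Mixture weights are uniform by default.
#'
#' @param images A labelled [image_set()], at least two images per label.
#' @param weights `"uniform"` (default, `1/C`) or `"empirical"` (`N_c / N`).
#'
#' @return A `mixture_prior` whose `label_table` is the identity over the
#'   label set (components are the categories).
#' @export
build_supervised_prior <- function(images, weights = c("uniform", "empirical")) {
  stopifnot(inherits(images, "image_set"))
  weights <- match.arg(weights)
  if (is.null(images$labels)) stop("supervised prior requires labels")
  labs <- sort(unique(images$labels))
  C <- length(labs)
  p <- ncol(images$data)
  counts <- table(factor(images$labels, levels = labs))
  if (any(counts < 2))
    stop("label(s) with fewer than 2 images: ",
         paste(labs[counts < 2], collapse = ", "))
  means <- matrix(NA_real_, C, p)
  covs <- vector("list", C)
  for (ci in seq_len(C)) {
    mo <- component_moments(images$data[images$labels == labs[ci], , drop = FALSE])
    means[ci, ] <- mo$mean
    covs[[ci]] <- mo$cov
  }
  w <- if (weights == "uniform") rep(1 / C, C) else as.numeric(counts) / sum(counts)
  lt <- diag(C)
  dimnames(lt) <- list(labs, labs)
  new_mixture_prior(means, covs, w, lt, normalization = NULL,
                    grid_shape = images$grid_shape, component_names = labs)
}

# Seeded k-means++ initial centers (Arthur & Vassilvitskii); assumes the RNG
# state is already set by the caller.
kmeanspp_centers <- function(data, C) {
  n <- nrow(data)
  centers <- matrix(NA_real_, C, ncol(data))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- data[idx, ]
  if (C == 1L) return(centers)
  d2 <- rowSums(sweep(data, 2, centers[1L, ])^2)
  for (ci in 2:C) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L)       # all points coincide with a center
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[ci, ] <- data[idx, ]
    d2 <- pmin(d2, rowSums(sweep(data, 2, centers[ci, ])^2))
  }
  centers
}

#' Unsupervised mixture prior via K-means clustering
#'
#' Images are clustered with K-means (Euclidean distance, seeded k-means++
#' initialization, best of `restarts` runs by within-cluster sum of squares).
#' Component means are the K-means centroids; covariances are the `1/N_c`
#' sample covariances of the assigned images. Singleton or rank-zero
#' components receive a diagonal covariance `tau * I` for log-determinant
#' stability, with `tau` equal to `1e-6` times the mean per-pixel variance of
#' the image set.
#'
#' @param images An [image_set()].
#' @param C Number of clusters, `1 <= C <=` number of images.
#' @param restarts Independent K-means restarts (default 10).
#' @param seed Integer seed.
#' @param weights `"uniform"` or `"empirical"` mixture weights.
#'
#' @return A `mixture_prior`; if `images` carries labels, `label_table` holds
#'   the per-cluster label frequencies and `assignments` the 1-based cluster
#'   memberships.
#' @export
build_unsupervised_prior <- function(images, C, restarts = 10L, seed = 1L,
                                     weights = c("uniform", "empirical")) {
  stopifnot(inherits(images, "image_set"))
  weights <- match.arg(weights)
  data <- images$data
  n <- nrow(data)
  C <- as.integer(C)
  if (C < 1L || C > n) stop("C must be between 1 and the number of images")

  best <- NULL
  seeds <- derive_seeds(seed, restarts)
  for (r in seq_len(restarts)) {
    km <- withr::with_seed(seeds[r], {
      init <- kmeanspp_centers(data, C)
      tryCatch(stats::kmeans(data, centers = init, iter.max = 300L,
                             algorithm = "Lloyd"),
               error = function(e) NULL,
               warning = function(w) suppressWarnings(
                 stats::kmeans(data, centers = init, iter.max = 500L,
                               algorithm = "Lloyd")))
    })
    if (is.null(km)) next                  # empty cluster: re-seed next restart
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    stop("K-means failed to produce ", C, " non-empty clusters in ",
         restarts, " restarts")

  assignments <- best$cluster
  sizes <- tabulate(assignments, nbins = C)
  if (any(sizes == 0)) {
    warning("dropping ", sum(sizes == 0), " empty cluster(s)")
    keep <- which(sizes > 0)
    remap <- match(assignments, keep)
    assignments <- remap
    best$centers <- best$centers[keep, , drop = FALSE]
    C <- length(keep)
    sizes <- tabulate(assignments, nbins = C)
  }

  tau <- 1e-6 * mean(colMeans(data^2) - colMeans(data)^2)
  p <- ncol(data)
  means <- best$centers
  covs <- vector("list", C)
  for (ci in seq_len(C)) {
    members <- data[assignments == ci, , drop = FALSE]
    if (nrow(members) < 2L) {
      covs[[ci]] <- diag(tau, p)
    } else {
      cc <- component_moments(members)$cov
      if (all(abs(cc) < .Machine$double.eps)) cc <- diag(tau, p)
      covs[[ci]] <- cc
    }
  }
  w <- if (weights == "uniform") rep(1 / C, C) else sizes / n
  lt <- if (!is.null(images$labels))
    label_distribution(assignments, images$labels, C) else NULL
  prior <- new_mixture_prior(means, covs, w, lt, normalization = NULL,
                             grid_shape = images$grid_shape,
                             component_names = paste0("c", seq_len(C) - 1L))
  prior$assignments <- assignments
  prior
}

#' Per-cluster label frequency table
#'
#' Entry `(c, l)` is the fraction of cluster `c`'s images carrying label `l`,
#' i.e. the estimate of `P(l | c)` used to score letter categories under an
#' unsupervised prior.
#'
#' @param assignments Integer cluster memberships in `1..C`.
#' @param labels Per-image labels (same length).
#' @param C Number of clusters.
#'
#' @return `C x L` row-stochastic matrix with label column names. Clusters
#'   with no members get a uniform row with a warning.
#' @export
label_distribution <- function(assignments, labels, C) {
  if (length(assignments) != length(labels))
    stop("assignments and labels differ in length")
  if (any(assignments < 1L | assignments > C))
    stop("assignments must lie in 1..C")
  labs <- sort(unique(labels))
  tab <- table(factor(assignments, levels = seq_len(C)),
               factor(labels, levels = labs))
  tab <- matrix(as.numeric(tab), nrow = C, dimnames = list(NULL, labs))
  sizes <- rowSums(tab)
  if (any(sizes == 0)) {
    warning("cluster(s) with no members get a uniform label row: ",
            paste(which(sizes == 0), collapse = ", "))
    tab[sizes == 0, ] <- 1 / length(labs)
    sizes[sizes == 0] <- 1
  }
  tab / sizes
}

#' Validate mixture-prior invariants
#'
#' Checks the simplex constraint on weights, symmetry and numerical positive
#' semidefiniteness (eigenvalues `>= -1e-9` relative) of every covariance,
#' and row-stochasticity of the label table.
#'
#' @param prior A `mixture_prior`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_prior <- function(prior) {
  stopifnot(inherits(prior, "mixture_prior"))
  if (abs(sum(prior$weights) - 1) > 1e-12 || any(prior$weights < 0))
    stop("mixture weights are not a simplex vector")
  for (ci in seq_len(n_components(prior))) {
    R <- prior$covariances[[ci]]
    if (max(abs(R - t(R))) > 1e-8) stop("covariance ", ci, " not symmetric")
    ev <- eigen(symmetrize(R), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9 * max(1, max(abs(ev))))
      stop("covariance ", ci, " has eigenvalue ", min(ev))
  }
  if (!is.null(prior$label_table)) {
    if (max(abs(rowSums(prior$label_table) - 1)) > 1e-12)
      stop("label table rows do not sum to 1")
  }
  invisible(TRUE)
}
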