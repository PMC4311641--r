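# Plain-text interchange: TSV matrices (lossless %.17g), 8-bit grayscale PNG
# images with a JSON sidecar for grid shape, TSV labels and JSON reports.
# Cluster/trial indices are 0-based in all files; image flattening is
# row-major; every sidecar states these conventions.

#' Write a numeric matrix as TSV
#'
#' Values are formatted with 17 significant digits so the round trip through
#' [read_matrix()] is exact.
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @param col_names Optional header row.
#' @export
write_matrix <- function(m, path, col_names = NULL) {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(col_names))
    writeLines(paste(col_names, collapse = "\t"), con)
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, con)
}

#' Read a TSV numeric matrix
#'
#' @param path Input file.
#' @param header Does the first row hold column names?
#' @return Numeric matrix (column names attached when `header = TRUE`).
#' @export
read_matrix <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "numeric", check.names = FALSE)
  m <- as.matrix(df)
  if (!header) dimnames(m) <- NULL else rownames(m) <- NULL
  m
}

#' Write a response set (TSV with voxel-id header)
#' @param responses A [response_set()].
#' @param path Output file.
#' @export
write_responses <- function(responses, path) {
  write_matrix(responses$data, path, col_names = responses$voxel_ids)
}

#' Read a response set written by [write_responses()]
#' @param path Input file.
#' @return A [response_set()].
#' @export
read_responses <- function(path) {
  m <- read_matrix(path, header = TRUE)
  response_set(m, voxel_ids = colnames(m))
}

#' Write an image set as TSV plus JSON sidecar (and optional labels TSV)
#'
#' @param images An [image_set()].
#' @param path Output TSV; a `<path>.json` sidecar records the grid shape and
#'   the row-major flattening convention, and `<path>.labels.tsv` the labels.
#' @export
write_images <- function(images, path) {
  write_matrix(images$data, path)
  jsonlite::write_json(list(grid_shape = images$grid_shape,
                            flattening = "row-major",
                            index_base = 0L,
                            n_images = nrow(images$data)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  if (!is.null(images$labels))
    writeLines(images$labels, paste0(path, ".labels.tsv"))
}

#' Read an image set written by [write_images()]
#' @param path The TSV path (sidecars are located next to it).
#' @return An [image_set()].
#' @export
read_images <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels_path <- paste0(path, ".labels.tsv")
  labels <- if (file.exists(labels_path)) readLines(labels_path) else NULL
  image_set(read_matrix(path), meta$grid_shape, labels = labels)
}

#' Write images as 8-bit grayscale PNG files
#'
#' One `NNNN.png` per trial (0-based), pixel values min-max scaled to the
#' image set's global range.
#'
#' @param images An [image_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_images_png <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(images$data); hi <- max(images$data)
  denom <- if (hi > lo) hi - lo else 1
  paths <- character(nrow(images$data))
  for (j in seq_len(nrow(images$data))) {
    img <- row_to_image((images$data[j, ] - lo) / denom, images$grid_shape)
    paths[j] <- file.path(dir, sprintf("%04d.png", j - 1L))
    png::writePNG(img, paths[j])
  }
  jsonlite::write_json(list(grid_shape = images$grid_shape, lo = lo, hi = hi,
                            flattening = "row-major", index_base = 0L),
                       file.path(dir, "images.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read PNG images written by [write_images_png()]
#' @param dir Directory holding `NNNN.png` files and `images.json`.
#' @return An [image_set()] on the original intensity scale.
#' @export
read_images_png <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "images.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^[0-9]+\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG images in ", dir)
  m <- t(vapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    flatten_image(img * (meta$hi - meta$lo) + meta$lo)
  }, numeric(prod(meta$grid_shape))))
  rownames(m) <- NULL
  image_set(m, meta$grid_shape)
}

#' Write an evaluation/pipeline report as JSON
#' @param report A list (e.g. an `eval_report`).
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Serialize an encoding model to a directory
#'
#' `model.json` holds shapes, seeds, thresholds, per-voxel penalties and noise
#' variances, the voxel mask and the standardization transform; `B.tsv` holds
#' the coefficient matrix.
#'
#' @param model An `encoding_model`.
#' @param dir Output directory (created if needed).
#' @export
write_encoding_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(p = nrow(model$B), q = ncol(model$B),
               grid_shape = model$grid_shape,
               selected = model$selected, folds = model$folds,
               voxel_ids = model$voxel_ids, config = unclass(model$config),
               flattening = "row-major", index_base = 0L)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  # per-voxel numeric parameters as TSV: the %.17g format is lossless
  write_matrix(rbind(model$sigma2, model$lambdas, model$center, model$scale),
               file.path(dir, "voxel_params.tsv"))
  write_matrix(matrix(model$grid, nrow = 1), file.path(dir, "grid.tsv"))
  write_matrix(model$B, file.path(dir, "B.tsv"))
}

#' Read an encoding model written by [write_encoding_model()]
#' @param dir Model directory.
#' @return An `encoding_model`.
#' @export
read_encoding_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(encoding_config, meta$config)
  vp <- read_matrix(file.path(dir, "voxel_params.tsv"))
  structure(list(B = read_matrix(file.path(dir, "B.tsv")),
                 sigma2 = vp[1, ], lambdas = vp[2, ],
                 selected = meta$selected, center = vp[3, ],
                 scale = vp[4, ],
                 grid = drop(read_matrix(file.path(dir, "grid.tsv"))),
                 folds = meta$folds, voxel_ids = meta$voxel_ids,
                 grid_shape = as.integer(meta$grid_shape), config = cfg),
            class = "encoding_model")
}

#' Serialize a mixture prior to a directory
#'
#' `prior.json` holds weights, component names and normalization parameters;
#' `means.tsv` the component means; `covariances.tsv` the row-stacked
#' covariance matrices (`C * p` rows); `label_table.tsv` the per-cluster
#' label frequencies when present.
#'
#' @param prior A `mixture_prior`.
#' @param dir Output directory.
#' @export
write_prior <- function(prior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  C <- n_components(prior)
  meta <- list(C = C, p = ncol(prior$means), weights = prior$weights,
               component_names = prior$component_names,
               grid_shape = prior$grid_shape,
               normalization = prior$normalization,
               labels = if (!is.null(prior$label_table))
                 colnames(prior$label_table),
               flattening = "row-major", index_base = 0L)
  jsonlite::write_json(meta, file.path(dir, "prior.json"), auto_unbox = TRUE,
                       digits = NA)
  write_matrix(prior$means, file.path(dir, "means.tsv"))
  write_matrix(do.call(rbind, prior$covariances),
               file.path(dir, "covariances.tsv"))
  if (!is.null(prior$label_table))
    write_matrix(prior$label_table, file.path(dir, "label_table.tsv"))
}

#' Read a mixture prior written by [write_prior()]
#' @param dir Prior directory.
#' @return A `mixture_prior`.
#' @export
read_prior <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "prior.json"),
                              simplifyVector = TRUE)
  p <- meta$p
  covs_stack <- read_matrix(file.path(dir, "covariances.tsv"))
  covs <- lapply(seq_len(meta$C), function(ci)
    covs_stack[((ci - 1) * p + 1):(ci * p), , drop = FALSE])
  lt <- NULL
  if (file.exists(file.path(dir, "label_table.tsv"))) {
    lt <- read_matrix(file.path(dir, "label_table.tsv"))
    colnames(lt) <- meta$labels
  }
  pr <- structure(list(means = read_matrix(file.path(dir, "means.tsv")),
                       covariances = covs, weights = meta$weights,
                       label_table = lt,
                       normalization = meta$normalization,
                       grid_shape = as.integer(meta$grid_shape),
                       component_names = meta$component_names),
                  class = "mixture_prior")
  rownames(pr$means) <- pr$component_names
  pr
}

#' Serialize a gating model as JSON (sparse weights as index/value lists)
#' @param model A `gating_model`.
#' @param path Output JSON file.
#' @export
write_gating_model <- function(model, path) {
  nz <- which(model$weights != 0, arr.ind = TRUE)
  jsonlite::write_json(
    list(class_order = model$class_order, intercepts = model$intercepts,
         penalty = model$penalty, n_features = ncol(model$weights),
         weights = list(row = as.integer(nz[, 1]) - 1L,
                        col = as.integer(nz[, 2]) - 1L,
                        value = model$weights[nz]),
         index_base = 0L),
    path, auto_unbox = TRUE, digits = NA)
}

#' Read a gating model written by [write_gating_model()]
#' @param path JSON file.
#' @return A `gating_model`.
#' @export
read_gating_model <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- length(meta$class_order)
  W <- matrix(0, K, meta$n_features)
  if (length(meta$weights$row))
    W[cbind(meta$weights$row + 1L, meta$weights$col + 1L)] <-
      meta$weights$value
  structure(list(intercepts = meta$intercepts, weights = W,
                 penalty = meta$penalty, class_order = meta$class_order),
            class = "gating_model")
}
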