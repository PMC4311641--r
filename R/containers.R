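#' Trial-by-pixel image set
#'
#' Container for a set of images stored as a trial-by-pixel matrix, one image
#' per row, pixels flattened row-major from an `H x W` grid. Optionally carries
#' per-trial category labels.
#'
#' @param data Numeric matrix, `N x p`, one flattened image per row.
#' @param grid_shape Integer vector `c(H, W)` with `H * W == ncol(data)`.
#' @param labels Optional character/factor vector of length `N`.
#'
#' @return An object of class `image_set`: a list with elements `data`,
#'   `grid_shape` and `labels` (possibly `NULL`).
#' @export
#' @examples
#' im <- image_set(matrix(runif(8), 2, 4), c(2, 2), labels = c("a", "b"))
#' im
image_set <- function(data, grid_shape, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("grid_shape must be two positive integers (H, W)")
  if (prod(grid_shape) != ncol(data))
    stop("grid_shape (", grid_shape[1], " x ", grid_shape[2],
         ") does not match pixel count ", ncol(data))
  if (!all(is.finite(data)))
    stop("image data contains non-finite values")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(data))
      stop("labels length ", length(labels), " != number of trials ", nrow(data))
  }
  structure(list(data = data, grid_shape = grid_shape, labels = labels),
            class = "image_set")
}

#' Trial-by-voxel response set
#'
#' @param data Numeric matrix, `N x q`, one trial per row.
#' @param voxel_ids Optional character vector of length `q`; defaults to
#'   `"v1" ... "vq"`.
#'
#' @return An object of class `response_set` with elements `data`, `voxel_ids`.
#' @export
response_set <- function(data, voxel_ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("response data contains non-finite values")
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(ncol(data)))
  if (length(voxel_ids) != ncol(data))
    stop("voxel_ids length does not match voxel count")
  structure(list(data = data, voxel_ids = as.character(voxel_ids)),
            class = "response_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat("<image_set> ", nrow(x$data), " images, ",
      x$grid_shape[1], "x", x$grid_shape[2], " pixels",
      if (!is.null(x$labels))
        paste0(", ", length(unique(x$labels)), " categories"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.response_set <- function(x, ...) {
  cat("<response_set> ", nrow(x$data), " trials x ", ncol(x$data),
      " voxels\n", sep = "")
  invisible(x)
}

n_trials <- function(x) nrow(x$data)

check_paired <- function(images, responses) {
  if (nrow(images$data) != nrow(responses$data))
    stop("image set (", nrow(images$data), " trials) and response set (",
         nrow(responses$data), " trials) do not match")
  invisible(TRUE)
}
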