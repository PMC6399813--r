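#' Label image with reserved boundary value
#'
#' Integer segmentation image using the encoding 0 = background, 1 = segment
#' boundary (watershed line), and values >= 2 as unique region indices.
#'
#' @param labels integer matrix `[y, x]` or array `[y, x, z]`.
#' @param voxel_size optional `c(dz, dy, dx)` in micrometres carried along
#'   for physical measurements.
#' @return object of class `label_image` (an integer matrix/array with
#'   attributes).
#' @export
label_image <- function(labels, voxel_size = NULL) {
  lab <- as_label_array(labels)
  check_label_encoding(lab)
  if (!is.null(voxel_size)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    attr(lab, "voxel_size") <- stats::setNames(as.numeric(voxel_size),
                                               c("dz", "dy", "dx"))
  }
  class(lab) <- c("label_image", class(lab))
  lab
}

as_label_array <- function(labels) {
  if (inherits(labels, "label_image")) {
    a <- unclass(labels)
    attr(a, "voxel_size") <- attr(labels, "voxel_size")
    return(a)
  }
  if (is.null(dim(labels)) || !(length(dim(labels)) %in% c(2L, 3L))) {
    stop("`labels` must be a 2D matrix or 3D array")
  }
  storage.mode(labels) <- "integer"
  labels
}

check_label_encoding <- function(lab) {
  if (anyNA(lab)) stop("labels contain NA")
  if (any(lab < 0L)) stop("labels must be non-negative (0, 1, or >= 2)")
  invisible(TRUE)
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x)
  ids <- label_ids(x)
  cat(sprintf("<label_image> %s px, %d region(s)\n",
              paste(d, collapse = " x "), length(ids)))
  invisible(x)
}

#' Region indices present in a label image
#' @param labels a [label_image()].
#' @return sorted integer vector of region indices (values >= 2).
#' @export
label_ids <- function(labels) {
  v <- sort(unique(as.integer(labels)))
  v[v >= 2L]
}

label_voxel_size <- function(labels, default = c(1, 1, 1)) {
  vs <- attr(labels, "voxel_size")
  if (is.null(vs)) stats::setNames(default, c("dz", "dy", "dx")) else vs
}
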