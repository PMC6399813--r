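#' Read a multi-page TIFF stack into a voxel grid
#'
#' Pages are interpreted as z-slices; for multi-channel stacks the channels
#' are interleaved within each z position (channel index varying fastest),
#' the layout written by [write_stack()] and used by ImageJ hyperstacks.
#' Voxel sizes are taken, in order of preference, from a `<path>.meta.yaml`
#' sidecar written by [write_stack()], from an ImageJ-style description tag
#' (`spacing=` for dz) together with the TIFF x/y-resolution tags, or fall
#' back to unit voxels with a warning.
#'
#' @param path TIFF file.
#' @param n_channels number of interleaved channels; overrides metadata.
#' @param channel_names optional channel names; overrides metadata.
#' @param voxel_size optional `c(dz, dy, dx)` in micrometres; overrides
#'   metadata.
#' @param flip_z reverse the slice order, for stacks acquired with the
#'   objective-side slice last (the package convention is z = 1 outermost).
#' @param allow_nonsquare accept non-square slices (stitched mosaics);
#'   by default non-square acquisition frames are rejected.
#' @return a [voxel_grid()].
#' @export
read_stack <- function(path, n_channels = NULL, channel_names = NULL,
                       voxel_size = NULL, flip_z = FALSE,
                       allow_nonsquare = TRUE) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  meta <- read_stack_sidecar(path)
  # uint16 pages are read as raw detector counts; uint32 pages carry
  # value/scale quantised over the full 32-bit range and must be read
  # normalised (as.is would overflow the signed integer type)
  raw_counts <- !identical(meta$storage, "uint32")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE,
                                   as.is = raw_counts),
                    error = function(e) stop("cannot read '", path, "': ",
                                             conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("ragged stack: page heights ", paste(unique(dims[1, ]), collapse = "/"),
         ", widths ", paste(unique(dims[2, ]), collapse = "/"))
  }
  if (!allow_nonsquare && dims[1, 1] != dims[2, 1]) {
    stop("non-square slices: height ", dims[1, 1], " != width ", dims[2, 1])
  }
  info <- attributes(pages[[1]])

  if (is.null(n_channels)) {
    n_channels <- if (!is.null(meta$n_channels)) meta$n_channels
                  else parse_imagej_channels(info)
    if (is.null(n_channels)) n_channels <- 1L
  }
  n_channels <- as.integer(n_channels)
  if (length(pages) %% n_channels != 0L) {
    stop("page count ", length(pages), " is not a multiple of ",
         n_channels, " channels")
  }
  nz <- length(pages) %/% n_channels

  if (is.null(voxel_size)) {
    voxel_size <- if (!is.null(meta$voxel_size)) as.numeric(meta$voxel_size)
                  else parse_voxel_tags(info)
    if (is.null(voxel_size)) {
      warning("no voxel-size metadata found in '", basename(path),
              "'; assuming unit voxels")
      voxel_size <- c(1, 1, 1)
    }
  }
  if (is.null(channel_names) && !is.null(meta$channel_names)) {
    channel_names <- meta$channel_names
  }

  scale <- if (!raw_counts && !is.null(meta$scale)) meta$scale else 1
  arr <- array(0, c(dims[1, 1], dims[2, 1], nz, n_channels))
  for (z in seq_len(nz)) {
    for (c in seq_len(n_channels)) {
      arr[, , z, c] <- pages[[(z - 1L) * n_channels + c]] * scale
    }
  }
  if (flip_z) arr <- arr[, , rev(seq_len(nz)), , drop = FALSE]
  voxel_grid(arr, voxel_size = voxel_size, channel_names = channel_names)
}

#' Write a voxel grid to a multi-page TIFF with a metadata sidecar
#'
#' Integer-valued grids with intensities below 65536 are stored as 16-bit
#' unsigned samples and round-trip bit-exactly; other grids are stored as
#' 32-bit samples scaled by the recorded intensity maximum.  Voxel sizes and
#' channel names go to `<path>.meta.yaml` (this build of the \pkg{tiff}
#' library cannot write description tags).
#'
#' @param grid a [voxel_grid()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  int_ok <- max(grid$data) <= 65535 &&
    isTRUE(all(grid$data == round(grid$data)))
  if (int_ok) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(grid$data, 1)
    bits <- 32L
  }
  pages <- vector("list", d[3] * d[4])
  for (z in seq_len(d[3])) {
    for (c in seq_len(d[4])) {
      pages[[(z - 1L) * d[4] + c]] <- grid$data[, , z, c] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  write_stack_sidecar(path, list(
    n_channels = d[4],
    n_slices = d[3],
    channel_names = grid$channel_names,
    voxel_size = as.numeric(grid$voxel_size),
    scale = if (int_ok) 65535 else scale,
    storage = if (int_ok) "uint16" else "uint32"))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

write_stack_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, sidecar_path(path))
}

read_stack_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  meta <- yaml::read_yaml(sp)
  if (!is.null(meta$scale) && identical(meta$storage, "uint16")) {
    meta$scale <- 65535
  }
  meta
}

parse_imagej_channels <- function(info) {
  desc <- info$description
  if (is.null(desc)) return(NULL)
  m <- regmatches(desc, regexec("channels=([0-9]+)", desc))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NULL
}

parse_voxel_tags <- function(info) {
  desc <- info$description
  dz <- NA_real_
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2L) dz <- as.numeric(m[2])
  }
  dx <- if (!is.null(info$x.resolution) && info$x.resolution > 0) {
    1 / info$x.resolution
  } else NA_real_
  dy <- if (!is.null(info$y.resolution) && info$y.resolution > 0) {
    1 / info$y.resolution
  } else dx
  if (is.na(dz) && is.na(dx)) return(NULL)
  if (is.na(dz)) dz <- 1
  if (is.na(dx)) dx <- dy <- 1
  c(dz, dy, dx)
}

#' Write a label image to a 32-bit TIFF
#'
#' Labels use the encoding 0 = background, 1 = segment boundary, >= 2 = a
#' unique region index.  3D label stacks become multi-page files with one
#' page per z-slice.  Read-back with [read_label_image()] is bit-exact for
#' indices up to 2^24.
#'
#' @param labels a [label_image()] or plain integer matrix / 3D array.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  lab <- as_label_array(labels)
  check_label_encoding(lab)
  mx <- 2^32 - 1
  if (length(dim(lab)) == 2L) {
    pages <- list(lab / mx)
  } else {
    pages <- lapply(seq_len(dim(lab)[3]), function(z) lab[, , z] / mx)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  vs <- attr(labels, "voxel_size")
  if (!is.null(vs)) {
    write_stack_sidecar(path, list(voxel_size = as.numeric(vs),
                                   storage = "label32"))
  }
  invisible(path)
}

#' Read a label image written by [write_label_image()]
#'
#' @param path TIFF path.
#' @return a [label_image()] (2D matrix or 3D array of integers).
#' @export
read_label_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  mx <- 2^32 - 1
  lab <- if (length(pages) == 1L) {
    matrix(as.integer(round(pages[[1]] * mx)), nrow(pages[[1]]))
  } else {
    array(as.integer(round(unlist(lapply(pages, function(p) p * mx)))),
          c(dim(pages[[1]]), length(pages)))
  }
  meta <- read_stack_sidecar(path)
  vs <- if (!is.null(meta$voxel_size)) meta$voxel_size else NULL
  label_image(lab, voxel_size = vs)
}

#' Write a morphometric feature table as CSV
#'
#' RFC-4180 CSV with a header carrying unit suffixes (for example
#' `area_um2`), one row per label, sorted by index.  Numeric values are
#' written with 6 significant digits and a `.` decimal separator
#' independently of the locale.
#'
#' @param table data.frame of per-region features (must contain `index`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) && "index" %in% names(table)) {
    table <- table[order(table$index), , drop = FALSE]
  }
  out <- table
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- signif(out[[nm]], 6)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
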