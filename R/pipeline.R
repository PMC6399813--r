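#' Pipeline configuration
#'
#' Builds the configuration driving [run_pipeline()], merging user settings
#' into the defaults.  Unknown keys are rejected before any computation so
#' typos cannot silently fall back to defaults.  Settings can also be read
#' from a YAML file with [read_pipeline_config()].
#'
#' @param ... named settings overriding the defaults, using dotted key
#'   paths flattened as nested lists, e.g.
#'   `surface = list(depth = 3)`, `diffusion = list(iterations = 5)`.
#' @return nested list of class `pipeline_config`.
#' @section Keys:
#' \describe{
#'   \item{input}{`path` (stack TIFF), `wall_channel`, `nucleus_channel`,
#'     `flip_z`}
#'   \item{diffusion}{`enabled`, `iterations`, `kappa`, `gamma`, `mode`,
#'     `per_slice`}
#'   \item{surface}{`min_intensity`, `smooth_radius`, `smooth`,
#'     `trichome_radius` (0 disables trichome removal), `depth` (virtual-cut
#'     depth, slices)}
#'   \item{segment}{`cell_tolerance`, `nucleus_tolerance`,
#'     `background_threshold`, `connectivity_2d`, `connectivity_3d`}
#'   \item{measure}{`epidermal_depth` (slices, for the cell cylinder and
#'     nucleus matching), `simplify_tol`}
#'   \item{output}{`dir`, `save_intermediates`}
#' }
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    input = list(path = NULL, wall_channel = "wall",
                 nucleus_channel = "nucleus", flip_z = FALSE),
    diffusion = list(enabled = TRUE, iterations = 10L, kappa = 30,
                     gamma = NULL, mode = "exponential", per_slice = TRUE),
    surface = list(min_intensity = 50, smooth_radius = 2L,
                   smooth = "median", trichome_radius = 0L, depth = 2),
    segment = list(cell_tolerance = 30, nucleus_tolerance = 60,
                   background_threshold = 80, min_nucleus_size = 15,
                   connectivity_2d = 4L, connectivity_3d = 6L),
    measure = list(epidermal_depth = 8, simplify_tol = 1),
    output = list(dir = ".", save_intermediates = FALSE))
  user <- list(...)
  cfg <- merge_config(defaults, user, path = character(0))
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, user, path) {
  if (!length(user)) return(base)
  nm <- names(user)
  if (is.null(nm) || any(nm == "")) {
    stop("configuration entries must be named (at ",
         if (length(path)) paste(path, collapse = ".") else "top level", ")")
  }
  unknown <- setdiff(nm, names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "))
  }
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]],
                                if (is.list(user[[k]])) user[[k]] else
                                  stop("key '", k, "' must be a section"),
                                c(path, k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the sections documented in
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full stack-to-features pipeline
#'
#' Executes read (or takes an in-memory grid) -> denoise -> surface mask ->
#' optional trichome removal -> virtual cut -> watershed segmentation of
#' cells (border mode on the cut) and nuclei (object mode in 3D) -> healing
#' of fragmented nuclei -> morphometry -> cell-nucleus matching, and
#' writes the label images and the feature CSV.  Deterministic given the
#' configuration and input.
#'
#' @param config a [pipeline_config()].
#' @param grid optional [voxel_grid()] overriding `config$input$path`.
#' @param edits optional list of label edits applied to the cell
#'   segmentation before measuring; each element is
#'   `list(op = "merge", ids = c(...))`, `list(op = "remove", id = ...)` or
#'   `list(op = "group", assignment = c("2" = "rowA"))`.
#' @param verbose print per-stage messages.
#' @return list with `features` (data.frame), `cells`, `nuclei` (label
#'   images), `mask` (surface mask), `cut` (virtual cut), `matches`, and
#'   the paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), grid = NULL,
                         edits = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[leafcut] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(grid)) {
    if (is.null(config$input$path)) stop("no input: set input$path or pass `grid`")
    say("reading %s", config$input$path)
    grid <- stage("read", read_stack(config$input$path,
                                     flip_z = isTRUE(config$input$flip_z)))
  }
  wall_ch <- config$input$wall_channel
  nuc_ch <- config$input$nucleus_channel

  wall <- stage("channels", grid_channel(grid, wall_ch))
  nuc <- stage("channels", grid_channel(grid, nuc_ch))

  if (isTRUE(config$diffusion$enabled)) {
    # the configured kappa is stated on an 8-bit scale; rescale per channel
    # so the conductance threshold tracks the actual intensity range
    diffuse <- function(arr) {
      rng <- diff(range(arr))
      kap <- if (rng > 0) config$diffusion$kappa * rng / 255 else
        config$diffusion$kappa
      dp <- diffusion_params(iterations = config$diffusion$iterations,
                             kappa = kap,
                             gamma = config$diffusion$gamma,
                             mode = config$diffusion$mode)
      say("anisotropic diffusion (%d iterations, kappa %.1f)",
          dp$iterations, dp$kappa)
      if (isTRUE(config$diffusion$per_slice)) {
        for (z in seq_len(dim(arr)[3])) {
          arr[, , z] <- anisotropic_diffusion(arr[, , z], dp)
        }
        arr
      } else {
        anisotropic_diffusion(arr, dp, grid$voxel_size)
      }
    }
    wall <- stage("diffusion", diffuse(wall))
    nuc <- stage("diffusion", diffuse(nuc))
  }
  wgrid <- voxel_grid(wall, grid$voxel_size, "wall")

  say("building surface mask (min intensity %g)", config$surface$min_intensity)
  mask <- stage("surface",
                build_surface_mask(wgrid, "wall",
                                   min_intensity = config$surface$min_intensity,
                                   smooth_radius = config$surface$smooth_radius,
                                   smooth = config$surface$smooth))
  if (config$surface$trichome_radius > 0) {
    say("removing trichomes (closing radius %d)",
        config$surface$trichome_radius)
    mask <- stage("trichomes",
                  remove_trichomes(mask, config$surface$trichome_radius))
  }
  say("extracting virtual cut at depth %g slices", config$surface$depth)
  cut <- stage("cut",
               extract_virtual_cut(wgrid, mask, "wall",
                                   depth = config$surface$depth))

  say("segmenting cells (border mode, tolerance %g)",
      config$segment$cell_tolerance)
  cells <- stage("segment-cells", segment_watershed(
    cut,
    segmentation_params("border",
                        dynamic_tolerance = config$segment$cell_tolerance,
                        connectivity = config$segment$connectivity_2d),
    voxel_size = grid$voxel_size))

  say("segmenting nuclei (object mode, tolerance %g)",
      config$segment$nucleus_tolerance)
  nuclei <- stage("segment-nuclei", segment_watershed(
    nuc,
    segmentation_params("object",
                        dynamic_tolerance = config$segment$nucleus_tolerance,
                        connectivity = config$segment$connectivity_3d,
                        background_threshold =
                          config$segment$background_threshold,
                        min_size = config$segment$min_nucleus_size),
    voxel_size = grid$voxel_size))
  nuclei <- stage("heal", heal_fragmented_labels(nuclei))

  if (!is.null(edits)) {
    for (e in edits) {
      cells <- stage("edit", switch(
        e$op,
        merge = merge_labels(cells, e$ids),
        remove = remove_label(cells, e$id),
        group = group_labels(cells, e$assignment),
        stop("unknown edit op '", e$op, "'")))
    }
  }

  say("measuring %d cells", length(label_ids(cells)))
  feats <- stage("measure",
                 compute_shape_features(cells, grid$voxel_size,
                                        simplify_tol =
                                          config$measure$simplify_tol))
  matches <- stage("match",
                   match_cells_to_nuclei(cells, nuclei, mask,
                                         depth = config$measure$epidermal_depth,
                                         voxel_size = grid$voxel_size))
  feats$cylinder_volume_um3 <- cylinder_cell_volume(
    feats$area_um2,
    config$measure$epidermal_depth * grid$voxel_size[["dz"]])
  feats$nucleus_index <- matches$nucleus_index[match(feats$index,
                                                     matches$cell_index)]
  feats$nucleus_volume_um3 <- matches$nucleus_volume_um3[
    match(feats$index, matches$cell_index)]
  if (!"group" %in% names(feats)) feats$group <- ""
  feats <- feats[, c("index", "area_um2", "perimeter_um", "length_um",
                     "width_um", "elongation", "circularity",
                     "rectangularity", "lobeyness", "neighbor_count",
                     "is_marginal", "centroid_y_um", "centroid_x_um",
                     "cylinder_volume_um3", "nucleus_index",
                     "nucleus_volume_um3", "group")]

  outdir <- config$output$dir
  paths <- list()
  if (!is.null(outdir) && nzchar(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths$features <- file.path(outdir, "features.csv")
    write_feature_table(feats, paths$features)
    paths$cells <- file.path(outdir, "cells_labels.tif")
    write_label_image(cells, paths$cells)
    paths$nuclei <- file.path(outdir, "nuclei_labels.tif")
    write_label_image(nuclei, paths$nuclei)
    if (isTRUE(config$output$save_intermediates)) {
      paths$mask <- file.path(outdir, "surface_mask.tif")
      write_surface_mask(mask, paths$mask)
      paths$cut <- file.path(outdir, "virtual_cut.tif")
      tiff::writeTIFF(cut$intensity / max(cut$intensity, 1), paths$cut,
                      bits.per.sample = 32L, reduce = FALSE)
    }
    say("wrote %s", paths$features)
  }
  invisible(list(features = feats, cells = cells, nuclei = nuclei,
                 mask = mask, cut = cut, matches = matches, paths = paths,
                 config = config))
}
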