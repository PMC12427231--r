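#' Build a layered cylindrical tissue phantom
#'
#' Voxelizes a cylinder of concentric tissue layers (axis along z) with an
#' optional embedded spherical tumor. Voxel membership is decided by the
#' voxel-center position: each center inside the cylinder gets the label of
#' the innermost layer whose radius contains its radial distance to the axis;
#' the tumor sphere overrides the layer label; centers outside the cylinder
#' are label 0 (exterior).
#'
#' @param config list (or path to a JSON file, see [read_phantom_config()])
#'   with fields:
#'   \describe{
#'     \item{spacing_mm}{grid spacing (scalar or 3-vector), mm.}
#'     \item{height_mm}{cylinder height, mm (axis along z, centered at 0).}
#'     \item{layers}{list of `list(radius_mm=, tissue=)` pairs with strictly
#'       increasing radii, innermost first.}
#'     \item{tumor}{optional `list(center_mm=, radius_mm=, tissue="tumor")`.}
#'     \item{tissue_table}{a [tissue_table()], a CSV path, or omitted for
#'       [default_tissue_table()].}
#'   }
#' @return object of class `tissue_phantom` with fields `grid`, `labels`
#'   (integer vector over all grid voxels, x fastest), `table`.
#' @export
build_layered_cylinder_phantom <- function(config) {
  if (is.character(config)) config <- read_phantom_config(config)
  layers <- config$layers
  if (is.null(layers) || !length(layers))
    stop_config("config must list at least one layer")
  radii <- vapply(layers, function(l) as.numeric(l$radius_mm), numeric(1))
  tissues <- vapply(layers, function(l) as.character(l$tissue), character(1))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop_config("layer radii must be positive")
  if (is.unsorted(radii, strictly = TRUE))
    stop_config("layer radii must be strictly increasing (innermost first)")
  height <- as.numeric(config$height_mm %||% stop_config("height_mm required"))
  if (!is.finite(height) || height <= 0) stop_config("height_mm must be > 0")
  spacing <- as.numeric(config$spacing_mm %||% stop_config("spacing_mm required"))

  table <- config$tissue_table
  if (is.null(table)) table <- default_tissue_table()
  else if (is.character(table)) table <- read_tissue_table(table)
  else table <- tissue_table(table)

  rmax <- radii[length(radii)]
  n_xy <- as.integer(ceiling(2 * rmax / spacing[1])) + 1L
  sp_z <- if (length(spacing) == 3L) spacing[3] else spacing[1]
  n_z <- as.integer(ceiling(height / sp_z)) + 1L
  grid <- voxel_grid(c(n_xy, n_xy, n_z), spacing)

  xyz <- voxel_centers(grid)
  rad <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  inside <- rad <= rmax & abs(xyz[, 3]) <= height / 2

  layer_labels <- tissue_label(table, tissues)
  labels <- integer(n_voxels(grid))
  # innermost matching layer wins: assign outermost first, overwrite inward
  for (li in rev(seq_along(radii))) {
    sel <- inside & rad <= radii[li]
    labels[sel] <- layer_labels[li]
  }

  tum <- config$tumor
  if (!is.null(tum)) {
    ctr <- as.numeric(tum$center_mm)
    rt <- as.numeric(tum$radius_mm)
    if (length(ctr) != 3L || !is.finite(rt) || rt <= 0)
      stop_config("tumor needs center_mm (triple) and radius_mm > 0")
    if (sqrt(ctr[1]^2 + ctr[2]^2) + rt > rmax || abs(ctr[3]) + rt > height / 2)
      stop_config("tumor sphere not fully inside the cylinder")
    d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
    labels[inside & d2 <= rt^2] <- tissue_label(table, tum$tissue %||% "tumor")
  }

  structure(list(grid = grid, labels = labels, table = table,
                 config = config),
            class = "tissue_phantom")
}

#' Read a phantom configuration file
#'
#' Plain-JSON key-value configuration (see [build_layered_cylinder_phantom()]
#' for the schema).
#'
#' @param path JSON file path.
#' @return config list.
#' @export
read_phantom_config <- function(path) {
  if (!file.exists(path)) stop_config("phantom config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(cfg$layers) && is.data.frame(cfg$layers))
    cfg$layers <- lapply(seq_len(nrow(cfg$layers)), function(i) as.list(cfg$layers[i, ]))
  cfg
}

#' @export
print.tissue_phantom <- function(x, ...) {
  nt <- sum(x$labels > 0L)
  cat(sprintf("tissue_phantom: %d tissue voxels of %d (%d tissue types)\n",
              nt, n_voxels(x$grid), length(unique(x$labels[x$labels > 0L]))))
  invisible(x)
}

tissue_indices <- function(phantom) which(phantom$labels > 0L)

#' Partition tissue voxels into tumor / transition / healthy regions
#'
#' The tumor region is the union of tumor-labeled voxels and the ball of
#' radius `rt` around `centroid` (so irregular imported tumors are covered and
#' `rt` acts as a lower bound); the transition shell extends to `rh` and
#' carries no mask constraints; everything else is healthy tissue.
#'
#' @param phantom a `tissue_phantom`.
#' @param centroid tumor center, mm-triple.
#' @param rt tumor radial extent, mm.
#' @param rh transition outer radius, mm; must exceed `rt`.
#' @param tumor_label optional label treated as tumor tissue (default: the
#'   table row named "tumor" if present).
#' @return object of class `region_partition` with logical masks
#'   `tumor_mask`, `transition_mask`, `healthy_mask` over all grid voxels.
#' @export
partition_regions <- function(phantom, centroid, rt, rh, tumor_label = NULL) {
  if (!is.finite(rt) || !is.finite(rh) || rt <= 0 || rt >= rh)
    stop_arg("need 0 < rt < rh")
  centroid <- as.numeric(centroid)
  if (length(centroid) != 3L) stop_arg("centroid must be an mm-triple")
  if (is.null(tumor_label)) {
    tumor_label <- match("tumor", phantom$table$name)
    if (is.na(tumor_label)) tumor_label <- 0L
  }
  xyz <- voxel_centers(phantom$grid)
  d <- sqrt((xyz[, 1] - centroid[1])^2 + (xyz[, 2] - centroid[2])^2 +
            (xyz[, 3] - centroid[3])^2)
  tissue <- phantom$labels > 0L
  tumor <- tissue & (d <= rt | phantom$labels == tumor_label)
  if (!any(tumor)) stop_arg("empty tumor mask: centroid outside tissue?")
  transition <- tissue & !tumor & d <= rh
  healthy <- tissue & !tumor & !transition
  structure(list(tumor_mask = tumor, transition_mask = transition,
                 healthy_mask = healthy, centroid = centroid,
                 rt = rt, rh = rh),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "region_partition: %d tumor / %d transition / %d healthy voxels (rt=%g, rh=%g mm)\n",
    sum(x$tumor_mask), sum(x$transition_mask), sum(x$healthy_mask), x$rt, x$rh))
  invisible(x)
}

#' Export phantom labels as plain text
#'
#' Writes the label volume as a CSV of (i, j, k, label) for nonzero voxels
#' plus a JSON header with grid metadata. A plain-text stand-in for a NIfTI
#' label export, so no imaging dependency is needed.
#'
#' @param phantom a `tissue_phantom`.
#' @param path output CSV path (a `.meta.json` sidecar is written next to it).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(phantom, path) {
  idx <- grid_index_table(phantom$grid)
  keep <- phantom$labels > 0L
  utils::write.csv(
    data.frame(i = idx[keep, 1], j = idx[keep, 2], k = idx[keep, 3],
               label = phantom$labels[keep]),
    path, row.names = FALSE)
  meta <- list(shape = phantom$grid$shape, spacing_mm = phantom$grid$spacing,
               origin_mm = phantom$grid$origin,
               tissues = as.list(stats::setNames(seq_len(nrow(phantom$table)),
                                                 phantom$table$name)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
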