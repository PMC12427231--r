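#' Voxel grid geometry
#'
#' A regular voxel grid with 0-based indices, voxel-center coordinates in mm,
#' and a right-handed frame whose z axis is vertical (the array polarization
#' axis). `origin` is the position of the center of voxel (0, 0, 0).
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing voxel edge length per axis, mm; scalar or length-3.
#' @param origin center of voxel (0,0,0), mm; defaults to centering the grid
#'   on (0, 0, 0).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_arg("shape must be three positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_arg("spacing must be strictly positive")
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_arg("origin must be a finite mm-triple")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %d x %d x %d, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

# Linear index (1-based, x fastest) <-> 0-based (i,j,k) index triples.
grid_index_table <- function(grid) {
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  cbind(
    i = rep.int(rep.int(0:(nx - 1L), ny), nz),
    j = rep.int(rep(0:(ny - 1L), each = nx), nz),
    k = rep(0:(nz - 1L), each = nx * ny)
  )
}

#' Voxel-center coordinates
#'
#' @param grid a [voxel_grid()].
#' @param linear optional 1-based linear voxel indices (x fastest); default all.
#' @return numeric matrix with columns x, y, z in mm.
#' @export
voxel_centers <- function(grid, linear = NULL) {
  idx <- grid_index_table(grid)
  if (!is.null(linear)) idx <- idx[linear, , drop = FALSE]
  xyz <- sweep(sweep(idx, 2L, grid$spacing, `*`), 2L, grid$origin, `+`)
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
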