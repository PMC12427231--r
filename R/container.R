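FIELD_CONTAINER_VERSION <- "1.0"

#' Write / read a field-matrix container
#'
#' Lossless plain-text (JSON) container for externally simulated or surrogate
#' field matrices. Real and imaginary parts are written at full IEEE
#' precision so the round-trip is bit-identical. The container records the
#' grid metadata (shape, spacing, origin in mm), the sampled voxel index, the
#' operating frequency, antenna positions, the reference input resistance R0
#' (convention: 50 ohm), and a `format_version` attribute.
#'
#' @param EN a `field_matrix`.
#' @param path output path (conventionally `.json`).
#' @return `path` invisibly (write); a `field_matrix` (read).
#' @export
write_field_container <- function(EN, path) {
  idx <- grid_index_table(EN$grid)[EN$voxel_linear, , drop = FALSE]
  payload <- list(
    format_version = FIELD_CONTAINER_VERSION,
    grid = list(shape = EN$grid$shape, spacing_mm = EN$grid$spacing,
                origin_mm = EN$grid$origin),
    M = EN$M, N = EN$N,
    frequency_hz = EN$frequency_hz,
    antenna_positions_mm = EN$positions_mm,
    r0_ohm = EN$r0_ohm,
    voxel_index = idx,
    # %.17g strings round-trip IEEE doubles bit-exactly (JSON number
    # serialization does not); column-major over the 3M x N matrix
    EN_re = sprintf("%.17g", Re(EN$values)),
    EN_im = sprintf("%.17g", Im(EN$values))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_field_container
#' @export
read_field_container <- function(path) {
  if (!file.exists(path)) stop_format("field container not found: ", path)
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop_format("unreadable container: ",
                                                conditionMessage(e)))
  if (is.null(p$format_version))
    stop_format("container missing format_version")
  if (!identical(as.character(p$format_version), FIELD_CONTAINER_VERSION))
    stop_format("unsupported container version: ", p$format_version)
  for (field in c("grid", "EN_re", "EN_im", "voxel_index"))
    if (is.null(p[[field]])) stop_format("container missing ", field)
  g <- p$grid
  if (is.null(g$spacing_mm)) stop_format("container missing grid spacing")
  grid <- voxel_grid(g$shape, g$spacing_mm, g$origin_mm)
  re <- as.numeric(unlist(p$EN_re)); im <- as.numeric(unlist(p$EN_im))
  if (length(re) != length(im)) stop_format("EN_re/EN_im shape mismatch")
  if (any(!is.finite(re)) || any(!is.finite(im)))
    stop_format("non-numeric field entries in container")
  idx <- matrix(as.integer(as.matrix(p$voxel_index)), ncol = 3L)
  M <- nrow(idx)
  N <- as.integer(p$N %||% (length(re) / (3L * M)))
  if (length(re) != 3L * M * N)
    stop_format("EN entries (", length(re), ") != 3*M*N (", 3L * M * N, ")")
  re <- matrix(re, nrow = 3L * M, ncol = N)
  im <- matrix(im, nrow = 3L * M, ncol = N)
  lin <- 1L + idx[, 1L] + grid$shape[1L] * (idx[, 2L] + grid$shape[2L] * idx[, 3L])
  if (M < N)
    warning("container has M < N sampled voxels: pseudo-inverse projection is ill-posed")
  pos <- if (!is.null(p$antenna_positions_mm)) as.matrix(p$antenna_positions_mm)
  new_field_matrix(matrix(complex(real = re, imaginary = im), nrow = 3L * M),
                   lin, grid,
                   frequency_hz = as.numeric(p$frequency_hz %||% NA_real_),
                   positions_mm = pos,
                   r0_ohm = as.numeric(p$r0_ohm %||% 50))
}
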