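#' Tissue property table
#'
#' Validates a data frame of per-tissue dielectric and thermal properties.
#' Columns: `name`, `eps_r` (relative permittivity, unitless), `sigma_S_per_m`
#' (effective conductivity), `rho_kg_per_m3` (mass density),
#' `k_W_per_mC` (thermal conductivity), `cp_J_per_kgC` (specific heat),
#' `omega_ml_per_min_kg` (blood perfusion rate).
#'
#' Tissue labels in a phantom are the 1-based row numbers of this table;
#' label 0 is reserved for the exterior (water/air).
#'
#' @param df data frame with the columns above.
#' @return object of class `tissue_table`.
#' @export
tissue_table <- function(df) {
  req <- c("name", "eps_r", "sigma_S_per_m", "rho_kg_per_m3",
           "k_W_per_mC", "cp_J_per_kgC", "omega_ml_per_min_kg")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_config("tissue table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[req]
  if (anyDuplicated(df$name))
    stop_config("duplicate tissue names in table")
  num <- df[-1L]
  if (any(!vapply(num, is.numeric, logical(1))) || any(!is.finite(as.matrix(num))))
    stop_config("tissue properties must be finite numerics")
  with(df, {
    if (any(sigma_S_per_m < 0)) stop_config("sigma must be >= 0")
    if (any(rho_kg_per_m3 <= 0)) stop_config("rho must be > 0")
    if (any(k_W_per_mC <= 0)) stop_config("k must be > 0")
    if (any(cp_J_per_kgC <= 0)) stop_config("Cp must be > 0")
    if (any(omega_ml_per_min_kg < 0)) stop_config("omega must be >= 0")
  })
  rownames(df) <- NULL
  class(df) <- c("tissue_table", "data.frame")
  df
}

#' Read a tissue table CSV
#'
#' @param path CSV file with the [tissue_table()] header.
#' @return a `tissue_table`.
#' @export
read_tissue_table <- function(path) {
  if (!file.exists(path)) stop_config("tissue table not found: ", path)
  tissue_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Built-in 434 MHz head-and-neck tissue table
#'
#' Representative single-frequency dielectric and thermal properties for the
#' layered neck fixture (skin, fat, muscle, cortical bone, spinal cord,
#' tumor). The tumor dielectric pair (eps_r = 59, sigma = 0.89 S/m) follows
#' published head-and-neck planning values; the remaining rows are
#' IT'IS-style literature values chosen for the fixture, not measurements.
#'
#' @return a `tissue_table`.
#' @export
default_tissue_table <- function() {
  path <- system.file("extdata", "tissues_434MHz.csv", package = "apahtp",
                      mustWork = TRUE)
  read_tissue_table(path)
}

tissue_label <- function(table, name) {
  idx <- match(name, table$name)
  if (anyNA(idx)) stop_config("unknown tissue name: ",
                              paste(name[is.na(idx)], collapse = ", "))
  idx
}

# Per-voxel property lookup; total for valid phantoms (label 0 excluded).
lookup_property <- function(phantom, column, linear = NULL) {
  labels <- phantom$labels
  if (!is.null(linear)) labels <- labels[linear]
  if (any(labels < 1L | labels > nrow(phantom$table)))
    stop_config("phantom contains labels absent from the tissue table")
  phantom$table[[column]][labels]
}
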