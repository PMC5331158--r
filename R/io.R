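#' Read and write angle tables
#'
#' Angle tables are tab-separated files with columns `group_id`,
#' `angle1_deg`, `angle2_deg` (plus any extra provenance columns, which are
#' kept on reading). In memory the package uses the column names `group`,
#' `angle1`, `angle2`.
#'
#' @param path file path.
#' @return `read_angles()`: tibble with columns `group`, `angle1`, `angle2`.
#' @export
read_angles <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("group_id", "angle1_deg", "angle2_deg")
  if (!all(need %in% names(df))) {
    stop("angle table must have columns ", paste(need, collapse = ", "))
  }
  dplyr::rename(df, group = "group_id", angle1 = "angle1_deg",
                angle2 = "angle2_deg")
}

#' @rdname read_angles
#' @param data tibble with columns `group`, `angle1`, `angle2`.
#' @export
write_angles <- function(data, path) {
  out <- dplyr::rename(data, group_id = "group", angle1_deg = "angle1",
                       angle2_deg = "angle2")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write gridded densities
#'
#' Density grids are stored long-form as TSV with columns `angle1_deg`,
#' `angle2_deg` (cell midpoints) and `density`, direction 1 varying slowest.
#'
#' @param p a [density_grid()].
#' @param path file path.
#' @param domain the [angular_domain()] of the stored grid (needed on read).
#' @export
write_density_grid <- function(p, path) {
  df <- tibble::as_tibble(p)
  readr::write_tsv(
    dplyr::rename(df, angle1_deg = "angle1", angle2_deg = "angle2"), path)
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path, domain) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  g1 <- sort(unique(df$angle1_deg)) * pi / 180
  g2 <- sort(unique(df$angle2_deg)) * pi / 180
  f <- matrix(NA_real_, length(g1), length(g2))
  i1 <- match(round(df$angle1_deg * pi / 180, 10), round(g1, 10))
  i2 <- match(round(df$angle2_deg * pi / 180, 10), round(g2, 10))
  f[cbind(i1, i2)] <- df$density
  density_grid(f, list(g1, g2), domain)
}

#' Read and write labeled distance matrices
#'
#' TSV with a header row of labels and a leading label column.
#'
#' @param D symmetric matrix with dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- tibble::as_tibble(D, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  m
}

#' Fitting configuration as JSON
#'
#' Serializes/restores the basis and fitting settings used by
#' [fit_collective()] so runs can be reproduced from a config file.
#'
#' @param config named list of settings.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
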