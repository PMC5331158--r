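#' Density values on a regular angular grid
#'
#' Light container for a bivariate density evaluated on the midpoint grid of
#' an [angular_domain()]. Values are stored as a `grid_points[1]` x
#' `grid_points[2]` matrix, direction 1 on rows.
#'
#' @param f numeric matrix of nonnegative density values.
#' @param grid list of the two radian grid vectors (cell midpoints).
#' @param domain the [angular_domain()] the grid covers.
#' @return object of class `density_grid`.
#' @export
density_grid <- function(f, grid, domain) {
  stopifnot(is.matrix(f), nrow(f) == length(grid[[1]]),
            ncol(f) == length(grid[[2]]), all(is.finite(f)))
  structure(list(f = f, grid = grid, domain = domain,
                 cell_area = prod(vapply(1:2, function(d) {
                   (domain$upper[d] - domain$lower[d]) / length(grid[[d]])
                 }, 0))),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d grid, integral %.6f\n",
              nrow(x$f), ncol(x$f), grid_integral(x)))
  invisible(x)
}

#' Midpoint-quadrature integral of a gridded density
#'
#' @param p a [density_grid()].
#' @return scalar Riemann-sum integral (cell area times sum of values).
#' @export
grid_integral <- function(p) {
  sum(p$f) * p$cell_area
}

#' Integrated squared error between two gridded densities
#'
#' \eqn{\int (p - q)^2} by midpoint quadrature; both densities must share the
#' same grid.
#'
#' @param p,q [density_grid()] objects on a common grid.
#' @return nonnegative scalar.
#' @export
ise <- function(p, q) {
  check_same_grid(p, q)
  sum((p$f - q$f)^2) * p$cell_area
}

check_same_grid <- function(p, q) {
  if (!isTRUE(all.equal(dim(p$f), dim(q$f))) ||
      max(abs(p$grid[[1]] - q$grid[[1]])) > 1e-10 ||
      max(abs(p$grid[[2]] - q$grid[[2]])) > 1e-10) {
    stop("density grids do not match")
  }
  invisible(TRUE)
}

#' @export
as.data.frame.density_grid <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' Tidy a density grid into a long tibble
#'
#' @param x a [density_grid()].
#' @param ... unused.
#' @return tibble with columns `angle1`, `angle2` (degrees, cell midpoints)
#'   and `density`.
#' @export
as_tibble.density_grid <- function(x, ...) {
  tibble::tibble(
    angle1 = rep(x$grid[[1]] * 180 / pi, times = length(x$grid[[2]])),
    angle2 = rep(x$grid[[2]] * 180 / pi, each = length(x$grid[[1]])),
    density = as.vector(x$f)
  )
}

#' Heatmap of a gridded angular density
#'
#' @param object a [density_grid()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.density_grid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  lab <- object$domain$labels
  ggplot2::ggplot(df, ggplot2::aes(.data$angle1, .data$angle2,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0(lab[1], " (deg)"), y = paste0(lab[2], " (deg)"))
}
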