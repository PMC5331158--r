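#' Wrapped-kernel density estimate of one group of angle pairs
#'
#' Product-Gaussian kernel density estimation adapted to the angular domain:
#' in periodic directions the kernel is wrapped over `wrap_terms` periods on
#' each side, in bounded directions mass is reflected at the range limits.
#' This is the non-collective baseline estimator and also supplies the
#' initial values for [fit_collective()].
#'
#' Bandwidths default to a circular analogue of Silverman's rule per
#' direction: \eqn{h = (4/3n)^{1/5}\,\hat\sigma}, with \eqn{\hat\sigma} the
#' circular standard deviation \eqn{\sqrt{-2\log\bar R}} in periodic
#' directions and the usual standard deviation in bounded ones, floored at
#' 0.05 rad.
#'
#' @param x numeric matrix (n x 2) of angle pairs in radians, inside the
#'   domain.
#' @param domain an [angular_domain()].
#' @param bandwidth numeric length 2 (radians), or `NULL` for the default
#'   rule.
#' @param wrap_terms number of wrap/reflection images per side (default 3).
#' @param grid_points grid size per direction (default 90).
#' @param renormalize divide by the grid integral so the result integrates to
#'   exactly 1 on its grid (default `TRUE`).
#' @return a [density_grid()].
#' @export
circular_kde <- function(x, domain, bandwidth = NULL, wrap_terms = 3,
                         grid_points = 90, renormalize = TRUE) {
  stopifnot(inherits(domain, "angular_domain"))
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("need at least one observation")
  if (is.null(bandwidth)) bandwidth <- silverman_bandwidth(x, domain)
  if (any(bandwidth <= 0)) stop("bandwidths must be positive")
  if (wrap_terms < 1) stop("wrap_terms must be >= 1")

  grid <- domain_grid(domain, grid_points)
  # per-direction kernel matrices: grid_points x n
  Kd <- lapply(1:2, function(d) {
    kernel_matrix_1d(grid[[d]], x[, d], bandwidth[d], domain$periodic[d],
                     domain$lower[d], domain$upper[d], wrap_terms)
  })
  # f(g1, g2) = mean_j K1[g1, j] * K2[g2, j]
  f <- tcrossprod(Kd[[1]], Kd[[2]]) / nrow(x)
  out <- density_grid(f, grid, domain)
  if (renormalize) out$f <- out$f / grid_integral(out)
  out
}

# 1-D Gaussian kernel with wrapping (periodic) or reflection (bounded);
# returns grid x n matrix of kernel values
kernel_matrix_1d <- function(g, xs, h, periodic, lower, upper, wrap_terms) {
  n <- length(xs)
  K <- matrix(0, length(g), n)
  if (periodic) {
    period <- upper - lower
    for (w in -wrap_terms:wrap_terms) {
      K <- K + outer(g, xs, function(a, b) stats::dnorm(a - b + w * period, sd = h))
    }
  } else {
    # reflection at both range limits keeps boundary mass inside the domain;
    # one image per edge suffices for bandwidths well below the range width
    K <- outer(g, xs, function(a, b) stats::dnorm(a - b, sd = h)) +
      outer(g, 2 * lower - xs, function(a, b) stats::dnorm(a - b, sd = h)) +
      outer(g, 2 * upper - xs, function(a, b) stats::dnorm(a - b, sd = h))
  }
  K
}

silverman_bandwidth <- function(x, domain) {
  n <- nrow(x)
  vapply(1:2, function(d) {
    s <- if (domain$periodic[d]) {
      Rbar <- sqrt(mean(cos(x[, d]))^2 + mean(sin(x[, d]))^2)
      Rbar <- min(Rbar, 1 - 1e-12)
      sqrt(-2 * log(Rbar))
    } else {
      stats::sd(x[, d])
    }
    if (!is.finite(s)) s <- 0
    max((4 / (3 * n))^(1 / 5) * s, 0.05)
  }, 0)
}

#' Per-group wrapped-kernel densities from an angle table
#'
#' Applies [circular_kde()] to each group of an angle tibble (degrees, columns
#' `group`, `angle1`, `angle2`).
#'
#' @param data data frame with columns `group`, `angle1`, `angle2` (degrees).
#' @param domain an [angular_domain()].
#' @param ... passed to [circular_kde()].
#' @return named list of [density_grid()] objects, one per group (in order of
#'   first appearance).
#' @export
kde_densities <- function(data, domain = domain_torus(), ...) {
  groups <- unique(data$group)
  x <- angles_to_matrix(data, domain)
  out <- lapply(groups, function(g) {
    circular_kde(x[data$group == g, , drop = FALSE], domain, ...)
  })
  names(out) <- as.character(groups)
  out
}
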