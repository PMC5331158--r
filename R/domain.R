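#' Angular domains for bivariate backbone-angle densities
#'
#' An angular domain describes the rectangle on which a bivariate angle
#' density lives, and which directions are periodic. The two stock domains
#' are the torus of dihedral pairs (phi, psi) -- both directions periodic on
#' (-180, 180] degrees -- and the pseudo-angle domain of (theta, tau) pairs,
#' where the planar angle theta is bounded and the torsion tau is periodic.
#'
#' All tabular interfaces in this package use degrees; internal numerics use
#' radians. The domain stores ranges in radians.
#'
#' @param periodic logical vector of length 2; is each direction periodic?
#' @param range1,range2 numeric length-2 ranges in degrees for direction 1
#'   (first angle) and direction 2 (second angle).
#' @param labels character vector of length 2 naming the directions.
#' @return An object of class `angular_domain`: a list with elements
#'   `periodic`, `lower`, `upper` (radians) and `labels`.
#' @examples
#' domain_torus()
#' domain_theta_tau()
#' @export
angular_domain <- function(periodic = c(TRUE, TRUE),
                           range1 = c(-180, 180),
                           range2 = c(-180, 180),
                           labels = c("angle1", "angle2")) {
  stopifnot(length(periodic) == 2, is.logical(periodic),
            length(range1) == 2, length(range2) == 2,
            range1[2] > range1[1], range2[2] > range2[1])
  for (d in 1:2) {
    r <- if (d == 1) range1 else range2
    if (periodic[d] && abs(diff(r) - 360) > 1e-8) {
      stop("periodic direction ", d, " must span exactly 360 degrees")
    }
  }
  structure(list(
    periodic = periodic,
    lower = c(range1[1], range2[1]) * pi / 180,
    upper = c(range1[2], range2[2]) * pi / 180,
    labels = labels
  ), class = "angular_domain")
}

#' @rdname angular_domain
#' @export
domain_torus <- function() {
  angular_domain(c(TRUE, TRUE), c(-180, 180), c(-180, 180), c("phi", "psi"))
}

#' @rdname angular_domain
#' @details `domain_theta_tau()` uses the empirical range (75, 165) degrees for
#'   the bounded planar angle theta and the full circle for the torsion tau.
#' @export
domain_theta_tau <- function() {
  angular_domain(c(FALSE, TRUE), c(75, 165), c(-180, 180), c("theta", "tau"))
}

#' @export
print.angular_domain <- function(x, ...) {
  for (d in 1:2) {
    cat(sprintf("%s: [%.1f, %.1f] deg%s\n", x$labels[d],
                x$lower[d] * 180 / pi, x$upper[d] * 180 / pi,
                if (x$periodic[d]) " (periodic)" else ""))
  }
  invisible(x)
}

domain_area <- function(domain) {
  prod(domain$upper - domain$lower)
}

# wrap values of a periodic direction into (lower, upper]; bounded directions
# are returned unchanged
wrap_angle <- function(x, lower, upper) {
  p <- upper - lower
  y <- lower + (x - lower) %% p
  y[y == lower] <- upper
  y
}

# radians matrix (n x 2) from a degrees tibble with columns angle1, angle2
angles_to_matrix <- function(data, domain) {
  stopifnot(all(c("angle1", "angle2") %in% names(data)))
  x <- cbind(data$angle1, data$angle2) * pi / 180
  for (d in 1:2) {
    if (domain$periodic[d]) {
      x[, d] <- wrap_angle(x[, d], domain$lower[d], domain$upper[d])
    } else if (any(x[, d] < domain$lower[d] - 1e-9 |
                   x[, d] > domain$upper[d] + 1e-9)) {
      stop("angle", d, " values fall outside the bounded domain range")
    }
  }
  x
}

# midpoint quadrature grid: n points per direction, cell midpoints
domain_grid <- function(domain, grid_points = 90) {
  lapply(1:2, function(d) {
    h <- (domain$upper[d] - domain$lower[d]) / grid_points
    domain$lower[d] + (seq_len(grid_points) - 0.5) * h
  })
}
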