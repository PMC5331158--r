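#' Simulate grouped angle data from a shared-basis log-density model
#'
#' Generates m groups of bivariate angle observations whose true
#' log-densities follow the collective model exactly: K_true smooth
#' orthonormal coefficient components are drawn in the span of a
#' tensor-product basis, per-group scores are placed around `n_clusters`
#' centroids whose minimum pairwise separation is `separation`, and points
#' are sampled from each exact density by a grid-cell multinomial with
#' uniform within-cell jitter (so the truth is exact under the estimator's
#' midpoint quadrature convention).
#'
#' @param m number of groups.
#' @param n_i observations per group (scalar or length m).
#' @param K_true number of shared components of the truth.
#' @param n_clusters number of score-space clusters (default
#'   `min(3, m)`).
#' @param separation minimum distance between cluster centroids in score
#'   space (default 4); 0 makes all centroids coincide.
#' @param score_sd within-cluster standard deviation of scores (default 0.5).
#' @param amplitude target mean standard deviation of the log-densities over
#'   the grid (default 3); all scores are rescaled jointly to reach it, so
#'   larger values give more concentrated, Ramachandran-like densities.
#' @param domain an [angular_domain()].
#' @param df,order basis configuration for the truth (defaults 8 per
#'   direction, cubic).
#' @param grid_points sampling/truth grid resolution (default 90).
#' @param seed optional integer seed; generation is fully reproducible given
#'   the seed.
#' @return list with `data` (tibble: `group`, `angle1`, `angle2` in degrees),
#'   `truth` (list of m [density_grid()]s), `labels` (integer cluster of each
#'   group), `Theta`, `A`, and `basis`.
#' @examples
#' sim <- simulate_shared_basis(m = 4, n_i = 50, K_true = 2, seed = 1,
#'                              grid_points = 30)
#' dplyr::count(sim$data, group)
#' @export
simulate_shared_basis <- function(m = 20, n_i = 75, K_true = 3,
                                  n_clusters = min(3, m), separation = 4,
                                  score_sd = 0.5, amplitude = 3,
                                  domain = domain_torus(),
                                  df = c(8, 8), order = 4, grid_points = 90,
                                  seed = NULL) {
  if (separation < 0) stop("separation must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n_i <- rep_len(n_i, m)
  basis <- angular_basis(domain, df = df, order = order,
                         grid_points = grid_points)
  if (K_true > basis$L) stop("K_true exceeds the basis rank")

  Theta <- smooth_components(basis, K_true)
  # scale each component so the log-density function B theta_k has unit
  # standard deviation over the grid: scores of order `separation` then
  # produce genuinely multimodal, Ramachandran-like structure
  Phi_sd <- apply(basis$B %*% Theta, 2, stats::sd)
  Theta <- Theta %*% diag(1 / pmax(Phi_sd, 1e-12), K_true, K_true)
  centroids <- matrix(stats::rnorm(n_clusters * K_true), n_clusters, K_true)
  if (n_clusters > 1 && separation > 0) {
    dmin <- min(stats::dist(centroids))
    if (dmin < 1e-8) stop("degenerate random centroids; change the seed")
    centroids <- centroids * (separation / dmin)
  } else if (separation == 0) {
    centroids <- matrix(rep(centroids[1, ], each = n_clusters),
                        n_clusters, K_true)
  }
  labels <- rep_len(seq_len(n_clusters), m)
  A <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(m * K_true, sd = score_sd), m, K_true)
  # rescale all scores jointly so the average log-density spread over the
  # grid equals `amplitude` (still exactly a shared-basis model); protein
  # angle densities are strongly concentrated, so the default spread of 3
  # gives peak-to-floor ratios around e^10
  omega_sd <- mean(apply(basis$B %*% tcrossprod(Theta, A), 2, stats::sd))
  if (omega_sd > 0 && amplitude > 0) A <- A * (amplitude / omega_sd)

  grid <- basis$grid
  h <- (domain$upper - domain$lower) / grid_points
  truth <- vector("list", m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    omega <- as.vector(basis$B %*% (Theta %*% A[i, ]))
    cc <- normalizing_constant(omega, basis$cell_area)
    fvec <- exp(omega + cc)
    truth[[i]] <- density_grid(t(matrix(fvec, nrow = grid_points)),
                               grid, domain)
    # multinomial over cells, uniform jitter within the sampled cell
    cell <- sample.int(length(fvec), n_i[i], replace = TRUE,
                       prob = fvec / sum(fvec))
    i1 <- (cell - 1) %/% grid_points + 1 # direction-1 outer layout
    i2 <- (cell - 1) %% grid_points + 1
    a1 <- grid[[1]][i1] + stats::runif(n_i[i], -h[1] / 2, h[1] / 2)
    a2 <- grid[[2]][i2] + stats::runif(n_i[i], -h[2] / 2, h[2] / 2)
    rows[[i]] <- tibble::tibble(group = sprintf("g%02d", i),
                                angle1 = a1 * 180 / pi,
                                angle2 = a2 * 180 / pi)
  }
  names(truth) <- sprintf("g%02d", seq_len(m))
  list(data = dplyr::bind_rows(rows), truth = truth, labels = labels,
       Theta = Theta, A = A, basis = basis)
}

# K orthonormal smooth coefficient components: random coefficients smoothed
# along both directions of the coefficient grid (wrapping where the penalty
# does), then QR-orthonormalized
smooth_components <- function(basis, K) {
  L <- basis$L
  M <- basis$M
  N <- basis$N
  Z <- matrix(stats::rnorm(L * K), L, K)
  smooth_dir <- function(v, cyclic) {
    n <- length(v)
    if (cyclic) {
      (v + v[c(2:n, 1)] + v[c(n, 1:(n - 1))]) / 3
    } else {
      (v + v[c(2:n, n)] + v[c(1, 1:(n - 1))]) / 3
    }
  }
  for (k in seq_len(K)) {
    G <- matrix(Z[, k], N, M) # direction-2 fastest
    for (pass in 1:4) {
      G <- apply(G, 2, smooth_dir, cyclic = basis$cyclic_penalty[2])
      G <- t(apply(G, 1, smooth_dir, cyclic = basis$cyclic_penalty[1]))
    }
    Z[, k] <- as.vector(G)
  }
  qr.Q(qr(Z))[, seq_len(K), drop = FALSE]
}

#' Simulate grouped angles from von Mises mixtures
#'
#' Misspecification stress data: each group draws from a mixture of
#' independent-margin von Mises components on the torus, a model outside the
#' shared-basis family. Component centers are shared across groups within a
#' cluster and shifted between clusters.
#'
#' @param m number of groups.
#' @param n_i observations per group.
#' @param n_components mixture components per group.
#' @param kappa von Mises concentration (both margins, all components); must
#'   be positive (values below 1e-8 are treated as uniform).
#' @param n_clusters,separation cluster structure of the component centers:
#'   cluster centers are rotated apart by `separation` radians.
#' @param seed optional integer seed.
#' @return list with `data` (tibble `group`, `angle1`, `angle2`, degrees) and
#'   `labels`.
#' @export
simulate_vm_mixture <- function(m = 6, n_i = 100, n_components = 2,
                                kappa = 8, n_clusters = min(2, m),
                                separation = 1.5, seed = NULL) {
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n_i <- rep_len(n_i, m)
  base_mu <- matrix(stats::runif(n_components * 2, -pi, pi), n_components, 2)
  labels <- rep_len(seq_len(n_clusters), m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    shift <- (labels[i] - 1) * separation
    comp <- sample.int(n_components, n_i[i], replace = TRUE)
    a1 <- rvonmises(n_i[i], base_mu[comp, 1] + shift, kappa)
    a2 <- rvonmises(n_i[i], base_mu[comp, 2] - shift, kappa)
    rows[[i]] <- tibble::tibble(group = sprintf("g%02d", i),
                                angle1 = a1 * 180 / pi,
                                angle2 = a2 * 180 / pi)
  }
  list(data = dplyr::bind_rows(rows), labels = labels)
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution;
# vectorized over mu
rvonmises <- function(n, mu, kappa) {
  mu <- rep_len(mu, n)
  if (kappa < 1e-8) {
    return(wrap_angle(stats::runif(n, -pi, pi), -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 ||
          log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu[i] + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out, -pi, pi)
}
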