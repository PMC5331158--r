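#' Symmetrized Kullback-Leibler divergence between gridded densities
#'
#' \eqn{\mathrm{SKLD}(p, q) = \tfrac12[\mathrm{KL}(p\|q) + \mathrm{KL}(q\|p)]}
#' with each Kullback-Leibler term computed by midpoint quadrature on the
#' common grid. Densities are floored at `floor` before taking logarithms.
#'
#' @param p,q [density_grid()] objects on the same grid.
#' @param floor lower bound applied to density values before logs
#'   (default 1e-12).
#' @return nonnegative scalar; 0 when the densities coincide.
#' @export
skld <- function(p, q, floor = 1e-12) {
  check_same_grid(p, q)
  pf <- pmax(p$f, floor)
  qf <- pmax(q$f, floor)
  kl_pq <- sum(pf * (log(pf) - log(qf))) * p$cell_area
  kl_qp <- sum(qf * (log(qf) - log(pf))) * p$cell_area
  (kl_pq + kl_qp) / 2
}

#' Pairwise SKLD distance matrix between fitted densities
#'
#' @param densities list of [density_grid()] objects on a common grid; names
#'   (if any) label the rows/columns.
#' @param floor passed to [skld()].
#' @return symmetric m x m matrix with zero diagonal.
#' @export
density_distances <- function(densities, floor = 1e-12) {
  m <- length(densities)
  if (m < 2) stop("need at least two densities")
  Dm <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      Dm[i, j] <- Dm[j, i] <- skld(densities[[i]], densities[[j]], floor)
    }
  }
  labs <- names(densities)
  if (is.null(labs)) labs <- as.character(seq_len(m))
  dimnames(Dm) <- list(labs, labs)
  Dm
}

#' Score-space distance matrix from a collective fit
#'
#' Euclidean distances between the per-group score vectors \eqn{\alpha_i} of
#' a [fit_collective()] object: a cheap alternative to [density_distances()]
#' exploiting that the scores are a low-dimensional representation of the
#' densities.
#'
#' @param fit a [fit_collective()] object.
#' @return symmetric m x m matrix.
#' @export
score_distances <- function(fit) {
  Dm <- as.matrix(stats::dist(fit$A))
  dimnames(Dm) <- list(fit$groups, fit$groups)
  Dm
}
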