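#' Trigonometric B-spline basis on the circle
#'
#' Evaluates the normalized trigonometric B-spline basis of order `order` with
#' the given knots. The basis is built by the half-angle sine recursion: the
#' order-1 functions are knot-interval indicators, and
#' \deqn{S_i^{\nu}(\phi) = \frac{\sin\frac{\phi - x_i}{2}}{\sin\frac{x_{i+\nu-1}-x_i}{2}} S_i^{\nu-1}(\phi)
#'   + \frac{\sin\frac{x_{i+\nu}-\phi}{2}}{\sin\frac{x_{i+\nu}-x_{i+1}}{2}} S_{i+1}^{\nu-1}(\phi).}
#' Each piece of an order-\eqn{\nu} function lies in the trigonometric
#' monomial space spanned by half-angle sines/cosines (see [fm_span()]), so
#' the basis is smooth and intrinsically periodic: no seam constraints are
#' needed on the circle.
#'
#' For a periodic knot vector the knots are extended by period
#' \eqn{2\pi} and the basis index wraps modulo the number of knots, giving
#' exactly `length(knots)` basis functions, each supported on `order`
#' consecutive knot intervals.
#'
#' @param points numeric vector of evaluation angles (radians), inside one
#'   period of the knot vector.
#' @param knots strictly increasing knot angles (radians) spanning less than
#'   one period \eqn{2\pi}.
#' @param order spline order \eqn{\nu \ge 1} (4 = cubic-like, the default
#'   elsewhere in the package).
#' @param periodic if `TRUE` (default) the knot sequence wraps with period
#'   \eqn{2\pi} and there are `length(knots)` basis functions; if `FALSE` the
#'   basis is the plain trigonometric spline family on the given knots with
#'   `length(knots) - order` functions.
#' @return numeric matrix, one row per point, one column per basis function.
#'   All entries are nonnegative.
#' @examples
#' kn <- seq(-pi, pi, length.out = 9)[-9]
#' B <- trig_bspline_basis(seq(-pi, pi, length.out = 50), kn, order = 4)
#' range(B)
#' @export
trig_bspline_basis <- function(points, knots, order = 4, periodic = TRUE) {
  if (order < 1 || order != round(order)) stop("order must be an integer >= 1")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  kappa <- length(knots)
  period <- 2 * pi
  if (periodic) {
    if (knots[kappa] - knots[1] >= period) {
      stop("periodic knots must lie within one period")
    }
    if (kappa < order + 1) stop("need at least order + 1 knots")
    # extend knots cyclically so every basis function sees order + 1 knots
    ext <- c(knots, knots[seq_len(order)] + period)
    nb <- kappa
  } else {
    if (kappa <= order) stop("need more than `order` knots")
    ext <- knots
    nb <- kappa - order
  }
  # sine half-angle denominators must be nonzero: spans < 2*pi by construction
  span <- ext[length(ext)] - ext[1]
  if (!periodic && span >= period) stop("knot span must be below one period")

  eval_one <- function(i, phi) {
    # S_i^order at scalar angle phi (already shifted into [ext[i], ext[i+order]))
    S <- function(j, nu) {
      if (nu == 1) {
        return(as.numeric(phi >= ext[j] & phi < ext[j + 1]))
      }
      d1 <- sin((ext[j + nu - 1] - ext[j]) / 2)
      d2 <- sin((ext[j + nu] - ext[j + 1]) / 2)
      t1 <- if (d1 != 0) sin((phi - ext[j]) / 2) / d1 * S(j, nu - 1) else 0
      t2 <- if (d2 != 0) sin((ext[j + nu] - phi) / 2) / d2 * S(j + 1, nu - 1) else 0
      t1 + t2
    }
    S(i, order)
  }

  B <- matrix(0, length(points), nb)
  for (i in seq_len(nb)) {
    lo <- ext[i]
    hi <- ext[i + order]
    phi <- points
    if (periodic) {
      # map each point into [lo, lo + 2*pi); support test happens inside
      phi <- lo + (points - lo) %% period
    }
    inside <- phi >= lo & phi < hi
    if (any(inside)) {
      B[inside, i] <- vapply(phi[inside], function(p) eval_one(i, p), 0)
    }
  }
  B
}

#' Trigonometric monomial span of one spline piece
#'
#' The restriction of an order-\eqn{\nu} trigonometric B-spline to a single
#' knot interval lies in a \eqn{\nu}-dimensional trigonometric monomial
#' space: for even order \eqn{\nu = 2q} the odd half-angle harmonics
#' \eqn{\{\cos(\phi/2), \sin(\phi/2), \ldots, \cos((2q-1)\phi/2),
#' \sin((2q-1)\phi/2)\}}, and for odd order \eqn{\nu = 2q-1} the constants and
#' full-angle harmonics \eqn{\{1, \cos\phi, \sin\phi, \ldots,
#' \cos((q-1)\phi), \sin((q-1)\phi)\}}.
#'
#' @param points angles (radians) at which to evaluate the monomials.
#' @param order spline order.
#' @return matrix with `length(points)` rows and `order` columns.
#' @export
fm_span <- function(points, order) {
  if (order %% 2 == 0) {
    q <- order / 2
    freqs <- seq(1, 2 * q - 1, by = 2) / 2
    cols <- lapply(freqs, function(f) cbind(cos(f * points), sin(f * points)))
    do.call(cbind, cols)
  } else {
    q <- (order + 1) / 2
    out <- matrix(1, length(points), 1)
    if (q >= 2) {
      cols <- lapply(seq_len(q - 1), function(f) {
        cbind(cos(f * points), sin(f * points))
      })
      out <- cbind(out, do.call(cbind, cols))
    }
    out
  }
}

#' Polynomial B-spline basis on a bounded direction
#'
#' Standard (Cox-de Boor) B-splines with clamped boundary knots, evaluated
#' through [splines::splineDesign()]. Used for the bounded planar-angle
#' direction of the pseudo-angle domain; rows form a partition of unity.
#'
#' @param points evaluation points inside `range(knots)`.
#' @param knots strictly increasing interior + boundary knot sites (the
#'   boundary knots are repeated `order` times internally).
#' @param order spline order (4 = cubic).
#' @return matrix, one row per point, `length(knots) + order - 2` columns.
#' @export
poly_bspline_basis <- function(points, knots, order = 4) {
  if (order < 1 || order != round(order)) stop("order must be an integer >= 1")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  lo <- knots[1]
  hi <- knots[length(knots)]
  if (any(points < lo | points > hi)) stop("points outside knot range")
  full <- c(rep(lo, order - 1), knots, rep(hi, order - 1))
  # splineDesign drops the point exactly at the right boundary; nudge it in
  eps <- (hi - lo) * 1e-12
  pts <- pmin(points, hi - eps)
  splines::splineDesign(full, pts, ord = order)
}

#' Tensor product of two basis matrices
#'
#' Kronecker product `B1 %x% B2`: rows enumerate the two-dimensional grid with
#' direction 1 as the outer (slow) index and direction 2 as the inner (fast)
#' index; columns follow the same convention for the coefficient layout. This
#' ordering is used consistently for grids, coefficient vectors and the
#' penalty matrix throughout the package.
#'
#' @param B1 n1 x M matrix for direction 1.
#' @param B2 n2 x N matrix for direction 2.
#' @return (n1*n2) x (M*N) matrix.
#' @export
tensor_product_basis <- function(B1, B2) {
  if (length(B1) == 0 || length(B2) == 0) stop("empty basis matrix")
  kronecker(B1, B2)
}

# row-wise tensor product: both matrices evaluated at the same n points
row_tensor <- function(B1, B2) {
  M <- ncol(B1)
  N <- ncol(B2)
  B1[, rep(seq_len(M), each = N), drop = FALSE] *
    B2[, rep(seq_len(N), times = M), drop = FALSE]
}

#' Difference matrix of order a
#'
#' The order-`a` difference operator on a coefficient sequence of length `M`,
#' as used in difference roughness penalties: each row holds the stencil of
#' binomial coefficients with alternating signs (`a = 1`: (1, -1); `a = 2`:
#' (1, -2, 1)). With `cyclic = TRUE` the stencils wrap modulo `M`, penalizing
#' roughness across the periodic seam, and the matrix is square.
#'
#' @param a difference order, `1 <= a < M`.
#' @param M number of coefficients.
#' @param cyclic wrap the stencil around the seam?
#' @return (M-a) x M matrix, or M x M when cyclic.
#' @examples
#' difference_matrix(1, 3)
#' difference_matrix(2, 5, cyclic = TRUE)
#' @export
difference_matrix <- function(a, M, cyclic = FALSE) {
  if (a < 1 || a != round(a)) stop("a must be an integer >= 1")
  if (M <= a) stop("M must exceed the difference order a")
  sten <- choose(a, 0:a) * (-1)^(0:a)
  if (cyclic) {
    L <- matrix(0, M, M)
    for (i in seq_len(M)) {
      idx <- ((i - 1 + 0:a) %% M) + 1
      L[i, idx] <- L[i, idx] + sten
    }
  } else {
    L <- matrix(0, M - a, M)
    for (i in seq_len(M - a)) {
      L[i, i + 0:a] <- sten
    }
  }
  L
}

#' Tensor-product difference penalty matrix
#'
#' Roughness penalty for a coefficient grid of M (direction 1) by N
#' (direction 2) tensor-product coefficients laid out direction-1-outer:
#' \deqn{D = D_1 \otimes I_N + I_M \otimes D_2,\qquad D_d = L_a^\top L_a,}
#' so the quadratic form \eqn{\theta^\top D \theta} sums the squared order-`a`
#' differences of the coefficient grid along both directions. `D` is symmetric
#' positive semi-definite and annihilates the constant coefficient vector
#' (when cyclic, exactly; otherwise through the polynomial nullspace of the
#' difference stencil).
#'
#' @param a difference order.
#' @param M,N univariate basis ranks for directions 1 and 2.
#' @param cyclic_1,cyclic_2 wrap-around stencils per direction (use the
#'   direction's periodicity).
#' @return symmetric (M*N) x (M*N) matrix.
#' @export
penalty_matrix <- function(a, M, N, cyclic_1 = TRUE, cyclic_2 = TRUE) {
  L1 <- difference_matrix(a, M, cyclic_1)
  L2 <- difference_matrix(a, N, cyclic_2)
  D1 <- crossprod(L1)
  D2 <- crossprod(L2)
  kronecker(D1, diag(N)) + kronecker(diag(M), D2)
}

#' Tensor-product angular basis with roughness penalty
#'
#' Builds the full bivariate basis for an [angular_domain()]: a trigonometric
#' B-spline basis in each periodic direction, a clamped polynomial B-spline
#' basis in each bounded direction, their tensor product evaluated on a
#' regular midpoint grid, and the order-`diff_order` difference penalty
#' assembled with [penalty_matrix()]. Knots are equally spaced over each
#' direction's range.
#'
#' @param domain an [angular_domain()].
#' @param df number of basis functions per direction (length 2). Defaults to
#'   15 per periodic direction and 5 per bounded direction.
#' @param order spline order (both directions); 4 = cubic.
#' @param diff_order difference-penalty order `a`; default 2.
#' @param cyclic_penalty logical length 2: wrap the penalty stencil per
#'   direction. Default: equal to the direction's periodicity.
#' @param grid_points evaluation/quadrature grid size per direction
#'   (default 90).
#' @return An object of class `tensor_basis`: list with the grid-evaluated
#'   basis `B` (`grid_points^2` x `L`), penalty `D` (`L` x `L`), univariate
#'   ranks `M`, `N`, `L = M*N`, knot vectors, the midpoint `grid` (list of two
#'   radian vectors), the grid cell area `cell_area`, and the configuration.
#' @examples
#' bas <- angular_basis(domain_torus(), df = c(8, 8), grid_points = 30)
#' dim(bas$B); dim(bas$D)
#' @export
angular_basis <- function(domain, df = NULL, order = 4, diff_order = 2,
                          cyclic_penalty = NULL, grid_points = 90) {
  stopifnot(inherits(domain, "angular_domain"))
  if (is.null(df)) df <- ifelse(domain$periodic, 15L, 5L)
  stopifnot(length(df) == 2, all(df >= order | domain$periodic))
  if (is.null(cyclic_penalty)) cyclic_penalty <- domain$periodic
  if (any(df <= diff_order)) stop("df must exceed diff_order in each direction")

  knots <- vector("list", 2)
  for (d in 1:2) {
    lo <- domain$lower[d]
    hi <- domain$upper[d]
    if (domain$periodic[d]) {
      # df equally spaced knots over one period, last knot excluded (wraps)
      knots[[d]] <- seq(lo, hi, length.out = df[d] + 1)[-(df[d] + 1)]
    } else {
      # clamped basis: df = n_knots + order - 2  =>  n_knots = df - order + 2
      nk <- df[d] - order + 2
      if (nk < 2) stop("df too small for bounded direction of this order")
      knots[[d]] <- seq(lo, hi, length.out = nk)
    }
  }

  grid <- domain_grid(domain, grid_points)
  B_uni <- lapply(1:2, function(d) {
    if (domain$periodic[d]) {
      trig_bspline_basis(grid[[d]], knots[[d]], order)
    } else {
      poly_bspline_basis(grid[[d]], knots[[d]], order)
    }
  })
  M <- ncol(B_uni[[1]])
  N <- ncol(B_uni[[2]])
  cell <- prod((domain$upper - domain$lower) / grid_points)

  structure(list(
    B = tensor_product_basis(B_uni[[1]], B_uni[[2]]),
    D = penalty_matrix(diff_order, M, N, cyclic_penalty[1], cyclic_penalty[2]),
    M = M, N = N, L = M * N,
    knots = knots, order = order, diff_order = diff_order,
    cyclic_penalty = cyclic_penalty,
    grid = grid, grid_points = grid_points, cell_area = cell,
    domain = domain
  ), class = "tensor_basis")
}

#' @export
print.tensor_basis <- function(x, ...) {
  cat(sprintf(
    "tensor_basis: %d x %d = %d functions (order %d), %d^2 grid, diff order %d\n",
    x$M, x$N, x$L, x$order, x$grid_points, x$diff_order))
  invisible(x)
}

#' Evaluate a tensor basis at arbitrary angle pairs
#'
#' @param basis a [angular_basis()] object.
#' @param x numeric matrix (n x 2) of angle pairs in radians.
#' @return n x L basis matrix using the same column layout as `basis$B`.
#' @export
evaluate_basis <- function(basis, x) {
  stopifnot(inherits(basis, "tensor_basis"), ncol(x) == 2)
  dom <- basis$domain
  B1 <- if (dom$periodic[1]) {
    trig_bspline_basis(x[, 1], basis$knots[[1]], basis$order)
  } else {
    poly_bspline_basis(x[, 1], basis$knots[[1]], basis$order)
  }
  B2 <- if (dom$periodic[2]) {
    trig_bspline_basis(x[, 2], basis$knots[[2]], basis$order)
  } else {
    poly_bspline_basis(x[, 2], basis$knots[[2]], basis$order)
  }
  row_tensor(B1, B2)
}
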