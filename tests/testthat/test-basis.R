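knots8 <- seq(-pi, pi, length.out = 9)[-9]
h8 <- pi / 4

test_that("trigonometric B-spline recursion reproduces closed forms", {
  # order 1: indicator of the knot interval
  B <- trig_bspline_basis(knots8[3] + 0.1, knots8, order = 1)
  expect_equal(as.vector(B), c(0, 0, 1, 0, 0, 0, 0, 0))

  # order 2 at an interior knot: the single active function equals 1
  B <- trig_bspline_basis(knots8[2], knots8, order = 2)
  expect_equal(B[1, 1], 1, tolerance = 1e-12)
  expect_equal(sum(B), 1, tolerance = 1e-12)

  # order 2 at the midpoint of [x_i, x_{i+1}]: sin(h/4)/sin(h/2)
  B <- trig_bspline_basis(knots8[1] + h8 / 2, knots8, order = 2)
  expect_equal(B[1, 1], sin(h8 / 4) / sin(h8 / 2), tolerance = 1e-12)
})

test_that("trigonometric basis is nonnegative with local support of order knots", {
  g <- seq(-pi, pi - 1e-9, length.out = 2000)
  for (ord in c(2, 3, 4)) {
    B <- trig_bspline_basis(g, knots8, order = ord)
    expect_true(all(B >= 0))
    # each function supported on exactly `ord` of the 8 knot intervals
    support <- colSums(B > 1e-12) / length(g)
    expect_equal(support, rep(ord / 8, 8), tolerance = 0.01)
  }
})

test_that("trigonometric basis is periodic across the seam", {
  B_lo <- trig_bspline_basis(-pi, knots8, order = 4)
  B_hi <- trig_bspline_basis(pi - 1e-13, knots8, order = 4)
  expect_lt(max(abs(B_lo - B_hi)), 1e-10)
  # first differences across the seam agree with interior first differences
  d <- 1e-4
  g <- c(pi - 2 * d, pi - d, -pi, -pi + d, -pi + 2 * d)
  B <- trig_bspline_basis(g, knots8, order = 4)
  fd <- diff(B)  # 4 successive first differences crossing the seam
  expect_lt(max(abs(fd[2, ] - fd[3, ])), 1e-6)
})

test_that("every spline piece lies in the trigonometric monomial span", {
  for (ord in c(2, 3, 4)) {
    for (piece in c(2, 5)) {
      pts <- seq(knots8[piece], knots8[piece + 1] - 1e-10, length.out = 60)
      B <- trig_bspline_basis(pts, knots8, order = ord)
      Fm <- fm_span(pts, ord)
      expect_equal(ncol(Fm), ord)
      resid <- apply(B, 2, function(col) {
        sqrt(sum(stats::lm.fit(Fm, col)$residuals^2))
      })
      expect_lt(max(resid), 1e-10)
    }
  }
})

test_that("basis evaluation rejects invalid knot configurations", {
  expect_error(trig_bspline_basis(0, knots8, order = 0), "order")
  expect_error(trig_bspline_basis(0, rev(knots8), order = 2), "increasing")
  expect_error(trig_bspline_basis(0, c(-pi, 0, pi + 1), order = 2), "period")
})

test_that("polynomial B-splines form a partition of unity with clamped ends", {
  kn <- seq(0, 1, length.out = 4)  # cubic, df = 4 + 4 - 2 = 6
  pts <- seq(0, 1, length.out = 57)
  B <- poly_bspline_basis(pts, kn, order = 4)
  expect_equal(ncol(B), 6)
  expect_equal(rowSums(B), rep(1, 57), tolerance = 1e-12)
  # clamped end condition: first/last basis function is 1 at the boundary
  expect_equal(B[1, 1], 1, tolerance = 1e-12)
  expect_equal(B[57, 6], 1, tolerance = 1e-10)
  # order 1 gives indicators
  B1 <- poly_bspline_basis(c(0.1, 0.5, 0.9), kn, order = 1)
  expect_equal(rowSums(B1), rep(1, 3))
  expect_true(all(B1 %in% c(0, 1)))
  expect_error(poly_bspline_basis(1.5, kn, order = 4), "outside")
})

test_that("tensor product follows the Kronecker dimension and row rule", {
  expect_equal(tensor_product_basis(diag(2), diag(2)), diag(4))
  B1 <- matrix(rnorm(6), 2, 3)
  B2 <- matrix(rnorm(8), 2, 4)
  TP <- tensor_product_basis(B1, B2)
  expect_equal(dim(TP), c(4, 12))
  # row (i, j) is the elementwise outer product of row i of B1, row j of B2
  for (i in 1:2) for (j in 1:2) {
    expect_equal(TP[(i - 1) * 2 + j, ], as.vector(t(outer(B1[i, ], B2[j, ]))),
                 tolerance = 1e-14)
  }
  expect_error(tensor_product_basis(matrix(0, 0, 0), B2), "empty")
})

test_that("difference matrices hold the alternating binomial stencils", {
  expect_equal(difference_matrix(1, 3),
               matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE))
  L2 <- difference_matrix(2, 6)
  for (r in seq_len(nrow(L2))) {
    expect_equal(L2[r, r + 0:2], c(1, -2, 1))
  }
  # cyclic stencils wrap and annihilate constants exactly
  L2c <- difference_matrix(2, 5, cyclic = TRUE)
  expect_equal(dim(L2c), c(5, 5))
  expect_equal(as.vector(L2c %*% rep(1, 5)), rep(0, 5))
  expect_equal(as.vector(difference_matrix(1, 4) %*% rep(3, 4)), rep(0, 3))
  expect_error(difference_matrix(3, 3), "exceed")
})

test_that("penalty matrix equals the brute-force sum of squared differences", {
  brute <- function(theta, M, N, a, cyc1, cyc2) {
    G <- t(matrix(theta, N, M))  # M x N coefficient grid (direction 1 rows)
    val <- 0
    d1 <- difference_matrix(a, M, cyc1)
    d2 <- difference_matrix(a, N, cyc2)
    for (j in seq_len(N)) val <- val + sum((d1 %*% G[, j])^2)
    for (i in seq_len(M)) val <- val + sum((d2 %*% G[i, ])^2)
    val
  }
  set.seed(7)
  cases <- list(c(4, 3, 1), c(4, 3, 2), c(6, 5, 2), c(8, 8, 2), c(10, 7, 3))
  for (cs in cases) {
    for (cyc in list(c(FALSE, FALSE), c(TRUE, TRUE), c(TRUE, FALSE))) {
      M <- cs[1]; N <- cs[2]; a <- cs[3]
      D <- penalty_matrix(a, M, N, cyc[1], cyc[2])
      expect_equal(D, t(D))
      theta <- rnorm(M * N)
      expect_equal(sum(theta * (D %*% theta)),
                   brute(theta, M, N, a, cyc[1], cyc[2]), tolerance = 1e-10)
      ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
})

test_that("penalty annihilates constant coefficient surfaces", {
  D <- penalty_matrix(2, 8, 6, TRUE, TRUE)
  ones <- rep(1, 48)
  expect_equal(sum(ones * (D %*% ones)), 0, tolerance = 1e-10)
  Dnc <- penalty_matrix(1, 5, 4, FALSE, FALSE)
  expect_equal(max(abs(Dnc %*% rep(2, 20))), 0, tolerance = 1e-12)
})

test_that("angular_basis assembles consistent grid, basis and penalty", {
  bas <- angular_basis(domain_torus(), df = c(8, 6), grid_points = 20)
  expect_equal(bas$M, 8)
  expect_equal(bas$N, 6)
  expect_equal(dim(bas$B), c(400, 48))
  expect_equal(dim(bas$D), c(48, 48))
  expect_equal(bas$cell_area, (2 * pi / 20)^2, tolerance = 1e-14)
  # off-grid evaluation at grid points reproduces the grid basis rows
  pts <- cbind(rep(bas$grid[[1]], each = 20), rep(bas$grid[[2]], times = 20))
  expect_equal(evaluate_basis(bas, pts), bas$B, tolerance = 1e-12)
  # bounded x periodic domain: Kronecker of polynomial and trig bases
  bas2 <- angular_basis(domain_theta_tau(), df = c(5, 8), grid_points = 15)
  expect_equal(bas2$L, 40)
  expect_true(all(rowSums(bas2$B) > 0))
})
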