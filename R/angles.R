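#' Backbone atoms of a PDB file as a tidy table
#'
#' Reads a PDB file (via [bio3d::read.pdb()]) and returns the backbone N,
#' CA and C atom coordinates, one row per atom, ordered by chain and residue
#' number. Only the first conformer of multi-model files and alternate
#' location 'A'/blank atoms are kept; residues missing any of the three
#' backbone atoms are dropped with a warning. Chain breaks (consecutive CA
#' atoms further than `break_cutoff` angstroms apart) split a chain into
#' segments, and no angle is later computed across a break.
#'
#' @param path path to a PDB-format file.
#' @param break_cutoff CA-CA distance (angstrom) above which a chain break is
#'   recorded (default 4.5).
#' @return tibble with columns `chain`, `segment`, `resno`, `atom`
#'   (`"N"`, `"CA"`, `"C"`), `x`, `y`, `z`.
#' @export
read_pdb_backbone <- function(path, break_cutoff = 4.5) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$elety %in% c("N", "CA", "C") &
             (is.na(at$alt) | at$alt %in% c("", "A")), , drop = FALSE]
  if (nrow(at) == 0) stop("no backbone atoms found in ", path)

  out <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    res <- unique(sub$resno)
    keep <- vapply(res, function(r) {
      all(c("N", "CA", "C") %in% sub$elety[sub$resno == r])
    }, TRUE)
    if (any(!keep)) {
      warning("chain ", ch, ": skipped ", sum(!keep),
              " residue(s) with missing backbone atoms")
    }
    res <- res[keep]
    if (length(res) == 0) next
    rows <- do.call(rbind, lapply(res, function(r) {
      s <- sub[sub$resno == r, , drop = FALSE]
      s[match(c("N", "CA", "C"), s$elety), , drop = FALSE]
    }))
    ca <- rows[rows$elety == "CA", c("x", "y", "z"), drop = FALSE]
    gap <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
    segment <- cumsum(c(1, as.integer(gap > break_cutoff)))
    out[[length(out) + 1]] <- tibble::tibble(
      chain = ch,
      segment = rep(segment, each = 3),
      resno = rep(res, each = 3),
      atom = rep(c("N", "CA", "C"), length(res)),
      x = rows$x, y = rows$y, z = rows$z)
  }
  if (length(out) == 0) stop("no complete backbone residues in ", path)
  dplyr::bind_rows(out)
}

#' Signed torsion angle of four points
#'
#' Dihedral angle about the p2-p3 axis in the IUPAC sign convention
#' (clockwise positive looking from p2 towards p3): 0 for a cis (eclipsed)
#' planar arrangement, 180 for trans, in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("collinear points: torsion undefined")
  }
  y <- sum(b1 * n2) * sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  atan2(y, x) * 180 / pi
}

#' Planar (bond) angle at the middle of three points
#'
#' @param p1,p2,p3 numeric xyz vectors; the angle is taken at `p2`.
#' @return angle in degrees, in [0, 180].
#' @export
planar_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Backbone dihedral angles (phi, psi) of a backbone table
#'
#' For each interior residue i of every unbroken chain segment:
#' \eqn{\phi_i} is the torsion of (C of residue i-1, N_i, CA_i, C_i) and
#' \eqn{\psi_i} the torsion of (N_i, CA_i, C_i, N of residue i+1). Terminal
#' residues of a segment yield no value.
#'
#' @param backbone output of [read_pdb_backbone()].
#' @return tibble with columns `chain`, `resno`, `angle1` (phi), `angle2`
#'   (psi), degrees -- directly consumable by [fit_collective()] after adding
#'   a `group` column.
#' @export
phi_psi <- function(backbone) {
  per_segment(backbone, min_res = 3, function(coords, res, chain) {
    n <- nrow(res)
    rows <- lapply(seq(2, n - 1), function(i) {
      Cprev <- coords[["C"]][i - 1, ]
      Nnext <- coords[["N"]][i + 1, ]
      tibble::tibble(
        chain = chain, resno = res$resno[i],
        angle1 = dihedral_angle(Cprev, coords[["N"]][i, ],
                                coords[["CA"]][i, ], coords[["C"]][i, ]),
        angle2 = dihedral_angle(coords[["N"]][i, ], coords[["CA"]][i, ],
                                coords[["C"]][i, ], Nnext))
    })
    dplyr::bind_rows(rows)
  })
}

#' C-alpha pseudo-angles (theta, tau) of a backbone table
#'
#' For consecutive CA atoms of an unbroken segment: \eqn{\theta_i} is the
#' planar angle at CA_i formed by (CA_{i-1}, CA_i, CA_{i+1}), and
#' \eqn{\tau_i} the torsion of (CA_{i-1}, CA_i, CA_{i+1}, CA_{i+2}).
#' A degenerate (collinear) C-alpha window leaves the torsion `NA` while the
#' planar angle is still reported (a straight trace gives theta = 180,
#' outside the empirical (75, 165) band seen in folded proteins).
#'
#' @param backbone output of [read_pdb_backbone()].
#' @return tibble with columns `chain`, `resno`, `angle1` (theta), `angle2`
#'   (tau), degrees.
#' @export
theta_tau <- function(backbone) {
  per_segment(backbone, min_res = 4, function(coords, res, chain) {
    ca <- coords[["CA"]]
    n <- nrow(res)
    rows <- lapply(seq(2, n - 2), function(i) {
      tau <- tryCatch(
        dihedral_angle(ca[i - 1, ], ca[i, ], ca[i + 1, ], ca[i + 2, ]),
        error = function(e) NA_real_)
      tibble::tibble(
        chain = chain, resno = res$resno[i],
        angle1 = planar_angle(ca[i - 1, ], ca[i, ], ca[i + 1, ]),
        angle2 = tau)
    })
    dplyr::bind_rows(rows)
  })
}

per_segment <- function(backbone, min_res, fun) {
  pieces <- split(backbone,
                  interaction(backbone$chain, backbone$segment, drop = TRUE))
  out <- lapply(pieces, function(seg) {
    res <- dplyr::distinct(seg[, c("chain", "segment", "resno")])
    if (nrow(res) < min_res) return(NULL)
    coords <- lapply(c(N = "N", CA = "CA", C = "C"), function(a) {
      as.matrix(seg[seg$atom == a, c("x", "y", "z")])
    })
    fun(coords, res, seg$chain[1])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) stop("chain too short: no angles computable")
  dplyr::arrange(out, .data$chain, .data$resno)
}

#' Build backbone coordinates from torsion angles
#'
#' Constructs idealized backbone N, CA, C coordinates for `n` residues from
#' given (phi, psi, omega) torsions and canonical bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 angstrom; N-CA-C 111.2, CA-C-N 116.2,
#' C-N-CA 121.7 degrees), by sequential internal-to-Cartesian placement.
#' Useful for generating test fixtures with known dihedral angles, e.g. an
#' ideal alpha-helix with phi = -57, psi = -47.
#'
#' @param n number of residues.
#' @param phi,psi,omega torsions in degrees (recycled to length `n`).
#' @return tibble in the layout of [read_pdb_backbone()].
#' @export
backbone_from_torsions <- function(n, phi = -57, psi = -47, omega = 180) {
  stopifnot(n >= 2)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7

  atoms <- matrix(0, 3 * n, 3)
  # seed the first residue in the xy-plane
  atoms[1, ] <- c(0, 0, 0)                      # N1
  atoms[2, ] <- c(b_nca, 0, 0)                  # CA1
  ang <- (180 - a_ncac) * pi / 180
  atoms[3, ] <- atoms[2, ] + b_cac * c(cos(ang), sin(ang), 0) # C1
  k <- 3
  for (i in seq(2, n)) {
    # N_i from (N, CA, C) of residue i-1 and psi_{i-1}
    atoms[k + 1, ] <- place_atom(atoms[k - 2, ], atoms[k - 1, ], atoms[k, ],
                                 b_cn, a_cacn, psi[i - 1])
    # CA_i from (CA_{i-1}, C_{i-1}, N_i) and omega
    atoms[k + 2, ] <- place_atom(atoms[k - 1, ], atoms[k, ], atoms[k + 1, ],
                                 b_nca, a_cnca, omega[i - 1])
    # C_i from (C_{i-1}, N_i, CA_i) and phi_i
    atoms[k + 3, ] <- place_atom(atoms[k, ], atoms[k + 1, ], atoms[k + 2, ],
                                 b_cac, a_ncac, phi[i])
    k <- k + 3
  }
  tibble::tibble(
    chain = "A", segment = 1L, resno = rep(seq_len(n), each = 3),
    atom = rep(c("N", "CA", "C"), n),
    x = atoms[, 1], y = atoms[, 2], z = atoms[, 3])
}

# place D given A, B, C with bond length |CD|, angle B-C-D (deg) and torsion
# A-B-C-D (deg)
place_atom <- function(a, b, c_, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}
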