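# Shared fixtures, computed lazily and cached for the whole test run.

shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_shared_basis(m = 5, n_i = 60, K_true = 2, n_clusters = 2,
                                   seed = 101, df = c(6, 6), grid_points = 30)
      fit <- fit_collective(sim$data, K = 2, df = c(6, 6), grid_points = 30)
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})

# radian point-set list of an angle tibble, grouped
angle_groups <- function(data, domain = domain_torus()) {
  lapply(unique(data$group), function(g) {
    angledens:::angles_to_matrix(data[data$group == g, , drop = FALSE], domain)
  })
}

# write a minimal PDB file with N/CA/C atoms from a backbone tibble
write_backbone_pdb <- function(backbone, path, chain = NULL) {
  lines <- character(0)
  serial <- 0
  for (r in seq_len(nrow(backbone))) {
    serial <- serial + 1
    ch <- if (is.null(chain)) backbone$chain[r] else chain
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      serial, backbone$atom[r], "ALA", ch, backbone$resno[r],
      backbone$x[r], backbone$y[r], backbone$z[r],
      substr(backbone$atom[r], 1, 1)))
  }
  writeLines(c(lines, "END"), path)
  path
}

# random rigid motion applied to a backbone tibble
rigid_motion <- function(backbone, seed = 1) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 20)
  xyz <- as.matrix(backbone[, c("x", "y", "z")]) %*% t(R)
  backbone$x <- xyz[, 1] + shift[1]
  backbone$y <- xyz[, 2] + shift[2]
  backbone$z <- xyz[, 3] + shift[3]
  backbone
}
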