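#' Ward clustering of a distance matrix
#'
#' Agglomerative hierarchical clustering with the `ward.D` linkage of
#' [stats::hclust()] -- the dissimilarities are used as given, without
#' squaring -- and the dendrogram cut into exactly `k` clusters.
#'
#' @param D symmetric distance matrix (or `dist` object) with zero diagonal.
#' @param k number of clusters, `1 <= k <= m`.
#' @return integer cluster labels (length m, values 1..k, named by the
#'   matrix labels), with the `hclust` tree attached as attribute `"tree"`.
#' @export
ward_cluster <- function(D, k) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
    D <- stats::as.dist(D)
  }
  m <- attr(D, "Size")
  if (k < 1 || k > m) stop("k out of range")
  tree <- stats::hclust(D, method = "ward.D")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Dendrogram of a clustering in Newick format
#'
#' @param labels output of [ward_cluster()] (carrying the `"tree"`
#'   attribute), or an `hclust` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to a file.
#' @export
cluster_newick <- function(labels, path = NULL) {
  tree <- if (inherits(labels, "hclust")) labels else attr(labels, "tree")
  if (is.null(tree)) stop("no hclust tree attached")
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Contingency table of two labelings
#'
#' Cross-tabulates two partitions of the same items: `counts[i, j]` is the
#' number of items in cluster i of the first labeling and cluster j of the
#' second, with row margins `a`, column margins `b` and total `N`.
#'
#' @param labels_a,labels_b vectors of equal length.
#' @return list with `counts` (r x c matrix), `a`, `b`, `N`.
#' @export
cluster_contingency <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  counts <- unclass(table(labels_a, labels_b))
  dimnames(counts) <- unname(dimnames(counts))
  list(counts = counts, a = rowSums(counts), b = colSums(counts),
       N = sum(counts))
}

entropy_nat <- function(sizes, N) {
  p <- sizes[sizes > 0] / N
  -sum(p * log(p))
}

#' Normalized mutual information of two labelings
#'
#' \eqn{\mathrm{NMI}(A, B) = \mathrm{MI}(A, B) / \max\{H(A), H(B)\}} with
#' entropies and mutual information in natural logarithms and the convention
#' \eqn{0 \log 0 = 0}. Two identical single-cluster labelings (both entropies
#' zero) return 1.
#'
#' @param labels_a,labels_b vectors of equal length.
#' @return scalar in [0, 1]; 1 for identical partitions.
#' @export
nmi <- function(labels_a, labels_b) {
  ct <- cluster_contingency(labels_a, labels_b)
  N <- ct$N
  mi <- 0
  for (i in seq_along(ct$a)) {
    for (j in seq_along(ct$b)) {
      nij <- ct$counts[i, j]
      if (nij > 0) {
        mi <- mi + nij / N *
          log(nij * N / (unname(ct$a[i]) * unname(ct$b[j])))
      }
    }
  }
  hmax <- max(entropy_nat(ct$a, N), entropy_nat(ct$b, N))
  if (hmax == 0) return(1) # both labelings a single cluster
  mi / hmax
}

#' Adjusted Rand index of two labelings
#'
#' The Rand index adjusted for chance agreement, computed from the
#' contingency table with binomial pair counts:
#' \deqn{\mathrm{ARI} = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}
#'   {\tfrac12[\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}] - E},\quad
#'   E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{N}{2}.}
#' Equals 1 exactly for identical partitions; can be negative for labelings
#' that agree less than chance.
#'
#' @param labels_a,labels_b vectors of equal length (at least 2 items).
#' @return scalar, at most 1.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) < 2) stop("need at least two items")
  ct <- cluster_contingency(labels_a, labels_b)
  sum_nij <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$a, 2))
  sum_b <- sum(choose(ct$b, 2))
  expected <- sum_a * sum_b / choose(ct$N, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1) # both partitions trivial (all-singletons or one cluster)
  (sum_nij - expected) / denom
}

#' Cluster fitted densities and score against a gold standard
#'
#' Convenience wrapper for the downstream pipeline: SKLD distances between
#' the fitted densities of a collective fit (or a list of density grids),
#' Ward clustering, and external agreement with reference labels.
#'
#' @param densities a [fit_collective()] object or list of [density_grid()]s.
#' @param k number of clusters; defaults to the number of distinct reference
#'   labels when given.
#' @param reference optional gold-standard labels (one per group).
#' @return tibble with columns `group`, `cluster` and (when a reference is
#'   given) attributes aside: `nmi`, `ari`, plus the `hclust` tree as
#'   attribute `"tree"`.
#' @export
cluster_densities <- function(densities, k = NULL, reference = NULL) {
  if (inherits(densities, "collective_fit")) densities <- density_grids(densities)
  if (is.null(k)) {
    if (is.null(reference)) stop("supply k or reference labels")
    k <- length(unique(reference))
  }
  Dm <- density_distances(densities)
  labels <- ward_cluster(Dm, k)
  out <- tibble::tibble(group = rownames(Dm), cluster = as.integer(labels))
  attr(out, "tree") <- attr(labels, "tree")
  if (!is.null(reference)) {
    if (length(reference) != nrow(out)) stop("reference length mismatch")
    attr(out, "nmi") <- nmi(out$cluster, reference)
    attr(out, "ari") <- ari(out$cluster, reference)
  }
  out
}
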