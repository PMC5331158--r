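# Independent oracles for the cluster-agreement indices.

# NMI by naive direct summation over the contingency table
nmi_oracle <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  N <- length(a)
  mi <- 0
  for (i in ua) for (j in ub) {
    nij <- sum(a == i & b == j)
    if (nij > 0) {
      mi <- mi + (nij / N) * log((nij / N) / ((sum(a == i) / N) * (sum(b == j) / N)))
    }
  }
  ha <- -sum(sapply(ua, function(i) {
    p <- sum(a == i) / N
    p * log(p)
  }))
  hb <- -sum(sapply(ub, function(j) {
    p <- sum(b == j) / N
    p * log(p)
  }))
  if (max(ha, hb) == 0) return(1)
  mi / max(ha, hb)
}

# ARI by all-pairs concordance counting (no contingency-table formula)
ari_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

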