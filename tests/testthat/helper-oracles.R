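# Independent brute-force oracles. Deliberately naive (double loops,
# exhaustive enumeration) and independent of the package's implementations.

# All set partitions of n items as restricted-growth label vectors.
enumerate_partitions <- function(n) {
  out <- vector("list", 0L)
  rec <- function(labels, maxl) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (l in seq_len(maxl + 1L)) rec(c(labels, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# Barber modularity by direct double sum over all (patient, comorbidity)
# pairs.
oracle_q <- function(A, pl, cl) {
  k <- rowSums(A)
  dg <- colSums(A)
  m <- sum(A)
  q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (pl[i] == cl[j]) q <- q + A[i, j] - k[i] * dg[j] / m
  q / m
}

# Exhaustive-maximum modularity over every joint partition of all nodes.
oracle_best_q <- function(A) {
  n <- nrow(A)
  d <- ncol(A)
  k <- rowSums(A)
  dg <- colSums(A)
  m <- sum(A)
  pairs <- which(matrix(TRUE, n, d), arr.ind = TRUE)
  bv <- A[pairs] - k[pairs[, 1]] * dg[pairs[, 2]] / m
  best <- -Inf
  for (p in enumerate_partitions(n + d)) {
    pl <- p[seq_len(n)]
    cl <- p[n + seq_len(d)]
    q <- sum(bv[pl[pairs[, 1]] == cl[pairs[, 2]]]) / m
    if (q > best) best <- q
  }
  best
}

# Rand index by explicit pair agreement counting.
oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# C-statistic by exhaustive case-control pair counting.
oracle_c <- function(scores, y) {
  cs <- scores[as.logical(y)]
  ct <- scores[!as.logical(y)]
  tot <- 0
  for (s in cs) for (t in ct) tot <- tot + (s > t) + 0.5 * (s == t)
  tot / (length(cs) * length(ct))
}

# NRI estimate by per-subject tabulation.
oracle_nri <- function(old, new, y, cutpoints = NULL) {
  y <- as.logical(y)
  if (is.null(cutpoints)) {
    up <- new > old
    down <- new < old
  } else {
    co <- cut(old, c(-Inf, cutpoints, Inf), labels = FALSE)
    cn <- cut(new, c(-Inf, cutpoints, Inf), labels = FALSE)
    up <- cn > co
    down <- cn < co
  }
  (mean(up[y]) - mean(down[y])) + (mean(down[!y]) - mean(up[!y]))
}

# IDI estimate by per-subject tabulation.
oracle_idi <- function(old, new, y) {
  y <- as.logical(y)
  d <- new - old
  mean(d[y]) - mean(d[!y])
}
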