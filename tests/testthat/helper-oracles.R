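# Independent brute-force oracles.  Each one re-implements the bare
# definition in the most literal way possible (loops, enumeration, per-base
# scans) and is kept free of any package internals.

oracle_bicor <- function(x, y) {
  mx <- median(x); my <- median(y)
  madx <- median(abs(x - mx)); mady <- median(abs(y - my))
  if (madx == 0 || mady == 0) return(cor(x, y))
  d <- numeric(length(x)); e <- numeric(length(y))
  for (i in seq_along(x)) {
    u <- (x[i] - mx) / (9 * madx)
    w <- if (abs(u) < 1) (1 - u^2)^2 else 0
    d[i] <- (x[i] - mx) * w
    v <- (y[i] - my) / (9 * mady)
    wv <- if (abs(v) < 1) (1 - v^2)^2 else 0
    e[i] <- (y[i] - my) * wv
  }
  if (all(d == 0) || all(e == 0)) return(cor(x, y))
  sum(d * e) / sqrt(sum(d^2) * sum(e^2))
}

oracle_tom <- function(A) {
  n <- nrow(A)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      }
      ki <- sum(A[i, -i])
      kj <- sum(A[j, -j])
      out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
    }
  }
  out
}

oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  ok <- is.finite(geo) & geo > 0
  raw <- apply(counts, 2, function(col) median(col[ok] / geo[ok]))
  raw / exp(mean(log(raw)))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# P(X >= a) by direct enumeration of the hypergeometric pmf: draw a
# module of size m from a universe of N containing n set genes.
oracle_hyper_p <- function(N, m, n, a) {
  total <- choose(N, m)
  s <- 0
  for (x in seq(a, min(m, n))) {
    s <- s + choose(n, x) * choose(N - n, m - x)
  }
  s / total
}

# per-base scan on 0-based half-open intervals
oracle_cnv_counts <- function(annotation, cnvs) {
  counts <- integer(nrow(annotation))
  for (g in seq_len(nrow(annotation))) {
    bases <- seq(annotation$start[g], annotation$end[g] - 1L)
    for (k in seq_len(nrow(cnvs))) {
      if (cnvs$chrom[k] != annotation$chrom[g]) next
      cb <- seq(cnvs$start[k], cnvs$end[k] - 1L)
      if (length(intersect(bases, cb)) > 0) counts[g] <- counts[g] + 1L
    }
  }
  names(counts) <- annotation$gene_id
  counts
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small config used across tests to keep fixtures fast
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 300L, n_lncRNAs = 40L,
             module_sizes = c(40L, 30L), n_dev_background = 80L,
             n_dev_samples = 60L, n_risk_genes = 12L, n_module_lnc = 6L,
             n_cnvs = 20L, ...)
}
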