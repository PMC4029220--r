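# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# All simple paths from src to dst by depth-first enumeration; returns the
# minimum length, or Inf if unreachable.
oracleShortestByEnumeration <- function(edges, src, dst) {
  adj <- split(edges$to, edges$from)
  best <- Inf
  recurse <- function(node, pathLen, seen) {
    succ <- adj[[node]]
    if (is.null(succ)) return()
    for (nb in succ) {
      if (nb == dst) {
        best <<- min(best, pathLen + 1L)
      } else if (!(nb %in% seen) && pathLen + 1L < best) {
        recurse(nb, pathLen + 1L, c(seen, nb))
      }
    }
  }
  recurse(src, 0L, src)
  best
}

# Floyd-Warshall all-pairs unweighted distances over the node set.
oracleFloydWarshall <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges)))
    d[edges$from[i], edges$to[i]] <- 1
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Benjamini-Hochberg step-up from the definition:
# q_i = min_{j: p_(j) >= p_i over the sorted order, stepping up} p_(j) * m / j
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# AUC as the concordance probability over all (positive, negative) pairs,
# ties credited one half.
oracleAUC <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by explicit enumeration with choose().
oracleHyperUpper <- function(k, K, N, n) {
  kk <- seq(k, min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Exact one-tailed rank-sum p-value P(W_x >= w_obs) by enumeration of all
# assignments of ranks to the first sample (tie-free inputs only).
oracleRankSumGreater <- function(x, y) {
  nx <- length(x); pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  ws <- colSums(matrix(r[combos], nrow = nx))
  mean(ws >= wObs)
}

# Seeded random digraph as an edge data.frame (no self-loops, no duplicates).
randomDigraph <- function(nNodes, nEdges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(nNodes))
  from <- sample(nodes, nEdges * 3, replace = TRUE)
  to <- sample(nodes, nEdges * 3, replace = TRUE)
  keep <- from != to & !duplicated(paste(from, to))
  data.frame(from = from[keep], to = to[keep])[seq_len(min(nEdges, sum(keep))), ]
}

# Write a small TSV fixture from lines.
writeTsvLines <- function(...) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(...), f)
  f
}
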