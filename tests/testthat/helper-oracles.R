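# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities by the most literal route available (elementwise
# loops, union-find, full eigendecomposition) so they share no code with the
# implementation they check.

looped_distances <- function(xy) {
  n <- nrow(xy)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
  d
}

# union-find connectivity of the graph with edges {d_ij <= t}
connected_at <- function(D, t) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] <= t) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

# smallest threshold keeping the graph connected, by scanning sorted edges —
# an algorithmically different route to the max MST edge
min_connecting_threshold <- function(D) {
  edges <- sort(unique(D[upper.tri(D)]))
  for (t in edges) if (connected_at(D, t)) return(t)
  stop("disconnected at every threshold")
}

# literal PCoA: Gower transform, double-center with explicit loops, eigen
brute_pcoa <- function(W) {
  n <- nrow(W)
  A <- -0.5 * W^2
  B <- matrix(0, n, n)
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  for (i in seq_len(n)) for (j in seq_len(n))
    B[i, j] <- A[i, j] - rm_[i] - cm_[j] + gm
  eigen((B + t(B)) / 2, symmetric = TRUE)
}

# Moran's I by explicit double summation with binary within-t weights
looped_morans_i <- function(x, D, t) {
  n <- length(x)
  xb <- mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && D[i, j] > 0 && D[i, j] <= t) {
      num <- num + (x[i] - xb) * (x[j] - xb)
      s0 <- s0 + 1
    }
  (n / s0) * num / sum((x - xb)^2)
}

# minimal valid input tables written to a temp dir, returned as paths
write_fixture_tables <- function(dir, sites, cases, py) {
  p <- function(f) file.path(dir, f)
  utils::write.csv(sites, p("sites.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cases, p("cases.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(py, p("py.csv"), row.names = FALSE, quote = FALSE)
  list(sites = p("sites.csv"), cases = p("cases.csv"), py = p("py.csv"))
}

# a small irregular layout reused by several files (seeded, Finland-like
# magnitudes so the degree guard never trips)
fixture_sites <- function(n = 25, seed = 404) {
  makeRandomSites(n, c(200e3, 120e3), seed = seed)
}
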