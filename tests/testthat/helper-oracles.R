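# Independent brute-force oracles used to check the topology and set
# statistics. These deliberately avoid the code paths of the package (and
# of igraph where the package delegates to it): everything is computed
# from the adjacency matrix by direct enumeration.

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# BFS from one source: distances and shortest-path counts.
bfs_sigma <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(A[v, ] == 1L)) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
        if (dist[u] == dist[v] + 1) sigma[u] <- sigma[u] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# All-pairs betweenness by explicit enumeration over (s, t, v) triples:
# sigma_st(v) = sigma_s(v) * sigma_v(t) when dist_s(v) + dist_v(t) = dist_s(t).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  bf <- lapply(1:n, function(s) bfs_sigma(A, s))
  D <- t(vapply(bf, `[[`, numeric(n), "dist"))
  S <- t(vapply(bf, `[[`, numeric(n), "sigma"))
  btw <- rep(0, n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(D[s, t])) next
    on_path <- is.finite(D[s, ]) & (D[s, ] + D[t, ] == D[s, t])
    on_path[c(s, t)] <- FALSE
    btw[on_path] <- btw[on_path] +
      S[s, on_path] * S[t, on_path] / S[s, t]
  }
  names(btw) <- rownames(A)
  btw
}

oracle_local_clustering <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (v in 1:n) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) < 2L) { out[v] <- 0; next }
    links <- sum(A[nb, nb]) / 2
    out[v] <- links / choose(length(nb), 2)
  }
  names(out) <- rownames(A)
  out
}

oracle_global_stats <- function(A) {
  n <- nrow(A)
  D <- t(vapply(1:n, function(s) bfs_sigma(A, s)$dist, numeric(n)))
  finite <- is.finite(D) & upper.tri(D)
  apl <- mean(D[finite])
  # components from reachability
  comp <- rep(NA_integer_, n); cid <- 0L
  for (v in 1:n) if (is.na(comp[v])) {
    cid <- cid + 1L
    comp[is.finite(D[v, ])] <- cid
  }
  giant <- max(table(comp)) / n
  triangles <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(choose(rowSums(A), 2))
  gcc <- if (triples == 0) 0 else 3 * triangles / triples
  list(average_path_length = apl, giant_component_fraction = giant,
       global_clustering = gcc)
}

oracle_density <- function(A, S) {
  idx <- match(S, rownames(A))
  cnt <- 0
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i < j && A[idx[i], idx[j]] == 1L) cnt <- cnt + 1
  }
  cnt / choose(length(S), 2)
}

oracle_expansion <- function(A, S) {
  idx <- match(S, rownames(A))
  nb <- unique(unlist(lapply(idx, function(i) which(A[i, ] == 1L))))
  length(setdiff(rownames(A)[nb], S)) / length(S)
}

# masked-vector Pearson correlation by the direct formula
oracle_masked_pcc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# rank-then-Pearson Spearman with average ranks
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  cor(rank(x[ok]), rank(y[ok]))
}

# exact hypergeometric upper tail by summing binomial coefficients
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
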