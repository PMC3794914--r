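#' Betweenness centrality
#'
#' Classic Freeman betweenness: each pair of vertices contributes to the
#' vertices interior to its shortest paths, weighted inversely to the number
#' of distinct shortest paths; endpoints are excluded and no normalization
#' is applied (only ranks matter downstream, and normalization is
#' rank-invariant).
#'
#' @param net An `igraph` network.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Local clustering coefficient
#'
#' Number of triangles through a vertex divided by the number of connected
#' triples centered on it, `choose(degree, 2)`; defined as 0 for vertices
#' of degree below 2.
#'
#' @param net An `igraph` network.
#' @param v Optional vertex name(s); default all vertices.
#' @return Named numeric vector in `[0, 1]`.
#' @export
local_clustering <- function(net, v = NULL) {
  if (!is.null(v) && !all(v %in% igraph::V(net)$name)) {
    stop("vertex not in network")
  }
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  names(cc) <- igraph::V(net)$name
  cc[igraph::degree(net) < 2L] <- 0
  if (is.null(v)) cc else cc[v]
}

#' Newman modularity of a vertex partition
#'
#' `Q = sum_c [ e_c/m - (d_c / 2m)^2 ]` where `e_c` is the number of
#' intra-cluster edges of cluster `c`, `d_c` the total degree of its
#' vertices and `m` the edge count.
#'
#' @param net An `igraph` network with at least one edge.
#' @param clustering A clustering from [cluster_network()], or a named
#'   vector assigning every vertex to a cluster id.
#' @return Modularity `Q` in `[-1, 1]`.
#' @export
newman_modularity <- function(net, clustering) {
  assignment <- clustering_assignment(clustering)
  verts <- igraph::V(net)$name
  if (!all(verts %in% names(assignment))) stop("clustering does not cover all vertices")
  m <- igraph::ecount(net)
  if (m == 0L) stop("modularity undefined for a network with no edges")
  memb <- assignment[verts]
  el <- igraph::as_edgelist(net)
  ca <- memb[el[, 1L]]
  cb <- memb[el[, 2L]]
  e_c <- table(factor(ca[ca == cb], levels = unique(memb)))
  d_c <- rowsum(igraph::degree(net)[verts], memb)[, 1L]
  sum(e_c[names(d_c)] / m - (d_c / (2 * m))^2)
}

clustering_assignment <- function(clustering) {
  if (inherits(clustering, "ppi_clustering")) clustering$assignment else clustering
}

# Single run of the seeded density-greedy clustering backend: repeatedly
# take the highest-degree unclustered vertex as a seed, grow its cluster by
# adding the unclustered neighbor with the most links into the cluster while
# the cluster density stays >= td, and emit clusters of size >= ts;
# remaining vertices become singletons.
density_greedy_partition <- function(adj, deg, td, ts) {
  n <- length(adj)
  assigned <- integer(n)     # 0 = unassigned
  next_id <- 0L
  links <- integer(n)
  order_seeds <- order(-deg, seq_len(n))
  for (s in order_seeds) {
    if (assigned[s] != 0L) next
    members <- s
    in_cluster <- s
    e_c <- 0L
    touched <- integer(0)
    for (u in adj[[s]]) if (assigned[u] == 0L) {
      links[u] <- links[u] + 1L
      touched <- c(touched, u)
    }
    repeat {
      cand <- touched[assigned[touched] == 0L & links[touched] > 0L &
                        !(touched %in% members)]
      if (length(cand) == 0L) break
      best <- cand[order(-links[cand], cand)][1L]
      size <- length(members)
      dens <- (e_c + links[best]) / (choose(size + 1L, 2L))
      if (dens < td) break
      members <- c(members, best)
      e_c <- e_c + links[best]
      for (u in adj[[best]]) if (assigned[u] == 0L && !(u %in% members)) {
        links[u] <- links[u] + 1L
        touched <- c(touched, u)
      }
    }
    links[touched] <- 0L
    if (length(members) >= ts) {
      next_id <- next_id + 1L
      assigned[members] <- next_id
    } else {
      # too small: emit each member as a singleton so the pass terminates
      for (v in members) {
        next_id <- next_id + 1L
        assigned[v] <- next_id
      }
    }
  }
  assigned
}

#' Cluster a network, selecting parameters by Newman modularity
#'
#' Runs the clustering backend over a grid of parameter settings and keeps
#' the partition with maximal Newman modularity, the standard exhaustive
#' search used with density-based module finders. The default backend
#' is a seeded density-greedy expansion: the highest-degree unclustered
#' vertex seeds a cluster which greedily absorbs the neighbor maximizing
#' cluster density while the density stays at least `T_d`, emitting clusters
#' of at least `T_s` vertices; unclustered vertices become singletons.
#'
#' @param net A nonempty `igraph` network.
#' @param td_grid,ts_grid Grids of density thresholds `T_d` and minimum
#'   cluster sizes `T_s` searched exhaustively.
#' @param seed Unused by the deterministic default backend; kept so that
#'   stochastic backends plugged in via `backend` stay reproducible.
#' @param backend Optional function `(net, td, ts) -> named cluster-id
#'   vector` replacing the default algorithm.
#' @return Object of class `ppi_clustering`: list with `assignment` (named
#'   vector gene -> cluster id), `modularity`, `params`, and the searched
#'   `trace`.
#' @export
cluster_network <- function(net, td_grid = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                            ts_grid = c(2L, 3L, 5L), seed = NULL,
                            backend = NULL) {
  if (igraph::vcount(net) == 0L) stop("cannot cluster an empty network")
  verts <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net), as.integer)
  deg <- igraph::degree(net)
  best <- NULL
  trace <- list()
  with_seed(seed, {
    for (td in td_grid) for (ts in ts_grid) {
      if (is.null(backend)) {
        memb <- density_greedy_partition(adj, deg, td, ts)
        names(memb) <- verts
      } else {
        memb <- backend(net, td, ts)
      }
      q <- newman_modularity(net, memb)
      trace[[length(trace) + 1L]] <- list(td = td, ts = ts, modularity = q)
      if (is.null(best) || q > best$modularity) {
        best <- list(assignment = memb, modularity = q,
                     params = list(td = td, ts = ts))
      }
    }
  })
  structure(c(best, list(trace = trace)), class = "ppi_clustering")
}

#' Participation coefficient
#'
#' `P(v) = 1 - sum_c (k_c(v)/deg(v))^2` where `k_c(v)` counts the edges of
#' `v` into cluster `c` (its own cluster included): 0 when all edges go to
#' one cluster, approaching 1 as edges spread evenly over many clusters.
#' Isolated vertices get `NA`.
#'
#' @param net An `igraph` network.
#' @param clustering A clustering covering the network's vertices.
#' @param v Optional vertex name(s); default all.
#' @return Named numeric vector in `[0, 1)` with `NA` for isolated vertices.
#' @export
participation_coefficient <- function(net, clustering, v = NULL) {
  assignment <- clustering_assignment(clustering)
  verts <- igraph::V(net)$name
  memb <- assignment[verts]
  el <- igraph::as_edgelist(net)
  deg <- igraph::degree(net)
  # for each endpoint, the cluster of the opposite endpoint
  node <- c(el[, 1L], el[, 2L])
  nb_cl <- c(memb[el[, 2L]], memb[el[, 1L]])
  p <- setNames(rep(NA_real_, length(verts)), verts)
  if (length(node) > 0L) {
    cnt <- table(node, nb_cl)
    frac2 <- rowSums((cnt / rowSums(cnt))^2)
    p[rownames(cnt)] <- 1 - frac2
  }
  if (is.null(v)) p else p[v]
}

#' Global network statistics
#'
#' Average shortest-path length over connected vertex pairs, relative size
#' of the giant (largest connected) component, and the global clustering
#' coefficient (thrice the number of triangles divided by the number of
#' connected triples; 0 when the network has no connected triple).
#'
#' @param net An `igraph` network with at least one edge.
#' @return List with `average_path_length`, `giant_component_fraction`,
#'   `global_clustering`.
#' @export
global_network_stats <- function(net) {
  stopifnot(igraph::ecount(net) >= 1L)
  apl <- igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
  giant <- max(igraph::components(net)$csize) / igraph::vcount(net)
  gcc <- igraph::transitivity(net, type = "global")
  if (!is.finite(gcc)) gcc <- 0
  list(average_path_length = apl,
       giant_component_fraction = giant,
       global_clustering = gcc)
}
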