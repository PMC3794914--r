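#' Density of a vertex set
#'
#' Number of edges between members of `S` divided by the maximum possible
#' `|S|(|S|-1)/2`.
#'
#' @param net An `igraph` network.
#' @param S Character vector of at least 2 vertex names.
#' @return Density in `[0, 1]`.
#' @export
set_density <- function(net, S) {
  S <- unique(S)
  if (length(S) < 2L) stop("set density requires at least 2 vertices")
  sub <- igraph::induced_subgraph(net, S)
  igraph::ecount(sub) / choose(length(S), 2)
}

#' Expansion of a vertex set
#'
#' Size of the external neighborhood of `S` (vertices outside `S` adjacent
#' to some member) divided by `|S|`.
#'
#' @param net An `igraph` network.
#' @param S Character vector of at least 1 vertex name.
#' @return Expansion, a nonnegative real.
#' @export
set_expansion <- function(net, S) {
  S <- unique(S)
  stopifnot(length(S) >= 1L)
  adj <- igraph::adjacent_vertices(net, S)
  nb <- unique(igraph::V(net)$name[unlist(lapply(adj, as.integer))])
  length(setdiff(nb, S)) / length(S)
}

# Add-one empirical test result from an observed value and null draws.
empirical_result <- function(observed, null, direction = c("greater", "less", "two-sided")) {
  direction <- match.arg(direction)
  B <- length(null)
  p_gr <- (1 + sum(null >= observed)) / (B + 1)
  p_ls <- (1 + sum(null <= observed)) / (B + 1)
  p <- switch(direction,
              greater = p_gr,
              less = p_ls,
              `two-sided` = min(1, 2 * min(p_gr, p_ls)))
  structure(list(observed = observed, null_samples = B,
                 null_mean = mean(null), null_sd = sd(null),
                 empirical_p = p, direction = direction,
                 z = if (sd(null) > 0) (observed - mean(null)) / sd(null) else NA_real_),
            class = "empirical_test")
}

#' Empirical resampling test of a set-level statistic
#'
#' Compares the density or expansion of a hub class with the same statistic
#' for random subsets of the same size drawn from the background hubs. The
#' empirical p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (B + 1)` (mirrored for direction `"less"`,
#' doubled and capped for two-sided), so it is never exactly 0.
#'
#' @param net An `igraph` network.
#' @param S The vertex set of interest.
#' @param background Background vertex pool (at least `|S|` vertices).
#' @param statistic `"density"` or `"expansion"`.
#' @param B Number of random subsets; default 1000.
#' @param seed Integer seed.
#' @param direction Tail of the test.
#' @return An `empirical_test` object.
#' @export
empirical_set_test <- function(net, S, background, statistic = c("density", "expansion"),
                               B = 1000L, seed = NULL,
                               direction = c("greater", "less", "two-sided")) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  S <- unique(S)
  background <- unique(background)
  if (length(background) < length(S)) stop("background smaller than the test set")
  f <- if (statistic == "density") set_density else set_expansion
  observed <- f(net, S)
  null <- with_seed(seed, vapply(seq_len(B), function(i) {
    f(net, sample(background, length(S)))
  }, 0))
  empirical_result(observed, null, direction)
}

# The three global statistics as a plain numeric vector.
global_stats_vec <- function(net) {
  s <- global_network_stats(net)
  c(average_path_length = s$average_path_length,
    giant_component_fraction = s$giant_component_fraction,
    global_clustering = s$global_clustering)
}

#' Hub-removal experiment
#'
#' Removes all vertices of a hub class (with their interactions) from the
#' network at once and measures the fold change of average path length,
#' giant component fraction and global clustering relative to the intact
#' network. Each fold change is compared against `B` removals of random
#' background-hub subsets of the same size; because all vertices are
#' removed at once the result does not depend on any removal order.
#'
#' @param net An `igraph` network.
#' @param S The hub class to remove.
#' @param background Background hub pool for the null removals.
#' @param B Number of random removals; default 1000.
#' @param seed Integer seed.
#' @param direction Tail for the empirical p-values; two-sided by default
#'   since removals can shift statistics either way.
#' @return Named list over the three statistics; each element has
#'   `fold_change` and `test` (an `empirical_test` whose observed value is
#'   the fold change).
#' @export
hub_removal_experiment <- function(net, S, background, B = 1000L, seed = NULL,
                                   direction = "two-sided") {
  S <- unique(S)
  stopifnot(length(S) >= 1L)
  if (length(background) < length(S)) stop("background smaller than the removed set")
  base <- global_stats_vec(net)
  removed <- igraph::delete_vertices(net, intersect(S, igraph::V(net)$name))
  if (igraph::ecount(removed) == 0L) stop("removal empties the network")
  obs_fold <- global_stats_vec(removed) / base
  null <- with_seed(seed, vapply(seq_len(B), function(i) {
    r <- igraph::delete_vertices(net, sample(background, length(S)))
    if (igraph::ecount(r) == 0L) rep(NA_real_, 3L) else global_stats_vec(r) / base
  }, numeric(3L)))
  out <- lapply(seq_along(obs_fold), function(j) {
    nj <- null[j, ]
    nj <- nj[!is.na(nj)]
    list(fold_change = unname(obs_fold[j]),
         test = empirical_result(unname(obs_fold[j]), nj, direction))
  })
  names(out) <- names(obs_fold)
  out
}
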