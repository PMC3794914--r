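#' Identify network hubs by a degree-fraction rule
#'
#' The hub degree threshold is the largest integer `d` such that at least
#' `fraction` of all vertices have degree `>= d`; every vertex at or above
#' the threshold is a hub, so ties at the threshold can only push the hub
#' fraction above the target.
#'
#' @param net A nonempty `igraph` network.
#' @param fraction Target hub fraction; default 0.10 (top decile).
#' @return List with `threshold` (integer degree) and `hubs` (character
#'   vector of hub gene ids).
#' @export
identify_hubs <- function(net, fraction = 0.10) {
  deg <- igraph::degree(net)
  if (length(deg) == 0L) stop("empty network")
  if (all(deg == 0L)) stop("all degrees are 0; no hubs definable")
  target <- fraction * length(deg)
  for (d in sort(unique(deg), decreasing = TRUE)) {
    if (sum(deg >= d) >= target) {
      return(list(threshold = as.integer(d), hubs = names(deg)[deg >= d]))
    }
  }
  list(threshold = 1L, hubs = names(deg)[deg >= 1L])
}

#' Identify hubs of degree at least a fixed minimum
#'
#' Alternative hub rule: all vertices with degree at or above `min_degree`.
#'
#' @param net An `igraph` network.
#' @param min_degree Minimum degree; default 3.
#' @return As [identify_hubs()].
#' @export
identify_hubs_min_degree <- function(net, min_degree = 3L) {
  deg <- igraph::degree(net)
  list(threshold = as.integer(min_degree),
       hubs = names(deg)[deg >= min_degree])
}

# top-k values of x (named), extended by ties at the k-th value
top_with_ties <- function(x, k) {
  if (k <= 0L || length(x) == 0L) return(character(0))
  ord <- order(-x, names(x))
  cutoff <- x[ord][min(k, length(x))]
  names(x)[x >= cutoff]
}

#' Identify extremal hubs
#'
#' Extremal hubs are the union of the top `top_fraction` (ceiling) of hubs
#' by degree and by betweenness centrality. Ties at the cut value are all
#' included, so the set may exceed its nominal size; a fully tied feature
#' (which would make every hub extremal through that feature) triggers a
#' warning.
#'
#' @param hubs Character vector of hub gene ids.
#' @param degree Named degree vector covering the hubs.
#' @param betweenness Named betweenness vector covering the hubs, computed
#'   on the same network.
#' @param top_fraction Fraction of hubs taken from the top of each ranking.
#' @return Character vector of extremal hub ids.
#' @export
identify_extremal <- function(hubs, degree, betweenness, top_fraction = 0.05) {
  if (length(hubs) == 0L) return(character(0))
  k <- ceiling(top_fraction * length(hubs))
  d <- degree[hubs]
  b <- betweenness[hubs]
  if (length(unique(b)) == 1L || length(unique(d)) == 1L) {
    warning("degenerate ties: a fully tied ranking makes every hub extremal")
  }
  sort(union(top_with_ties(d, k), top_with_ties(b, k)))
}

#' Classify hubs into date and party hubs
#'
#' Among non-extremal hubs with a defined avPCC, the top one third
#' (ceiling) by avPCC are party hubs and the remainder are date hubs.
#' Extremal hubs are labelled `"extremal"` and hubs without a defined avPCC
#' `"unclassified"`. Ties at the party/date boundary are broken by higher
#' avPCC then lexicographic gene id, so the split is deterministic.
#'
#' @param hubs Character vector of hub ids.
#' @param extremal Character vector of extremal hub ids.
#' @param avpcc Named avPCC vector (NA = undefined).
#' @return Named character vector over `hubs` with values `"party"`,
#'   `"date"`, `"extremal"` or `"unclassified"`.
#' @export
classify_date_party <- function(hubs, extremal, avpcc) {
  lab <- setNames(rep("unclassified", length(hubs)), hubs)
  lab[hubs %in% extremal] <- "extremal"
  cand <- hubs[!(hubs %in% extremal)]
  cand <- cand[!is.na(avpcc[cand])]
  if (length(cand) < 3L) stop("fewer than 3 classifiable hubs")
  ord <- cand[order(-avpcc[cand], cand)]
  k <- ceiling(length(cand) / 3)
  lab[ord[seq_len(k)]] <- "party"
  lab[ord[-seq_len(k)]] <- "date"
  lab
}

#' Compute the per-hub feature table
#'
#' One-stop computation of the per-gene features used throughout the
#' analysis: degree, avPCC, betweenness, local clustering, participation
#' coefficient over a modularity-selected clustering, functional similarity
#' with interaction partners, hub/extremal flags and the date/party class.
#'
#' @param net An `igraph` network.
#' @param scores Optional co-expression scores ([interaction_coexpression()]
#'   data frame, score matrix, or compendium). When absent the avPCC column
#'   is `NA` and hubs with no avPCC stay unclassified.
#' @param annotations Optional `annotation_set` for functional similarity.
#' @param ontology Ontology matching `annotations`.
#' @param clustering Optional precomputed clustering; computed with
#'   [cluster_network()] defaults otherwise.
#' @param hub_fraction Hub fraction for [identify_hubs()].
#' @param extremal_fraction Top fraction for [identify_extremal()].
#' @param min_defined Minimum defined edge scores for an avPCC.
#' @param min_degree_hub_rule If non-`NULL`, use the fixed minimum-degree
#'   hub rule with this threshold instead of the fraction rule.
#' @param classify Logical; set `FALSE` to skip date/party classification
#'   (e.g. when avPCC is unavailable).
#' @param ... Passed to [cluster_network()].
#' @return List with `features` (data frame, one row per gene), `threshold`,
#'   `clustering`.
#' @export
compute_hub_features <- function(net, scores = NULL, annotations = NULL,
                                 ontology = NULL, clustering = NULL,
                                 hub_fraction = 0.10, extremal_fraction = 0.05,
                                 min_defined = 3L, min_degree_hub_rule = NULL,
                                 classify = !is.null(scores), ...) {
  verts <- igraph::V(net)$name
  deg <- igraph::degree(net)
  btw <- betweenness_centrality(net)
  cc <- local_clustering(net)
  if (is.null(clustering)) clustering <- cluster_network(net, ...)
  part <- participation_coefficient(net, clustering)
  avpcc <- if (!is.null(scores)) avpcc_table(net, scores, min_defined = min_defined) else
    setNames(rep(NA_real_, length(verts)), verts)
  funcsim <- if (!is.null(annotations)) {
    node_functional_similarity(net, annotations, ontology)
  } else setNames(rep(NA_real_, length(verts)), verts)
  hubinfo <- if (is.null(min_degree_hub_rule)) identify_hubs(net, hub_fraction) else
    identify_hubs_min_degree(net, min_degree_hub_rule)
  hubs <- hubinfo$hubs
  extremal <- identify_extremal(hubs, deg, btw, extremal_fraction)
  lab <- setNames(rep(NA_character_, length(verts)), verts)
  if (classify) {
    lab[hubs] <- classify_date_party(hubs, extremal, avpcc)
  } else {
    lab[hubs] <- "unclassified"
    lab[extremal] <- "extremal"
  }
  features <- data.frame(
    gene = verts,
    degree = as.integer(deg[verts]),
    avpcc = unname(avpcc[verts]),
    betweenness = unname(btw[verts]),
    clustering = unname(cc[verts]),
    participation = unname(part[verts]),
    funcsim = unname(funcsim[verts]),
    is_hub = verts %in% hubs,
    is_extremal = verts %in% extremal,
    date_party = unname(lab[verts]),
    stringsAsFactors = FALSE
  )
  rownames(features) <- verts
  list(features = features, threshold = hubinfo$threshold,
       clustering = clustering)
}

#' Background hubs for resampling tests
#'
#' The background population from which random hub sets are drawn is the
#' set of non-extremal hubs.
#'
#' @param features Feature table from [compute_hub_features()].
#' @return Character vector of background hub gene ids.
#' @export
background_hubs <- function(features) {
  features$gene[features$is_hub & !features$is_extremal]
}
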