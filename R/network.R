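#' @importFrom stats cor cor.test median pt quantile rbinom rnorm rpois runif
#'   sd setNames complete.cases lm phyper wilcox.test var
#' @importFrom utils read.delim write.table head modifyList
NULL

# Evidence labels are stored on edges as a single "|"-joined string so that
# igraph can carry them through subsetting; these helpers convert.
join_evidence <- function(labels) {
  if (length(labels) == 0L) return(NA_character_)
  paste(sort(unique(labels)), collapse = "|")
}

split_evidence <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1L]]
}

#' Build a clean protein-protein interaction network
#'
#' Constructs a simple undirected [igraph][igraph::graph_from_data_frame]
#' graph over gene identifiers: self-loops are dropped and duplicate
#' unordered pairs are collapsed, with their evidence labels unioned.
#'
#' @param from,to Character vectors of endpoint gene identifiers
#'   (case-sensitive opaque strings; no identifier mapping is performed).
#' @param evidence Optional character vector of evidence labels per input
#'   edge (e.g. `"y2h"`, `"cocomplex"`); multiple labels may already be
#'   joined with `"|"`.
#' @param vertices Optional character vector of vertex names to include even
#'   when isolated.
#' @return An undirected simple `igraph` object; when evidence was supplied
#'   each edge carries an `evidence` attribute with its labels joined by
#'   `"|"`.
#' @export
ppi_network <- function(from, to, evidence = NULL, vertices = NULL) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (!is.null(evidence)) {
    evidence <- as.character(evidence)[keep]
    ev <- tapply(evidence, key, function(v) {
      join_evidence(unlist(lapply(v[!is.na(v)], split_evidence)))
    })
    u <- !duplicated(key)
    edges <- data.frame(from = a[u], to = b[u],
                        evidence = as.character(ev[key[u]]),
                        stringsAsFactors = FALSE)
  } else {
    u <- !duplicated(key)
    edges <- data.frame(from = a[u], to = b[u], stringsAsFactors = FALSE)
  }
  verts <- sort(unique(c(a, b, vertices)))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Read a tab-separated edge list
#'
#' Reads a TSV with two gene-identifier columns and an optional evidence
#' column. Self-loops are deleted and duplicate interactions collapsed
#' (evidence labels unioned), so the result is always a simple graph.
#'
#' @param path Path to the TSV file.
#' @param evidence_column Optional: name (when `header = TRUE`) or integer
#'   position of the evidence-label column.
#' @param header Logical; whether the first line is a header. Not
#'   auto-detected.
#' @return An undirected simple `igraph` network.
#' @export
read_edge_list <- function(path, evidence_column = NULL, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (header && length(lines) > 0L) {
    cn <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    lines <- lines[-1L]
  } else {
    cn <- NULL
  }
  if (length(lines) == 0L) {
    stop("empty edge list: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L] + as.integer(header)
    stop("malformed edge list line ", bad, " in ", path,
         ": fewer than 2 tab-separated fields")
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  ev <- NULL
  if (!is.null(evidence_column)) {
    idx <- if (is.character(evidence_column)) {
      if (is.null(cn)) stop("evidence_column given by name requires header = TRUE")
      match(evidence_column, cn)
    } else as.integer(evidence_column)
    if (is.na(idx)) stop("evidence column not found: ", evidence_column)
    ev <- vapply(fields, function(f) if (length(f) >= idx) f[[idx]] else NA_character_, "")
  }
  ppi_network(from, to, evidence = ev)
}

#' Write a network as a sorted TSV edge list
#'
#' Endpoints are written with the lexicographically smaller gene first and
#' rows sorted, so output is deterministic and round-trips through
#' [read_edge_list()].
#'
#' @param net An `igraph` network.
#' @param path Output file path.
#' @param evidence Logical; write the evidence column when present.
#' @export
write_edge_list <- function(net, path, evidence = "evidence" %in% igraph::edge_attr_names(net)) {
  el <- igraph::as_edgelist(net)
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  df <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  if (evidence) df$evidence <- igraph::E(net)$evidence
  df <- df[order(df$a, df$b), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Extract the subnetwork supported by one evidence type
#'
#' Keeps exactly the edges whose evidence set contains `label` (an edge with
#' several labels is retained under any of them) and restricts vertices to
#' endpoints of retained edges.
#'
#' @param net An `igraph` network with an `evidence` edge attribute.
#' @param label Evidence label, e.g. `"y2h"` or `"cocomplex"`.
#' @return The evidence-restricted `igraph` network.
#' @export
evidence_subnetwork <- function(net, label) {
  if (!"evidence" %in% igraph::edge_attr_names(net)) {
    stop("network has no edge evidence attribute")
  }
  ev <- igraph::E(net)$evidence
  keep <- vapply(ev, function(x) label %in% split_evidence(x), logical(1L))
  if (!any(keep)) {
    warning("evidence label '", label, "' matches no edge; returning empty network")
  }
  sub <- igraph::subgraph_from_edges(net, igraph::E(net)[keep], delete.vertices = TRUE)
  sub
}

#' Degree table of a network
#'
#' @param net An `igraph` network.
#' @return Named integer vector of vertex degrees.
#' @export
degree_table <- function(net) {
  igraph::degree(net)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Degree-preserving randomization of a network
#'
#' Rewires the network by repeated double-edge swaps that reject self-loops
#' and multi-edges, so the result is a simple graph with exactly the
#' original degree sequence on the original vertex set. Edge evidence (a
#' property of the real interactions) is dropped from the randomized copy.
#'
#' @param net A simple undirected `igraph` network.
#' @param seed Integer seed; the same seed always yields the same rewiring.
#' @param n_swaps Number of swap attempts; defaults to 10 x |E|.
#' @return A randomized `igraph` network with identical degrees.
#' @export
degree_preserving_randomize <- function(net, seed = NULL, n_swaps = 10L * igraph::ecount(net)) {
  g <- with_seed(seed, igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = n_swaps)))
  if ("evidence" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "evidence")
  }
  g
}
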