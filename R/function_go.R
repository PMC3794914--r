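#' Construct an ontology
#'
#' A lightweight DAG of terms with parent links and a namespace per term.
#' Each namespace (`BP`, `CC`, `MF`) has a single root, and every term must
#' reach its namespace root through parent links.
#'
#' @param parents Named list mapping each term id to a character vector of
#'   parent term ids (empty for roots).
#' @param namespace Named character vector mapping each term to `"BP"`,
#'   `"CC"` or `"MF"`.
#' @return Object of class `ontology` with elements `parents`, `namespace`,
#'   `roots` (named by namespace) and a memoized ancestor table.
#' @export
ontology <- function(parents, namespace) {
  terms <- names(parents)
  stopifnot(!is.null(terms), all(terms %in% names(namespace)))
  roots <- terms[lengths(parents) == 0L]
  rn <- namespace[roots]
  if (anyDuplicated(rn)) stop("more than one root in a namespace")
  roots <- setNames(roots, rn)
  # ancestors via repeated expansion; also detects cycles
  anc <- setNames(vector("list", length(terms)), terms)
  depth_cache <- setNames(rep(NA_integer_, length(terms)), terms)
  get_anc <- function(t, seen = character(0)) {
    if (t %in% seen) stop("cycle in ontology at term ", t)
    if (!is.null(anc[[t]])) return(anc[[t]])
    ps <- parents[[t]]
    res <- ps
    for (p in ps) res <- union(res, get_anc(p, c(seen, t)))
    anc[[t]] <<- res
    res
  }
  for (t in terms) get_anc(t)
  for (t in terms) {
    ns <- namespace[[t]]
    if (!(t %in% roots) && !(roots[[ns]] %in% anc[[t]])) {
      stop("term ", t, " does not reach its namespace root")
    }
  }
  structure(list(parents = parents, namespace = namespace,
                 roots = roots, ancestors = anc),
            class = "ontology")
}

#' Depth of a term
#'
#' Length of the shortest parent path from the term to its namespace root
#' (roots have depth 0).
#'
#' @param ont An [ontology()].
#' @param t Term id(s).
#' @return Integer vector of depths.
#' @export
term_depth <- function(ont, t) {
  one <- function(term) {
    d <- 0L
    frontier <- term
    root <- ont$roots[[ont$namespace[[term]]]]
    repeat {
      if (root %in% frontier) return(d)
      frontier <- unique(unlist(ont$parents[frontier]))
      if (length(frontier) == 0L) return(NA_integer_)
      d <- d + 1L
    }
  }
  vapply(t, one, integer(1L))
}

#' Direct children of a namespace root
#'
#' @param ont An [ontology()].
#' @param ns Namespace, one of `"BP"`, `"CC"`, `"MF"`.
#' @return Character vector of broad terms.
#' @export
root_children <- function(ont, ns) {
  root <- ont$roots[[ns]]
  terms <- names(ont$parents)
  sort(terms[vapply(terms, function(t) root %in% ont$parents[[t]], logical(1L))])
}

#' Construct an annotation set
#'
#' Direct gene-to-term associations are closed upward: the propagated set
#' of a gene contains its direct terms plus all their ancestors. When the
#' association table carries evidence codes or qualifiers, rows with
#' evidence in `drop_evidence` or qualifier `NOT` are excluded, mirroring
#' curated-association filtering.
#'
#' @param direct Named list mapping gene id -> character vector of directly
#'   annotated terms, or a data frame with columns `gene`, `term` and
#'   optionally `evidence`, `qualifier`.
#' @param ont The [ontology()] the terms belong to.
#' @param drop_evidence Evidence codes to exclude (data-frame input only).
#' @return Object of class `annotation_set` with `direct` and `propagated`
#'   per-gene term lists.
#' @export
annotation_set <- function(direct, ont,
                           drop_evidence = c("IEA", "RCA", "IPI", "ND")) {
  if (is.data.frame(direct)) {
    df <- direct
    keep <- rep(TRUE, nrow(df))
    if ("evidence" %in% names(df)) keep <- keep & !(df$evidence %in% drop_evidence)
    if ("qualifier" %in% names(df)) keep <- keep & !(df$qualifier %in% "NOT")
    df <- df[keep, , drop = FALSE]
    direct <- lapply(split(as.character(df$term), as.character(df$gene)), unique)
  }
  known <- names(ont$parents)
  direct <- lapply(direct, function(ts) intersect(ts, known))
  direct <- direct[lengths(direct) > 0L]
  propagated <- lapply(direct, function(ts) {
    union(ts, unique(unlist(ont$ancestors[ts])))
  })
  structure(list(direct = direct, propagated = propagated, ontology = ont),
            class = "annotation_set")
}

# number of genes whose propagated annotation contains each term
term_gene_counts <- function(ann) {
  table(unlist(ann$propagated, use.names = FALSE))
}

#' Information content of a term
#'
#' `IC(t) = -ln(n_t / N)` where `n_t` counts genes annotated (after
#' propagation) with the term and `N` all genes carrying at least one term.
#' Terms annotating no gene are undefined (`NA`).
#'
#' @param ann An [annotation_set()].
#' @param t Term id(s).
#' @return Numeric IC values (natural log).
#' @export
term_information_content <- function(ann, t) {
  counts <- term_gene_counts(ann)
  N <- length(ann$propagated)
  if (N == 0L) stop("no annotated genes")
  n_t <- as.numeric(counts[t])
  ic <- -log(n_t / N)
  ic[is.na(n_t)] <- NA_real_
  setNames(ic, t)
}

#' Eligible terms for functional similarity
#'
#' Terms of one namespace (BP by default) at depth at least `min_depth`
#' annotating between `min_genes` and `max_genes` genes after propagation.
#'
#' @param ann An [annotation_set()].
#' @param ns Namespace; default `"BP"`.
#' @param min_depth Minimum term depth; default 2.
#' @param min_genes,max_genes Annotation-count bounds; defaults 3 and 1000.
#' @return Character vector of eligible term ids.
#' @export
eligible_terms <- function(ann, ns = "BP", min_depth = 2L,
                           min_genes = 3L, max_genes = 1000L) {
  ont <- ann$ontology
  counts <- term_gene_counts(ann)
  cand <- names(counts)[counts >= min_genes & counts <= max_genes]
  cand <- cand[ont$namespace[cand] == ns]
  cand[term_depth(ont, cand) >= min_depth]
}

#' Functional similarity of a gene pair
#'
#' The default rule is Resnik-style on annotations: the maximum information
#' content over eligible terms shared by the two genes' propagated
#' annotation sets, and 0 when they share none (in particular for
#' unannotated genes). Alternative rules: mean or sum of IC over shared
#' eligible terms.
#'
#' @param ann An [annotation_set()].
#' @param i,j Gene ids.
#' @param eligible Eligible terms from [eligible_terms()].
#' @param ic Named IC vector over (at least) the eligible terms; computed
#'   if missing.
#' @param rule `"max"` (default), `"mean"` or `"sum"` over shared terms.
#' @return Nonnegative similarity.
#' @export
pair_functional_similarity <- function(ann, i, j, eligible, ic = NULL,
                                       rule = c("max", "mean", "sum")) {
  rule <- match.arg(rule)
  if (is.null(ic)) ic <- term_information_content(ann, eligible)
  ti <- intersect(ann$propagated[[i]], eligible)
  tj <- intersect(ann$propagated[[j]], eligible)
  shared <- intersect(ti, tj)
  if (length(shared) == 0L) return(0)
  switch(rule, max = max(ic[shared]), mean = mean(ic[shared]), sum = sum(ic[shared]))
}

#' Functional similarity of network vertices
#'
#' The functional similarity of a vertex is the average of its pairwise
#' functional similarity with all interaction partners; partners without
#' eligible annotations contribute 0. Isolated vertices get `NA`.
#'
#' @param net An `igraph` network.
#' @param ann An [annotation_set()].
#' @param ont Ignored (kept for interface symmetry; the annotation set
#'   carries its ontology).
#' @param v Optional vertex name(s); default all.
#' @param rule Pair-similarity rule, see [pair_functional_similarity()].
#' @param min_depth,min_genes,max_genes Eligibility bounds.
#' @return Named numeric vector of per-vertex functional similarities.
#' @export
node_functional_similarity <- function(net, ann, ont = NULL, v = NULL,
                                       rule = "max", min_depth = 2L,
                                       min_genes = 3L, max_genes = 1000L) {
  eligible <- eligible_terms(ann, min_depth = min_depth,
                             min_genes = min_genes, max_genes = max_genes)
  ic <- term_information_content(ann, eligible)
  verts <- igraph::V(net)$name
  gene_terms <- lapply(setNames(verts, verts), function(g) {
    ts <- ann$propagated[[g]]
    if (is.null(ts)) character(0) else intersect(ts, eligible)
  })
  adj <- igraph::as_adj_list(net)
  target <- if (is.null(v)) verts else v
  out <- setNames(rep(NA_real_, length(target)), target)
  for (g in target) {
    nbrs <- verts[as.integer(adj[[g]])]
    if (length(nbrs) == 0L) next
    tg <- gene_terms[[g]]
    sims <- vapply(nbrs, function(h) {
      shared <- intersect(tg, gene_terms[[h]])
      if (length(shared) == 0L) 0 else switch(rule,
        max = max(ic[shared]), mean = mean(ic[shared]), sum = sum(ic[shared]))
    }, 0)
    out[g] <- mean(sims)
  }
  out
}

#' Broad-term GO enrichment of a hub class
#'
#' For each namespace independently, the background is restricted to genes
#' annotated with at least one term other than the namespace root; each
#' broad term (direct child of the root) with at least one annotated
#' background gene is tested with the hypergeometric upper tail and
#' Bonferroni-corrected by the number of terms tested in that namespace.
#'
#' @param hub_class Character vector of class genes (subset of background).
#' @param background Character vector of background genes (all annotated
#'   hubs, typically).
#' @param ann An [annotation_set()].
#' @param ont The matching [ontology()].
#' @param alpha Significance level on the corrected p-value; default 0.05.
#' @return Data frame with columns `namespace`, `term`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `p_bonferroni`, `enriched`.
#' @export
go_enrichment <- function(hub_class, background, ann, ont, alpha = 0.05) {
  stopifnot(all(hub_class %in% background))
  res <- list()
  for (ns in c("BP", "CC", "MF")) {
    root <- ont$roots[[ns]]
    ns_terms <- names(ont$parents)[ont$namespace == ns]
    has_ns <- vapply(background, function(g) {
      ts <- ann$propagated[[g]]
      !is.null(ts) && length(setdiff(intersect(ts, ns_terms), root)) > 0L
    }, logical(1L))
    bg <- background[has_ns]
    cls <- intersect(hub_class, bg)
    if (length(bg) == 0L) {
      warning("no annotated background genes in namespace ", ns, "; skipped")
      next
    }
    broad <- root_children(ont, ns)
    Ks <- vapply(broad, function(t) {
      sum(vapply(bg, function(g) t %in% ann$propagated[[g]], logical(1L)))
    }, 0L)
    broad <- broad[Ks > 0L]
    Ks <- Ks[Ks > 0L]
    if (length(broad) == 0L) next
    N <- length(bg); n <- length(cls)
    for (idx in seq_along(broad)) {
      t <- broad[[idx]]; K <- Ks[[idx]]
      k <- sum(vapply(cls, function(g) t %in% ann$propagated[[g]], logical(1L)))
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        namespace = ns, term = t, k = k, n = n, K = K, N = N,
        p_raw = p, p_bonferroni = min(1, p * length(broad)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame())
  out$enriched <- out$p_bonferroni < alpha
  out
}

#' Read an ontology from a TSV
#'
#' Expected columns: `term`, `parent` (empty or `NA` for roots; repeated
#' rows for multiple parents), `namespace`.
#'
#' @param path TSV path.
#' @return An [ontology()].
#' @export
read_ontology_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  terms <- unique(df$term)
  parents <- lapply(setNames(terms, terms), function(t) {
    p <- df$parent[df$term == t]
    p <- p[!is.na(p) & nzchar(p)]
    unique(p)
  })
  ns <- setNames(df$namespace[match(terms, df$term)], terms)
  ontology(parents, ns)
}

#' Write an ontology as a TSV
#' @param ont An [ontology()].
#' @param path Output path.
#' @export
write_ontology_tsv <- function(ont, path) {
  rows <- lapply(names(ont$parents), function(t) {
    ps <- ont$parents[[t]]
    if (length(ps) == 0L) ps <- ""
    data.frame(term = t, parent = ps, namespace = ont$namespace[[t]],
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene-term associations from a TSV
#'
#' Columns: `gene`, `term`, optional `evidence` and `qualifier`.
#'
#' @param path TSV path.
#' @param ont The [ontology()] terms belong to.
#' @param ... Passed to [annotation_set()].
#' @return An [annotation_set()].
#' @export
read_associations_tsv <- function(path, ont, ...) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  annotation_set(df, ont, ...)
}

#' Write direct gene-term associations as a TSV
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @export
write_associations_tsv <- function(ann, path) {
  df <- data.frame(
    gene = rep(names(ann$direct), lengths(ann$direct)),
    term = unlist(ann$direct, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
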