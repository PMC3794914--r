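#' Construct an expression dataset
#'
#' A raw expression dataset is a genes x experiments matrix with missing
#' values allowed, a replicate-group label per experiment column, and a flag
#' saying whether values are absolute signal intensities (which are
#' log-transformed during processing) or already relative.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   experiment columns.
#' @param replicate_groups Character vector, one replicate-group id per
#'   column; replicates of the same experiment share a group id.
#' @param is_absolute Logical; `TRUE` for absolute signal values.
#' @param id Dataset identifier.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, replicate_groups = colnames(values),
                               is_absolute = FALSE, id = "dataset") {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (is.null(replicate_groups)) replicate_groups <- paste0("e", seq_len(ncol(values)))
  stopifnot(length(replicate_groups) == ncol(values))
  structure(list(values = values,
                 replicate_groups = as.character(replicate_groups),
                 is_absolute = isTRUE(is_absolute),
                 id = id, processed = FALSE),
            class = "expression_dataset")
}

#' Process a raw expression dataset
#'
#' Processing follows the standard compendium recipe: replicates of the same
#' experiment are merged by averaging over known values; genes with less
#' than `min_known_fraction` known values are removed; a log transform is
#' applied when the dataset holds absolute signal values; and every
#' remaining experiment column is transformed to z-scores over its known
#' values. Columns left with fewer than 2 known values or zero variance are
#' dropped with a warning, since their z-scores are undefined.
#'
#' @param raw An `expression_dataset`.
#' @param min_known_fraction Minimum fraction of known (merged) values a
#'   gene must have to be retained; default 0.5.
#' @param log_base Base of the log transform for absolute signals.
#' @param log_floor Values below this positive floor are clamped before the
#'   log (absolute signals only).
#' @return The processed `expression_dataset` (replicates merged, columns
#'   z-scored, `processed = TRUE`).
#' @export
process_dataset <- function(raw, min_known_fraction = 0.5,
                            log_base = 2, log_floor = 1.0) {
  stopifnot(inherits(raw, "expression_dataset"))
  if (isTRUE(raw$processed)) return(raw)
  M <- raw$values
  if (nrow(M) == 0L || ncol(M) == 0L) stop("empty expression matrix")
  groups <- unique(raw$replicate_groups)
  merged <- vapply(groups, function(g) {
    cols <- M[, raw$replicate_groups == g, drop = FALSE]
    v <- rowMeans(cols, na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    v
  }, numeric(nrow(M)))
  merged <- matrix(merged, nrow = nrow(M),
                   dimnames = list(rownames(M), groups))
  known <- rowMeans(!is.na(merged))
  merged <- merged[known >= min_known_fraction, , drop = FALSE]
  if (raw$is_absolute) {
    merged <- log(pmax(merged, log_floor), base = log_base)
  }
  keep_col <- logical(ncol(merged))
  for (j in seq_len(ncol(merged))) {
    v <- merged[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L || sd(v[ok]) == 0) {
      keep_col[j] <- FALSE
    } else {
      merged[ok, j] <- (v[ok] - mean(v[ok])) / sd(v[ok])
      keep_col[j] <- TRUE
    }
  }
  if (!all(keep_col)) {
    warning(sum(!keep_col), " column(s) with undefined z-scores dropped in dataset ", raw$id)
    merged <- merged[, keep_col, drop = FALSE]
  }
  out <- raw
  out$values <- merged
  out$replicate_groups <- colnames(merged)
  out$processed <- TRUE
  out
}

#' Assemble a processed expression compendium
#'
#' Datasets are processed (if not already) and weighted proportionally to
#' the number of expression datapoints each contributed, counted as retained
#' genes x retained experiment columns.
#'
#' @param datasets List of `expression_dataset` objects.
#' @param ... Passed on to [process_dataset()].
#' @return Object of class `expression_compendium` with elements `datasets`
#'   and `weights`.
#' @export
expression_compendium <- function(datasets, ...) {
  stopifnot(length(datasets) > 0L)
  processed <- lapply(datasets, process_dataset, ...)
  weights <- vapply(processed, function(d) as.numeric(nrow(d$values)) * ncol(d$values), 0)
  stopifnot(all(weights > 0))
  structure(list(datasets = processed, weights = weights),
            class = "expression_compendium")
}

#' Pearson correlation of two profiles with missing values
#'
#' Uses only the dimensions where both profiles are known. Returns `NA` when
#' fewer than `min_shared` shared dimensions remain or either restricted
#' profile has zero variance (2 shared points always give |PCC| = 1, which
#' carries no information).
#'
#' @param x,y Numeric vectors on the same experiment axis; `NA` = unknown.
#' @param min_shared Minimum number of shared known dimensions; default 3.
#' @return The PCC in `[-1, 1]`, or `NA` if undefined.
#' @export
pairwise_pcc <- function(x, y, min_shared = 3L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_shared) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Gene-by-gene co-expression score matrix of a compendium
#'
#' For every pair of genes the PCC is computed within each dataset
#' independently over pairwise-known dimensions, then the per-dataset PCCs
#' are averaged with weights proportional to the datapoints each dataset
#' contributed, renormalized over the datasets where the PCC is defined.
#' Pairs defined in no dataset get `NA`.
#'
#' @param comp An `expression_compendium`.
#' @param genes Optional character vector fixing the row/column gene order;
#'   defaults to the union of genes across datasets.
#' @param min_shared Minimum shared known dimensions for a defined PCC.
#' @return A symmetric numeric matrix of co-expression scores with `NA`
#'   where undefined.
#' @export
coexpression_matrix <- function(comp, genes = NULL, min_shared = 3L) {
  stopifnot(inherits(comp, "expression_compendium"))
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(comp$datasets, function(d) rownames(d$values)))))
  }
  p <- length(genes)
  S <- matrix(0, p, p, dimnames = list(genes, genes))
  W <- matrix(0, p, p)
  for (k in seq_along(comp$datasets)) {
    d <- comp$datasets[[k]]
    M <- matrix(NA_real_, p, ncol(d$values), dimnames = list(genes, NULL))
    common <- intersect(genes, rownames(d$values))
    M[common, ] <- d$values[common, , drop = FALSE]
    r <- suppressWarnings(cor(t(M), use = "pairwise.complete.obs"))
    K <- !is.na(M)
    n <- tcrossprod(K * 1)
    r[n < min_shared] <- NA_real_
    r[!is.finite(r)] <- NA_real_
    def <- !is.na(r)
    r[!def] <- 0
    S <- S + comp$weights[k] * r
    W <- W + comp$weights[k] * def
  }
  out <- S / W
  out[W == 0] <- NA_real_
  out
}

#' Co-expression scores for the interactions of a network
#'
#' @param net An `igraph` network.
#' @param comp An `expression_compendium`, or a precomputed score matrix
#'   from [coexpression_matrix()].
#' @param min_shared Minimum shared known dimensions for a defined PCC.
#' @return Data frame with columns `from`, `to`, `score` (NA where the
#'   co-expression score is undefined), one row per network edge.
#' @export
interaction_coexpression <- function(net, comp, min_shared = 3L) {
  el <- igraph::as_edgelist(net)
  if (inherits(comp, "expression_compendium")) {
    comp <- coexpression_matrix(comp, min_shared = min_shared)
  }
  score <- rep(NA_real_, nrow(el))
  ia <- match(el[, 1L], rownames(comp))
  ib <- match(el[, 2L], rownames(comp))
  ok <- !is.na(ia) & !is.na(ib)
  score[ok] <- comp[cbind(ia[ok], ib[ok])]
  data.frame(from = el[, 1L], to = el[, 2L], score = score,
             stringsAsFactors = FALSE)
}

#' Average co-expression (avPCC) of every vertex
#'
#' The avPCC of a vertex is the sum of the defined co-expression scores of
#' its interactions divided by its degree: interactions with no defined
#' score stay in the denominator, i.e. unknown edge scores are effectively
#' counted as 0. A vertex is scored only if it has at least `min_defined`
#' interactions with a defined score; otherwise its avPCC is `NA`.
#'
#' @param net An `igraph` network.
#' @param scores Edge scores from [interaction_coexpression()] (or a score
#'   matrix / compendium, converted internally).
#' @param min_defined Minimum number of interactions with defined scores.
#' @return Named numeric vector of avPCC values over all vertices.
#' @export
avpcc_table <- function(net, scores, min_defined = 3L) {
  if (!is.data.frame(scores)) scores <- interaction_coexpression(net, scores)
  verts <- igraph::V(net)$name
  deg <- igraph::degree(net)
  ends <- c(scores$from, scores$to)
  sc <- rep(scores$score, 2L)
  def <- !is.na(sc)
  ssum <- rowsum(ifelse(def, sc, 0), ends, reorder = FALSE)
  scount <- rowsum(def * 1L, ends, reorder = FALSE)
  out <- setNames(rep(NA_real_, length(verts)), verts)
  idx <- match(rownames(ssum), verts)
  vals <- ssum[, 1L] / deg[idx]
  vals[scount[, 1L] < min_defined] <- NA_real_
  out[idx] <- vals
  out[deg == 0L] <- NA_real_
  out
}

#' avPCC of one hub
#'
#' @inheritParams avpcc_table
#' @param hub A vertex name; must be in the network.
#' @return The hub's avPCC, or `NA` when fewer than `min_defined` of its
#'   interactions have a defined co-expression score.
#' @export
hub_avpcc <- function(net, scores, hub, min_defined = 3L) {
  if (!hub %in% igraph::V(net)$name) stop("vertex not in network: ", hub)
  unname(avpcc_table(net, scores, min_defined = min_defined)[hub])
}

#' Read an expression dataset pair of TSV files
#'
#' The expression TSV has gene ids in the first column and one experiment
#' per remaining column, with missing values written as `NA`. The design
#' TSV maps each experiment column to its replicate group and carries the
#' dataset id and absolute-signal flag.
#'
#' @param values_path Expression matrix TSV.
#' @param design_path Design TSV with columns `experiment`,
#'   `replicate_group`, `dataset`, `is_absolute`.
#' @return A list of raw `expression_dataset` objects, one per dataset id
#'   in the design.
#' @export
read_expression_tsv <- function(values_path, design_path) {
  tab <- read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(M) <- as.character(tab[[1L]])
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  stopifnot(all(c("experiment", "replicate_group", "dataset") %in% names(design)))
  lapply(split(design, design$dataset), function(d) {
    cols <- match(d$experiment, colnames(M))
    if (anyNA(cols)) stop("design refers to unknown experiment columns")
    expression_dataset(M[, cols, drop = FALSE],
                       replicate_groups = d$replicate_group,
                       is_absolute = isTRUE(as.logical(d$is_absolute[1L])),
                       id = as.character(d$dataset[1L]))
  })
}

#' Write an expression dataset list as a TSV pair
#'
#' Inverse of [read_expression_tsv()]; columns of different datasets are
#' concatenated and disambiguated by dataset id.
#'
#' @param datasets List of raw `expression_dataset` objects.
#' @param values_path,design_path Output paths.
#' @export
write_expression_tsv <- function(datasets, values_path, design_path) {
  genes <- sort(unique(unlist(lapply(datasets, function(d) rownames(d$values)))))
  mats <- list(); design <- list()
  for (d in datasets) {
    cn <- paste(d$id, colnames(d$values), sep = ".")
    M <- matrix(NA_real_, length(genes), ncol(d$values),
                dimnames = list(genes, cn))
    M[rownames(d$values), ] <- d$values
    mats[[d$id]] <- M
    design[[d$id]] <- data.frame(experiment = cn,
                                 replicate_group = d$replicate_groups,
                                 dataset = d$id,
                                 is_absolute = d$is_absolute,
                                 stringsAsFactors = FALSE)
  }
  all <- do.call(cbind, mats)
  out <- data.frame(gene = genes, all, check.names = FALSE)
  write.table(out, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, design), design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
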