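#' Spearman rank correlation
#'
#' Average-rank tie handling, restricted to genes where both values are
#' defined; the p-value comes from the t approximation.
#'
#' @param x,y Numeric vectors (aligned, `NA` = undefined).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs")
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Partial Spearman rank correlation
#'
#' All variables are rank-transformed (average ranks), `x` and `y` are
#' residualized on the covariates by least squares, and the Pearson
#' correlation of the residuals is reported with a t-based p-value on
#' `n - 2 - #covariates` degrees of freedom. With no covariates this equals
#' the plain Spearman correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates A numeric vector, list of vectors, or matrix of
#'   covariates (possibly empty).
#' @return List with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) covariates <- list()
  if (is.numeric(covariates) && !is.matrix(covariates)) covariates <- list(covariates)
  if (is.matrix(covariates)) covariates <- lapply(seq_len(ncol(covariates)), function(j) covariates[, j])
  if (length(covariates) == 0L) return(spearman_cor(x, y))
  Z <- do.call(cbind, covariates)
  ok <- !is.na(x) & !is.na(y) & apply(!is.na(Z), 1L, all)
  n <- sum(ok)
  k <- ncol(Z)
  if (n < k + 3L) stop("too few complete cases for partial correlation")
  Zc <- Z[ok, , drop = FALSE]
  const <- apply(Zc, 2L, function(z) length(unique(z)) == 1L)
  if (any(const)) {
    nm <- colnames(Zc)[const]
    if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("covariate ", which(const))
    stop("constant covariate: ", paste(nm, collapse = ", "))
  }
  rx <- rank(x[ok]); ry <- rank(y[ok])
  rz <- apply(Zc, 2L, rank)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  r <- cor(ex, ey)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tval), df), n = n)
}

#' Mann-Whitney U comparison of a feature between two hub groups
#'
#' Two-sided Mann-Whitney U test with tie correction and the normal
#' approximation, reporting both group medians.
#'
#' @param features Feature table (data frame with a `gene` column).
#' @param group_a,group_b Character vectors of gene ids.
#' @param feature_name Column of `features` to compare.
#' @return List with `U`, `p`, `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
compare_groups_mannwhitney <- function(features, group_a, group_b, feature_name) {
  v <- setNames(features[[feature_name]], features$gene)
  a <- v[intersect(group_a, names(v))]; a <- a[!is.na(a)]
  b <- v[intersect(group_b, names(v))]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) stop("each group needs >= 3 genes with the feature defined")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       median_a = median(a), median_b = median(b),
       n_a = length(a), n_b = length(b))
}

hub_feature_names <- c("avpcc", "clustering", "betweenness", "participation", "funcsim")

# Recompute the network-derived hub features (and avPCC via score lookup)
# on a randomized copy of the network. Clustering reuses the parameter
# setting selected on the real network.
features_on_randomized <- function(net, seed, score_matrix = NULL,
                                   ann = NULL, cluster_params = list(td = 0.5, ts = 3L),
                                   hub_fraction = 0.10) {
  g <- degree_preserving_randomize(net, seed = seed)
  cl <- cluster_network(g, td_grid = cluster_params$td, ts_grid = cluster_params$ts)
  feats <- data.frame(gene = igraph::V(g)$name, stringsAsFactors = FALSE)
  feats$betweenness <- unname(betweenness_centrality(g))
  feats$clustering <- unname(local_clustering(g))
  feats$participation <- unname(participation_coefficient(g, cl))
  feats$avpcc <- if (!is.null(score_matrix)) unname(avpcc_table(g, score_matrix)) else NA_real_
  feats$funcsim <- if (!is.null(ann)) unname(node_functional_similarity(g, ann)) else NA_real_
  rownames(feats) <- feats$gene
  feats
}

#' Pairwise hub-feature correlations with randomized-network controls
#'
#' Computes all pairwise Spearman correlations among avPCC, clustering,
#' betweenness, participation and functional similarity over the hubs
#' (extremal hubs included), and as a control recomputes the
#' network-derived features on `n_random` degree-preserving randomizations
#' of the network (expression and annotations held fixed) to report the
#' mean and sd of each correlation under the null.
#'
#' @param features Feature table from [compute_hub_features()].
#' @param net The network the features were computed on.
#' @param n_random Number of randomized control networks; default 20.
#' @param seed Integer seed.
#' @param score_matrix Optional co-expression score matrix for avPCC on the
#'   randomized copies.
#' @param ann Optional [annotation_set()] for functional similarity on the
#'   randomized copies.
#' @param cluster_params Clustering parameters (list with `td`, `ts`) reused
#'   on the randomized copies.
#' @param feature_names Feature columns to correlate.
#' @return Data frame with one row per feature pair: `rho`, `p`, `n`, and
#'   when controls were computed `control_mean_rho`, `control_sd_rho`.
#' @export
feature_correlation_matrix <- function(features, net, n_random = 20L, seed = NULL,
                                       score_matrix = NULL, ann = NULL,
                                       cluster_params = list(td = 0.5, ts = 3L),
                                       feature_names = hub_feature_names) {
  hubs <- features[features$is_hub, , drop = FALSE]
  pairs <- utils::combn(feature_names, 2L)
  obs <- apply(pairs, 2L, function(pr) {
    s <- try(spearman_cor(hubs[[pr[1L]]], hubs[[pr[2L]]]), silent = TRUE)
    if (inherits(s, "try-error")) list(rho = NA_real_, p = NA_real_, n = 0L) else s
  })
  out <- data.frame(feature_a = pairs[1L, ], feature_b = pairs[2L, ],
                    rho = vapply(obs, `[[`, 0, "rho"),
                    p = vapply(obs, `[[`, 0, "p"),
                    n = vapply(obs, function(o) as.integer(o$n), 0L),
                    stringsAsFactors = FALSE)
  if (n_random > 0L) {
    seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_random))
    ctrl <- array(NA_real_, dim = c(ncol(pairs), n_random))
    for (r in seq_len(n_random)) {
      rf <- features_on_randomized(net, seeds[r], score_matrix = score_matrix,
                                   ann = ann, cluster_params = cluster_params)
      rf <- rf[hubs$gene, , drop = FALSE]
      for (jp in seq_len(ncol(pairs))) {
        s <- try(spearman_cor(rf[[pairs[1L, jp]]], rf[[pairs[2L, jp]]]), silent = TRUE)
        if (!inherits(s, "try-error")) ctrl[jp, r] <- s$rho
      }
    }
    out$control_mean_rho <- rowMeans(ctrl, na.rm = TRUE)
    out$control_sd_rho <- apply(ctrl, 1L, sd, na.rm = TRUE)
  }
  out
}

#' Expected avPCC under degree-preserving network randomization
#'
#' For each gene, the mean of its avPCC over `n_random` degree-preserving
#' randomized copies of the network (expression held fixed). The result is
#' used as a partial-correlation covariate capturing how much avPCC a gene
#' would show given only its degree and the expression compendium.
#'
#' @param net An `igraph` network.
#' @param score_matrix Co-expression score matrix from
#'   [coexpression_matrix()].
#' @param genes Genes to report; default all vertices.
#' @param n_random Number of randomized networks; default 100.
#' @param seed Integer seed.
#' @param min_defined Minimum defined edge scores for a per-network avPCC.
#' @return Named numeric vector; `NA` for genes whose avPCC was defined in
#'   no randomization.
#' @export
avpcc_rand <- function(net, score_matrix, genes = igraph::V(net)$name,
                       n_random = 100L, seed = NULL, min_defined = 3L) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_random))
  acc <- setNames(rep(0, length(genes)), genes)
  cnt <- setNames(rep(0L, length(genes)), genes)
  for (r in seq_len(n_random)) {
    g <- degree_preserving_randomize(net, seed = seeds[r])
    av <- avpcc_table(g, score_matrix, min_defined = min_defined)[genes]
    ok <- !is.na(av)
    acc[ok] <- acc[ok] + av[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

srcc_row <- function(feature, target, type, x, y, covariates = NULL) {
  res <- try(if (is.null(covariates)) spearman_cor(x, y) else
    partial_spearman(x, y, covariates), silent = TRUE)
  if (inherits(res, "try-error") || is.na(res$rho)) {
    data.frame(feature = feature, target = target, type = type,
               rho = NA_real_, p = NA_real_, n = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature = feature, target = target, type = type,
               rho = res$rho, p = res$p, n = res$n, stringsAsFactors = FALSE)
  }
}

#' Genetic-interaction degree per gene
#'
#' @param genetic_edges Data frame with columns `from`, `to` and optionally
#'   `sign` (`"+"`/`"-"`).
#' @param genes Genes to report counts for.
#' @return Data frame with `genetic_degree` and, when signs are present,
#'   `genetic_degree_neg` / `genetic_degree_pos`, one row per gene.
#' @export
genetic_degree_table <- function(genetic_edges, genes) {
  ends <- c(genetic_edges$from, genetic_edges$to)
  tot <- table(ends)
  out <- data.frame(gene = genes,
                    genetic_degree = as.integer(ifelse(is.na(tot[genes]), 0L, tot[genes])),
                    stringsAsFactors = FALSE)
  if ("sign" %in% names(genetic_edges)) {
    sg <- rep(genetic_edges$sign, 2L)
    for (s in c("-", "+")) {
      tt <- table(ends[sg == s])
      col <- if (s == "-") "genetic_degree_neg" else "genetic_degree_pos"
      out[[col]] <- as.integer(ifelse(is.na(tt[genes]), 0L, tt[genes]))
    }
  }
  rownames(out) <- genes
  out
}

#' Associations of hub features with genetic degree and essentiality
#'
#' Spearman correlations of each hub feature with the genetic-interaction
#' degree (plus negative/positive sub-counts when edge signs are present)
#' and with the 0/1 essentiality indicator, over hubs (extremal hubs
#' included). Partial variants corrected for essentiality and, when
#' supplied, for the randomized-network avPCC covariate are reported
#' alongside. A constant label yields an `NA` row rather than an error.
#'
#' @param features Feature table from [compute_hub_features()].
#' @param genetic_edges Optional genetic-interaction edge data frame
#'   (`from`, `to`, optional `sign`).
#' @param essential Optional character vector of essential genes.
#' @param avpcc_rand_values Optional named covariate from [avpcc_rand()].
#' @param feature_names Feature columns to correlate.
#' @return Data frame of correlation rows (`feature`, `target`, `type`,
#'   `rho`, `p`, `n`).
#' @export
label_associations <- function(features, genetic_edges = NULL, essential = NULL,
                               avpcc_rand_values = NULL,
                               feature_names = hub_feature_names) {
  hubs <- features[features$is_hub, , drop = FALSE]
  rows <- list()
  ess <- if (!is.null(essential)) as.numeric(hubs$gene %in% essential) else NULL
  if (!is.null(genetic_edges)) {
    gd <- genetic_degree_table(genetic_edges, hubs$gene)
    gd_cols <- setdiff(names(gd), "gene")
    for (f in feature_names) for (gcol in gd_cols) {
      rows[[length(rows) + 1L]] <- srcc_row(f, gcol, "plain", hubs[[f]], gd[[gcol]])
      if (!is.null(ess) && length(unique(ess)) > 1L) {
        rows[[length(rows) + 1L]] <- srcc_row(f, gcol, "partial_essentiality",
                                              hubs[[f]], gd[[gcol]], ess)
      }
    }
  }
  if (!is.null(ess)) {
    for (f in feature_names) {
      if (length(unique(ess)) <= 1L) {
        rows[[length(rows) + 1L]] <- srcc_row(f, "essential", "plain", hubs[[f]], rep(NA_real_, nrow(hubs)))
      } else {
        rows[[length(rows) + 1L]] <- srcc_row(f, "essential", "plain", hubs[[f]], ess)
      }
    }
  }
  if (!is.null(avpcc_rand_values)) {
    ar <- avpcc_rand_values[hubs$gene]
    if (!is.null(genetic_edges)) {
      gd <- genetic_degree_table(genetic_edges, hubs$gene)
      for (f in feature_names) {
        rows[[length(rows) + 1L]] <- srcc_row(f, "genetic_degree", "partial_avpcc_rand",
                                              hubs[[f]], gd$genetic_degree, ar)
      }
    }
    if (!is.null(ess) && length(unique(ess)) > 1L) {
      for (f in feature_names) {
        rows[[length(rows) + 1L]] <- srcc_row(f, "essential", "partial_avpcc_rand",
                                              hubs[[f]], ess, ar)
      }
    }
  }
  do.call(rbind, rows)
}

#' Associations of hub features with interaction-evidence counts
#'
#' Counts each hub's interactions by evidence label (a hub with no edge of
#' a type counts 0, it is not missing) and reports the Spearman correlation
#' of every feature with every evidence count over hubs.
#'
#' @param features Feature table.
#' @param net Network with an `evidence` edge attribute.
#' @param feature_names Feature columns to correlate.
#' @return Data frame of correlation rows as in [label_associations()].
#' @export
evidence_type_associations <- function(features, net,
                                       feature_names = hub_feature_names) {
  if (!"evidence" %in% igraph::edge_attr_names(net)) {
    stop("network has no edge evidence labels")
  }
  el <- igraph::as_edgelist(net)
  ev <- lapply(igraph::E(net)$evidence, split_evidence)
  labels <- sort(unique(unlist(ev)))
  if (length(labels) == 0L) stop("network has no edge evidence labels")
  hubs <- features[features$is_hub, , drop = FALSE]
  rows <- list()
  for (lb in labels) {
    has <- vapply(ev, function(e) lb %in% e, logical(1L))
    ends <- c(el[has, 1L], el[has, 2L])
    cnt <- table(ends)
    counts <- as.integer(ifelse(is.na(cnt[hubs$gene]), 0L, cnt[hubs$gene]))
    for (f in feature_names) {
      rows[[length(rows) + 1L]] <- srcc_row(f, paste0("n_", lb), "plain",
                                            hubs[[f]], counts)
    }
  }
  do.call(rbind, rows)
}
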