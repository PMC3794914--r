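#' Read an ortholog map TSV
#'
#' Columns: `gene1`, `gene2`, optional `family_id`. A gene may appear in
#' several pairs when it has more than one ortholog.
#'
#' @param path TSV path.
#' @return Data frame with columns `gene1`, `gene2` (and `family_id` when
#'   present).
#' @export
read_ortholog_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

# Restrict an ortholog map to pairs where both sides are non-extremal hubs
# with the feature defined; returns the pair indices into each value vector.
usable_ortholog_pairs <- function(feat1, feat2, map, feature_name) {
  h1 <- feat1[feat1$is_hub & !feat1$is_extremal & !is.na(feat1[[feature_name]]), ]
  h2 <- feat2[feat2$is_hub & !feat2$is_extremal & !is.na(feat2[[feature_name]]), ]
  i1 <- match(map$gene1, h1$gene)
  i2 <- match(map$gene2, h2$gene)
  ok <- !is.na(i1) & !is.na(i2)
  list(v1 = setNames(h1[[feature_name]], h1$gene),
       v2 = setNames(h2[[feature_name]], h2$gene),
       g1 = map$gene1[ok], g2 = map$gene2[ok])
}

#' Cross-network conservation of a hub feature over ortholog pairs
#'
#' Spearman correlation of a feature across ortholog pairs of non-extremal
#' hubs in two networks. Because a hub can contribute to several pairs, the
#' analytic p-value overstates the effective sample size, so an empirical
#' p-value is also computed by permuting the feature values over the hubs
#' within each network (which preserves the ortholog-map topology and its
#' induced dependence) and recomputing the correlation `B` times.
#'
#' @param feat1,feat2 Feature tables of the two networks.
#' @param map Ortholog map data frame (`gene1` in network 1, `gene2` in
#'   network 2).
#' @param feature_name Feature column to compare.
#' @param B Number of permutations; default 1000.
#' @param seed Integer seed.
#' @param direction Tail for the empirical p; conservation predicts a
#'   positive correlation, so `"greater"` by default.
#' @return List with `rho`, `p`, `empirical_p`, `n_pairs`, `null_mean`,
#'   `null_sd`.
#' @export
ortholog_feature_correlation <- function(feat1, feat2, map, feature_name,
                                         B = 1000L, seed = NULL,
                                         direction = "greater") {
  u <- usable_ortholog_pairs(feat1, feat2, map, feature_name)
  if (length(u$g1) < 3L) stop("fewer than 3 usable ortholog pairs")
  x <- u$v1[u$g1]; y <- u$v2[u$g2]
  obs <- spearman_cor(x, y)
  null <- with_seed(seed, vapply(seq_len(B), function(b) {
    p1 <- setNames(sample(u$v1), names(u$v1))
    p2 <- setNames(sample(u$v2), names(u$v2))
    suppressWarnings(cor(p1[u$g1], p2[u$g2], method = "spearman"))
  }, 0))
  et <- empirical_result(obs$rho, null, direction)
  list(rho = obs$rho, p = obs$p, empirical_p = et$empirical_p,
       n_pairs = length(u$g1), null_mean = et$null_mean, null_sd = et$null_sd)
}

count_pairs_between <- function(g1, g2, set1, set2) {
  sum(g1 %in% set1 & g2 %in% set2)
}

#' Conservation between feature-ranked thirds of two hub sets
#'
#' Ranks the usable hubs of each network by a feature, takes the top and
#' bottom thirds (ceiling), and counts ortholog pairs between each
#' combination of groups. Each count is compared with `B` draws of random
#' hub groups of the same sizes in each network, yielding a z-score and an
#' add-one empirical p-value per cell. If the low range of the feature is
#' conserved as much as the high range, both diagonal cells (top-top and
#' bottom-bottom) are enriched.
#'
#' @inheritParams ortholog_feature_correlation
#' @param direction Tail for the empirical p-values; default two-sided.
#' @return Data frame with one row per cell (`group1`, `group2`, `count`,
#'   `null_mean`, `null_sd`, `z`, `empirical_p`).
#' @export
thirds_conservation <- function(feat1, feat2, map, feature_name,
                                B = 1000L, seed = NULL, direction = "two-sided") {
  u <- usable_ortholog_pairs(feat1, feat2, map, feature_name)
  if (length(u$v1) < 6L || length(u$v2) < 6L) {
    stop("each network needs at least 6 ranked hubs")
  }
  if (length(unique(u$v1)) == 1L || length(unique(u$v2)) == 1L) {
    stop("degenerate feature: all values tied")
  }
  thirds <- function(v) {
    ord <- names(v)[order(-v, names(v))]
    k <- ceiling(length(v) / 3)
    list(top = ord[seq_len(k)], bottom = rev(ord)[seq_len(k)], k = k)
  }
  t1 <- thirds(u$v1); t2 <- thirds(u$v2)
  groups <- expand.grid(group1 = c("top", "bottom"), group2 = c("top", "bottom"),
                        stringsAsFactors = FALSE)
  obs <- mapply(function(a, b) {
    count_pairs_between(u$g1, u$g2, t1[[a]], t2[[b]])
  }, groups$group1, groups$group2)
  null <- with_seed(seed, vapply(seq_len(B), function(bb) {
    s1 <- sample(names(u$v1), 2L * t1$k)
    s2 <- sample(names(u$v2), 2L * t2$k)
    r1 <- list(top = s1[seq_len(t1$k)], bottom = s1[t1$k + seq_len(t1$k)])
    r2 <- list(top = s2[seq_len(t2$k)], bottom = s2[t2$k + seq_len(t2$k)])
    mapply(function(a, b) count_pairs_between(u$g1, u$g2, r1[[a]], r2[[b]]),
           groups$group1, groups$group2)
  }, numeric(4L)))
  res <- lapply(seq_len(4L), function(j) {
    et <- empirical_result(obs[j], null[j, ], direction)
    data.frame(group1 = groups$group1[j], group2 = groups$group2[j],
               count = obs[j], null_mean = et$null_mean, null_sd = et$null_sd,
               z = et$z, empirical_p = et$empirical_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
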