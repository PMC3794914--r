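test_that("Spearman correlation handles monotone relations and ties", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # ties: equals rank-then-Pearson with average ranks
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:5, 30, replace = TRUE)
    b <- a + sample(0:3, 30, replace = TRUE)
    expect_equal(spearman_cor(a, b)$rho, oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  # invariance to strictly monotone transforms
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(exp(a), b^3 + b)$rho,
               tolerance = 1e-12)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(rank(a), rank(b))$rho,
               tolerance = 1e-12)
  expect_error(spearman_cor(c(1, 2, NA), c(1, NA, 3)), "fewer than 3")
})

test_that("pairwise-complete cases restrict the sample and are reported", {
  x <- c(1, 2, 3, 4, NA, 6)
  y <- c(2, 1, 4, NA, 5, 7)
  s <- spearman_cor(x, y)
  expect_equal(s$n, 4L)
})

test_that("partial Spearman reduces to plain Spearman without covariates", {
  set.seed(32)
  x <- rnorm(50); y <- x + rnorm(50)
  expect_equal(partial_spearman(x, y)$rho, spearman_cor(x, y)$rho)
  expect_equal(partial_spearman(x, y, list())$rho, spearman_cor(x, y)$rho)
})

test_that("partialling out a perfect confounder drives the correlation to ~0", {
  set.seed(33)
  z <- rnorm(200)
  y <- z                       # y equals the covariate
  x <- z + rnorm(200)
  ps <- partial_spearman(x, y, z)
  expect_lt(abs(ps$rho), 0.05)
})

test_that("an independent covariate barely changes the correlation", {
  set.seed(34)
  x <- rnorm(500); y <- 0.6 * x + rnorm(500); z <- rnorm(500)
  expect_lt(abs(partial_spearman(x, y, z)$rho - spearman_cor(x, y)$rho), 0.05)
})

test_that("partial correlation matches the analytic Gaussian target", {
  # x = a*z + e1, y = b*z + e2: partial corr given z is 0; marginal is ab/sqrt((a2+1)(b2+1))
  set.seed(35)
  n <- 4000
  z <- rnorm(n)
  x <- 0.8 * z + rnorm(n)
  y <- 0.7 * z + rnorm(n)
  marg <- spearman_cor(x, y)$rho
  part <- partial_spearman(x, y, z)$rho
  expect_equal(marg, 0.56 / sqrt(1.64 * 1.49) * 0.95, tolerance = 0.12)
  expect_lt(abs(part), 0.05)
  expect_error(partial_spearman(x, y, rep(1, n)), "constant covariate")
})

test_that("Mann-Whitney comparisons report U, p and medians", {
  f <- data.frame(gene = sprintf("g%02d", 1:20), val = c(1:10, 1:10))
  same <- compare_groups_mannwhitney(f, f$gene[1:10], f$gene[11:20], "val")
  expect_gt(same$p, 0.9)
  expect_equal(same$median_a, same$median_b)
  f2 <- data.frame(gene = sprintf("g%02d", 1:20), val = c(1:10, 101:110))
  sep <- compare_groups_mannwhitney(f2, f2$gene[1:10], f2$gene[11:20], "val")
  expect_equal(unname(sep$U), 0)
  expect_lt(sep$p, 1e-3)
  # U equals the direct pair count #(a > b) + 0.5 #(a == b)
  set.seed(36)
  a <- sample(1:8, 10, replace = TRUE); b <- sample(1:8, 10, replace = TRUE)
  f3 <- data.frame(gene = sprintf("g%02d", 1:20), val = c(a, b))
  got <- compare_groups_mannwhitney(f3, f3$gene[1:10], f3$gene[11:20], "val")
  u_direct <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(unname(got$U), u_direct)
  # normal-approximation p close to the exact permutation p for small n
  aa <- c(12, 5, 9, 14, 2, 11, 7, 3, 10, 8); bb <- c(1, 4, 6, 13, 15, 16, 17, 18, 19, 20)
  f4 <- data.frame(gene = sprintf("g%02d", 1:20), val = c(aa, bb))
  approx <- compare_groups_mannwhitney(f4, f4$gene[1:10], f4$gene[11:20], "val")
  exact <- wilcox.test(aa, bb, exact = TRUE)$p.value
  expect_equal(approx$p, exact, tolerance = 0.05)
  expect_error(compare_groups_mannwhitney(f, f$gene[1:2], f$gene[3:20], "val"),
               ">= 3 genes")
})

test_that("duplicated features correlate perfectly and controls stay small", {
  sw <- small_world_features()
  f <- sw$fw$features
  f$avpcc2 <- f$avpcc
  rep1 <- feature_correlation_matrix(f, sw$world$network, n_random = 0,
                                     feature_names = c("avpcc", "avpcc2"))
  expect_equal(rep1$rho, 1)
  # randomized-network control: topology correlations shrink toward 0
  rep2 <- feature_correlation_matrix(
    f, sw$world$network, n_random = 5, seed = 8,
    score_matrix = sw$score_matrix,
    cluster_params = sw$fw$clustering$params,
    feature_names = c("avpcc", "clustering", "participation"))
  expect_true(all(is.finite(rep2$control_sd_rho)))
  pair <- rep2[rep2$feature_a == "avpcc" & rep2$feature_b == "clustering", ]
  expect_lt(abs(pair$control_mean_rho), abs(pair$rho))
})

test_that("avpcc_rand with one randomization equals avPCC on that network", {
  sw <- small_world_features()
  net <- sw$world$network
  seeds <- hubdyn:::with_seed(17, sample.int(.Machine$integer.max, 1))
  g <- degree_preserving_randomize(net, seed = seeds[1])
  direct <- avpcc_table(g, sw$score_matrix)
  ar <- avpcc_rand(net, sw$score_matrix, n_random = 1, seed = 17)
  expect_equal(ar, direct)
})

test_that("avpcc_rand is near zero for uncorrelated expression", {
  set.seed(18)
  genes <- sprintf("g%02d", 1:40)
  M <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(genes, paste0("e", 1:30)))
  comp <- expression_compendium(list(expression_dataset(M)))
  sm <- coexpression_matrix(comp)
  A <- random_test_graph(40, 0.25, seed = 18)
  net <- graph_from_adj(A)
  igraph::V(net)$name <- genes
  ar <- avpcc_rand(net, sm, n_random = 30, seed = 19)
  expect_lt(max(abs(ar), na.rm = TRUE), 0.25)
  expect_lt(abs(mean(ar, na.rm = TRUE)), 0.05)
})

test_that("label associations recover identity and degenerate cases", {
  sw <- small_world_features()
  f <- sw$fw$features
  hubs <- f[f$is_hub, ]
  # genetic degree equal to PPI degree by construction -> same SRCC as degree
  el <- igraph::as_edgelist(sw$world$network)
  gen <- data.frame(from = el[, 1], to = el[, 2])
  rep <- label_associations(f, genetic_edges = gen, feature_names = "clustering")
  want <- spearman_cor(hubs$clustering, hubs$degree)
  got <- rep[rep$target == "genetic_degree" & rep$type == "plain", ]
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  # constant essentiality -> NA row, not an error
  rep2 <- label_associations(f, essential = character(0),
                             feature_names = "clustering")
  expect_true(is.na(rep2$rho[rep2$target == "essential"]))
})

test_that("evidence-type associations count edges per label", {
  sw <- small_world_features()
  f <- sw$fw$features
  rep <- evidence_type_associations(f, sw$world$network,
                                    feature_names = c("participation"))
  expect_setequal(unique(rep$target), c("n_cocomplex", "n_y2h"))
  # single-evidence network: counts equal degree
  net1 <- ppi_network(c("a", "a", "a", "b", "b", "c", "d", "d", "e"),
                      c("b", "c", "d", "c", "e", "d", "e", "f", "f"),
                      evidence = rep("y2h", 9))
  fw1 <- compute_hub_features(net1, classify = FALSE, hub_fraction = 0.5)
  r1 <- evidence_type_associations(fw1$features, net1,
                                   feature_names = "clustering")
  hubs1 <- fw1$features[fw1$features$is_hub, ]
  expect_equal(r1$rho[1], spearman_cor(hubs1$clustering, hubs1$degree)$rho,
               tolerance = 1e-12)
  expect_error(evidence_type_associations(f, igraph::delete_edge_attr(
    sw$world$network, "evidence")), "evidence")
})
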