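make_ds <- function(M, groups = colnames(M), absolute = FALSE) {
  expression_dataset(M, replicate_groups = groups, is_absolute = absolute)
}

test_that("processing merges replicates, filters genes and z-scores columns", {
  M <- rbind(
    g1 = c(4, 6, 1, 2, 3, 4),
    g2 = c(1, NA, NA, NA, NA, NA),  # 1 of 4 merged columns known -> dropped
    g3 = c(0, 2, 5, 1, 7, 2),
    g4 = c(2, 2, 3, 8, 1, 5))
  groups <- c("e1", "e1", "e2", "e3", "e4", "e4")
  ds <- process_dataset(make_ds(M, groups), min_known_fraction = 0.5)
  expect_false("g2" %in% rownames(ds$values))
  expect_equal(sort(colnames(ds$values)), c("e1", "e2", "e3", "e4"))
  # replicate merge happens before the z-score: check via a hand-built copy
  merged <- cbind(e1 = rowMeans(M[, 1:2]), e2 = M[, 3], e3 = M[, 4],
                  e4 = rowMeans(M[, 5:6]))
  merged <- merged[c("g1", "g3", "g4"), ]
  expect_equal(ds$values, scale(merged)[, ], tolerance = 1e-12)
  # z-scored columns have mean 0, sd 1
  expect_true(all(abs(colMeans(ds$values)) < 1e-12))
  expect_true(all(abs(apply(ds$values, 2, sd) - 1) < 1e-12))
})

test_that("a gene with a third of values known is removed at the 50% rule", {
  M <- matrix(rnorm(18), 3, 6,
              dimnames = list(c("keep1", "keep2", "drop"), paste0("e", 1:6)))
  M["drop", 3:6] <- NA
  ds <- process_dataset(make_ds(M))
  expect_setequal(rownames(ds$values), c("keep1", "keep2"))
})

test_that("constant columns are dropped because their z-score is undefined", {
  M <- matrix(c(1, 1, 1, 1, 2, 3), 3, 2,
              dimnames = list(paste0("g", 1:3), c("flat", "ok")))
  expect_warning(ds <- process_dataset(make_ds(M)), "dropped")
  expect_equal(colnames(ds$values), "ok")
})

test_that("absolute-signal datasets are log-transformed with a floor", {
  M <- matrix(2^c(1, 2, 3, 4, 5, 6, 7, 9, 4), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("e", 1:3)))
  ds <- process_dataset(make_ds(M, absolute = TRUE))
  ref <- process_dataset(make_ds(log2(M)))
  expect_equal(ds$values, ref$values, tolerance = 1e-12)
  # non-positive absolute signals are clamped at the floor, not -Inf
  M[1, 1] <- -5
  ds2 <- process_dataset(make_ds(M, absolute = TRUE))
  expect_true(all(is.finite(ds2$values)))
})

test_that("pairwise PCC masks missing dimensions and flags undefined cases", {
  expect_equal(pairwise_pcc(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pairwise_pcc(c(1, 2, 3, NA), c(3, 2, 1, 5)), -1.0)
  expect_true(is.na(pairwise_pcc(c(1, 2, NA), c(1, 2, 3))))      # 2 shared
  expect_true(is.na(pairwise_pcc(c(1, 1, 1), c(1, 2, 3))))       # no variance
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    x[sample(50, 10)] <- NA; y[sample(50, 10)] <- NA
    expect_equal(pairwise_pcc(x, y), oracle_masked_pcc(x, y), tolerance = 1e-12)
  }
})

test_that("interaction scores are weight-renormalized over defined datasets", {
  # hand-built compendium: dataset weights 100 and 300 by construction
  set.seed(5)
  mk <- function(genes, ncol) {
    M <- matrix(rnorm(length(genes) * ncol), length(genes), ncol,
                dimnames = list(genes, paste0("e", seq_len(ncol))))
    M
  }
  g <- sprintf("g%02d", 1:10)
  d1 <- make_ds(mk(g, 10))                 # 10 x 10 = 100 datapoints
  d2 <- make_ds(mk(g, 30))                 # 10 x 30 = 300 datapoints
  comp <- expression_compendium(list(d1, d2))
  expect_equal(unname(comp$weights), c(100, 300))
  net <- ppi_network("g01", "g02")
  sc <- interaction_coexpression(net, comp)
  p1 <- pairwise_pcc(comp$datasets[[1]]$values["g01", ], comp$datasets[[1]]$values["g02", ])
  p2 <- pairwise_pcc(comp$datasets[[2]]$values["g01", ], comp$datasets[[2]]$values["g02", ])
  expect_equal(sc$score, (100 * p1 + 300 * p2) / 400, tolerance = 1e-12)
  # PCC defined only in dataset 2: weights renormalize onto it
  d1b <- d1; d1b$values["g01", ] <- NA    # breaks the pair in dataset 1
  comp2 <- suppressWarnings(expression_compendium(list(d1b, d2)))
  sc2 <- interaction_coexpression(net, comp2)
  p2b <- pairwise_pcc(comp2$datasets[[2]]$values["g01", ], comp2$datasets[[2]]$values["g02", ])
  expect_equal(sc2$score, p2b, tolerance = 1e-12)
})

test_that("equal-weight averaging equals the unweighted mean of dataset PCCs", {
  set.seed(6)
  g <- sprintf("g%02d", 1:8)
  mk <- function() matrix(rnorm(8 * 12), 8, 12, dimnames = list(g, paste0("e", 1:12)))
  comp <- expression_compendium(list(make_ds(mk()), make_ds(mk()), make_ds(mk())))
  net <- ppi_network(c("g01", "g03"), c("g02", "g04"))
  sc <- interaction_coexpression(net, comp)
  for (r in 1:2) {
    ps <- vapply(comp$datasets, function(d) {
      pairwise_pcc(d$values[sc$from[r], ], d$values[sc$to[r], ])
    }, 0)
    expect_equal(sc$score[r], mean(ps), tolerance = 1e-12)
  }
})

test_that("avPCC keeps undefined edge scores in the denominator", {
  net <- ppi_network(rep("hub", 4), paste0("n", 1:4))
  sc <- interaction_coexpression(net, matrix(NA_real_, 0, 0))
  sc$score <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(hub_avpcc(net, sc, "hub"), 0.5)
  sc$score <- c(0.8, 0.8, 0.8, NA)
  expect_equal(hub_avpcc(net, sc, "hub"), 0.6)
})

test_that("avPCC is undefined below the minimum number of defined scores", {
  net <- ppi_network(rep("hub", 5), paste0("n", 1:5))
  sc <- data.frame(from = rep("hub", 5), to = paste0("n", 1:5),
                   score = c(0.9, 0.9, NA, NA, NA))
  expect_true(is.na(hub_avpcc(net, sc, "hub")))
  expect_error(hub_avpcc(net, sc, "nothere"), "not in network")
})

test_that("all defined scores and avPCCs stay within [-1, 1]", {
  sw <- small_world_features()
  sc <- interaction_coexpression(sw$world$network, sw$score_matrix)
  s <- sc$score[!is.na(sc$score)]
  expect_true(all(s >= -1 & s <= 1))
  av <- sw$fw$features$avpcc
  expect_true(all(abs(av[!is.na(av)]) <= 1))
})

test_that("within-module interactions score higher than cross-module ones", {
  sw <- small_world_features()
  w <- sw$world
  sc <- interaction_coexpression(w$network, sw$score_matrix)
  mod <- setNames(w$truth$module, w$truth$gene)
  same <- !is.na(mod[sc$from]) & !is.na(mod[sc$to]) & mod[sc$from] == mod[sc$to]
  expect_gt(mean(sc$score[same], na.rm = TRUE),
            mean(sc$score[!same], na.rm = TRUE) + 0.2)
})

test_that("expression TSV round-trips through the readers", {
  w <- small_world()
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "expr.tsv"); dp <- file.path(dir, "design.tsv")
  write_expression_tsv(w$expression, vp, dp)
  back <- read_expression_tsv(vp, dp)
  expect_equal(length(back), length(w$expression))
  orig <- w$expression[[1]]
  got <- back[[orig$id]]
  expect_equal(got$is_absolute, orig$is_absolute)
  expect_equal(unname(got$values[rownames(orig$values), ]),
               unname(orig$values), tolerance = 1e-9)
})
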