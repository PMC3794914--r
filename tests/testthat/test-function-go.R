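# toy ontology used across the GO tests:
#   BP root -> {broadA, broadB}; broadA -> {t1, t2}; broadB -> t3
toy_ontology <- function() {
  parents <- list(
    "BP:0" = character(0), "broadA" = "BP:0", "broadB" = "BP:0",
    "t1" = "broadA", "t2" = "broadA", "t3" = "broadB",
    "CC:0" = character(0), "MF:0" = character(0))
  ns <- setNames(c("BP", "BP", "BP", "BP", "BP", "BP", "CC", "MF"),
                 names(parents))
  ontology(parents, ns)
}

toy_annotations <- function(ont = toy_ontology()) {
  direct <- list(g1 = "t1", g2 = c("t1", "t2"), g3 = "t2", g4 = "t3",
                 g5 = "t3", g6 = "broadA")
  annotation_set(direct, ont)
}

test_that("ontology construction validates acyclicity and rootedness", {
  ont <- toy_ontology()
  expect_setequal(unname(ont$roots), c("BP:0", "CC:0", "MF:0"))
  expect_error(ontology(list(a = "b", b = "a"), c(a = "BP", b = "BP")), "cycle")
  expect_error(
    ontology(list("BP:0" = character(0), "CC:0" = character(0), x = "CC:0"),
             c("BP:0" = "BP", "CC:0" = "BP", x = "BP")),
    "root")
})

test_that("propagated annotations are closed under ancestors", {
  ann <- toy_annotations()
  expect_setequal(ann$propagated$g1, c("t1", "broadA", "BP:0"))
  expect_setequal(ann$propagated$g2, c("t1", "t2", "broadA", "BP:0"))
  for (g in names(ann$direct)) {
    expect_true(all(ann$direct[[g]] %in% ann$propagated[[g]]))
  }
})

test_that("information content matches hand-computed -ln ratios", {
  ann <- toy_annotations()
  # N = 6 annotated genes; t1 annotates g1, g2
  expect_equal(unname(term_information_content(ann, "t1")), -log(2 / 6))
  expect_equal(unname(term_information_content(ann, "broadA")), -log(4 / 6))
  # root annotates everyone -> IC 0
  expect_equal(unname(term_information_content(ann, "BP:0")), 0)
  expect_true(is.na(term_information_content(ann, "CC:0")))
})

test_that("IC never increases from child to parent", {
  sw <- small_world_features()
  ann <- sw$world$annotations
  ont <- sw$world$ontology
  counts <- table(unlist(ann$propagated, use.names = FALSE))
  terms <- names(counts)
  ic <- term_information_content(ann, terms)
  for (t in terms) {
    for (p in intersect(ont$parents[[t]], terms)) {
      expect_lte(ic[p], ic[t] + 1e-12)
    }
  }
})

test_that("term depth is the shortest path to the namespace root", {
  ont <- toy_ontology()
  expect_equal(unname(term_depth(ont, c("BP:0", "broadA", "t1"))), c(0L, 1L, 2L))
})

test_that("eligible terms respect namespace, depth and gene-count bounds", {
  ann <- toy_annotations()
  el <- eligible_terms(ann, min_depth = 2, min_genes = 2, max_genes = 3)
  expect_setequal(el, c("t1", "t2", "t3"))
  el2 <- eligible_terms(ann, min_depth = 1, min_genes = 2, max_genes = 10)
  expect_true("broadA" %in% el2)
})

test_that("pair functional similarity is the max IC over shared eligible terms", {
  ann <- toy_annotations()
  el <- c("t1", "t2", "t3")
  ic <- term_information_content(ann, el)
  # disjoint annotation sets -> 0
  expect_equal(pair_functional_similarity(ann, "g1", "g4", el, ic), 0)
  # g2 and g3 share t2 (IC -ln(2/6))
  expect_equal(pair_functional_similarity(ann, "g2", "g3", el, ic),
               -log(2 / 6))
  # self-similarity under the max rule is the best own term
  expect_equal(pair_functional_similarity(ann, "g2", "g2", el, ic),
               max(ic[c("t1", "t2")]))
  # two shared terms: the larger IC wins
  expect_equal(pair_functional_similarity(ann, "g1", "g2", el, ic),
               unname(ic["t1"]))
  # symmetry
  expect_equal(pair_functional_similarity(ann, "g2", "g3", el, ic),
               pair_functional_similarity(ann, "g3", "g2", el, ic))
})

test_that("node functional similarity averages over neighbors, zeros for unannotated", {
  ann <- toy_annotations()
  # hub g2 with neighbors g1 (shares t1), g4 (disjoint), gX (unannotated)
  net <- ppi_network(rep("g2", 3), c("g1", "g4", "gX"))
  fs <- node_functional_similarity(net, ann, min_genes = 2, max_genes = 3)
  ic <- term_information_content(ann, c("t1", "t2", "t3"))
  expect_equal(unname(fs["g2"]), mean(c(unname(ic["t1"]), 0, 0)))
  # all neighbors unannotated -> 0
  net2 <- ppi_network(c("g1", "g1"), c("u1", "u2"))
  fs2 <- node_functional_similarity(net2, ann, min_genes = 2, max_genes = 3)
  expect_equal(unname(fs2["g1"]), 0)
  # isolated vertex -> NA
  net3 <- ppi_network("g1", "g2", vertices = c("g1", "g2", "solo"))
  fs3 <- node_functional_similarity(net3, ann, min_genes = 2, max_genes = 3)
  expect_true(is.na(fs3["solo"]))
})

test_that("hypergeometric enrichment matches the closed-form example", {
  # background 20 hubs, 8 with broadA-descendant term, class of 10 holding all 8
  ont <- toy_ontology()
  genes <- sprintf("g%02d", 1:20)
  direct <- c(
    setNames(rep(list("t1"), 8), genes[1:8]),
    setNames(rep(list("t3"), 12), genes[9:20]))
  ann <- annotation_set(direct, ont)
  cls <- genes[c(1:8, 9:10)]
  res <- suppressWarnings(go_enrichment(cls, genes, ann, ont))
  row <- res[res$term == "broadA", ]
  expect_equal(row$k, 8L); expect_equal(row$K, 8L)
  expect_equal(row$p_raw, 66 / 184756, tolerance = 1e-12)
  expect_equal(row$p_raw, oracle_hyper_upper(8, 8, 20, 10), tolerance = 1e-12)
  # class = background -> all raw p-values 1
  res2 <- suppressWarnings(go_enrichment(genes, genes, ann, ont))
  expect_true(all(res2$p_raw == 1))
})

test_that("Bonferroni correction multiplies by the number of terms tested", {
  ont <- toy_ontology()
  genes <- sprintf("g%02d", 1:20)
  direct <- c(
    setNames(rep(list("t1"), 10), genes[1:10]),
    setNames(rep(list("t3"), 10), genes[11:20]))
  ann <- annotation_set(direct, ont)
  res <- suppressWarnings(go_enrichment(genes[1:6], genes, ann, ont))
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 2))
  # a raw p of ~0.03 with 2 terms tested is not significant at 0.05
  expect_true(all(res$enriched == (res$p_bonferroni < 0.05)))
})

test_that("enrichment matches the exact combinatorial oracle on small tables", {
  for (N in c(5, 10, 20, 30)) {
    for (K in c(1, floor(N / 3), floor(N / 2))) {
      for (n in c(2, floor(N / 2))) {
        for (k in 0:min(K, n)) {
          expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       oracle_hyper_upper(k, K, N, n), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("evidence codes and NOT qualifiers are filtered from associations", {
  ont <- toy_ontology()
  df <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                   term = c("t1", "t2", "t1", "t1"),
                   evidence = c("EXP", "IEA", "EXP", "EXP"),
                   qualifier = c("", "", "NOT", ""))
  ann <- annotation_set(df, ont)
  expect_equal(ann$direct$g1, "t1")       # IEA row dropped
  expect_false("g2" %in% names(ann$direct))  # NOT row dropped
})

test_that("ontology and associations round-trip through TSV", {
  sw <- small_world_features()
  dir <- withr::local_tempdir()
  op <- file.path(dir, "ont.tsv"); ap <- file.path(dir, "assoc.tsv")
  write_ontology_tsv(sw$world$ontology, op)
  write_associations_tsv(sw$world$annotations, ap)
  ont2 <- read_ontology_tsv(op)
  ann2 <- read_associations_tsv(ap, ont2)
  expect_setequal(names(ont2$parents), names(sw$world$ontology$parents))
  g <- names(sw$world$annotations$direct)[1]
  expect_setequal(ann2$propagated[[g]], sw$world$annotations$propagated[[g]])
})
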