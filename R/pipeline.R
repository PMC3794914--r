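#' Read a list of gene identifiers, one per line
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Read a genetic-interaction edge list
#'
#' TSV with columns `from`, `to` and optionally `sign` (`"+"`/`"-"`).
#'
#' @param path TSV path.
#' @return Data frame of genetic interactions.
#' @export
read_genetic_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

default_pipeline_config <- function() {
  list(
    network = NULL, expression = NULL, expression_design = NULL,
    ontology = NULL, associations = NULL, essential = NULL,
    genetic = NULL, network2 = NULL, expression2 = NULL,
    expression2_design = NULL, orthologs = NULL,
    hub_fraction = 0.10, extremal_fraction = 0.05,
    min_defined = 3, min_shared = 3,
    td_grid = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
    ts_grid = c(2, 3, 5),
    B_set = 1000, B_removal = 1000, B_ortholog = 1000,
    n_random_controls = 0, n_random_avpcc = 0,
    similarity_rule = "max", min_term_depth = 2,
    rho_threshold = 0.1, p_threshold = 0.05,
    removal_direction = "two-sided",
    seed = 1
  )
}

validate_pipeline_config <- function(config) {
  cfg <- modifyList(default_pipeline_config(), config)
  if (is.null(cfg$network)) stop("config error: 'network' path is required")
  paths <- c("network", "expression", "expression_design", "ontology",
             "associations", "essential", "genetic", "network2",
             "expression2", "expression2_design", "orthologs")
  for (p in paths) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config error: input path does not exist: ", p, " = ", cfg[[p]])
    }
  }
  fr <- c(cfg$hub_fraction, cfg$extremal_fraction)
  if (any(fr <= 0 | fr >= 1)) stop("config error: fractions must lie in (0, 1)")
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

compute_world_features <- function(net, expr_datasets, ann, cfg) {
  score_matrix <- NULL
  if (!is.null(expr_datasets)) {
    comp <- expression_compendium(expr_datasets)
    score_matrix <- coexpression_matrix(comp, genes = igraph::V(net)$name,
                                        min_shared = cfg$min_shared)
  }
  compute_hub_features(net, scores = score_matrix, annotations = ann,
                       hub_fraction = cfg$hub_fraction,
                       extremal_fraction = cfg$extremal_fraction,
                       min_defined = cfg$min_defined,
                       td_grid = cfg$td_grid, ts_grid = cfg$ts_grid)
}

#' Run the full hub-characterization pipeline
#'
#' Sequences the analysis stages in order — network ingestion, expression
#' processing and co-expression scoring, per-hub features, date/party
#' classification, set-level resampling tests, hub-removal experiments,
#' correlation analyses, broad-term enrichment, and (when a second network
#' and ortholog map are configured) cross-network conservation — and
#' writes tables, JSON reports and run metadata to `out_dir`. Expression,
#' annotation and label inputs are optional: without expression the
#' pipeline runs a topology-only subset and the avPCC columns stay empty.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Fields: input paths (`network`, `expression`,
#'   `expression_design`, `ontology`, `associations`, `essential`,
#'   `genetic`, `network2`, `expression2`, `expression2_design`,
#'   `orthologs`), thresholds (`hub_fraction`, `extremal_fraction`),
#'   resampling sizes (`B_set`, `B_removal`, `B_ortholog`,
#'   `n_random_controls`, `n_random_avpcc`), the clustering grids
#'   (`td_grid`, `ts_grid`) and `seed`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the report bundle as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  bundle <- list()

  net <- stage("network", read_edge_list(cfg$network, evidence_column = 3L))
  expr <- NULL
  if (!is.null(cfg$expression)) {
    expr <- stage("expression",
                  read_expression_tsv(cfg$expression, cfg$expression_design))
  }
  ann <- NULL; ont <- NULL
  if (!is.null(cfg$ontology) && !is.null(cfg$associations)) {
    ont <- stage("ontology", read_ontology_tsv(cfg$ontology))
    ann <- stage("annotations", read_associations_tsv(cfg$associations, ont))
  }

  fw <- stage("features", compute_world_features(net, expr, ann, cfg))
  features <- fw$features
  bundle$features <- features
  bundle$hub_threshold <- fw$threshold
  bundle$clustering <- fw$clustering
  write.table(features, fp("hub_features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = names(fw$clustering$assignment),
                         cluster = unname(fw$clustering$assignment)),
              fp("clustering.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  classes <- split(features$gene[features$is_hub],
                   features$date_party[features$is_hub])
  background <- background_hubs(features)

  if (all(c("date", "party") %in% names(classes))) {
    settests <- stage("settests", {
      out <- list()
      for (cl in c("date", "party")) {
        S <- classes[[cl]]
        out[[cl]] <- list(
          density = unclass(empirical_set_test(
            net, S, background, "density", B = cfg$B_set,
            seed = cfg$seed + 101L, direction = "greater")),
          expansion = unclass(empirical_set_test(
            net, S, background, "expansion", B = cfg$B_set,
            seed = cfg$seed + 102L, direction = "less")),
          removal = lapply(hub_removal_experiment(
            net, S, background, B = cfg$B_removal,
            seed = cfg$seed + 103L, direction = cfg$removal_direction),
            function(r) list(fold_change = r$fold_change,
                             empirical_p = r$test$empirical_p,
                             null_mean = r$test$null_mean,
                             null_sd = r$test$null_sd)))
      }
      out
    })
    bundle$settests <- settests
    write_json_report(settests, fp("settests.json"))
  }

  corr <- stage("correlations", {
    score_matrix <- NULL
    if (!is.null(expr)) {
      comp <- expression_compendium(expr)
      score_matrix <- coexpression_matrix(comp, genes = igraph::V(net)$name,
                                          min_shared = cfg$min_shared)
    }
    fc <- feature_correlation_matrix(
      features, net, n_random = cfg$n_random_controls,
      seed = cfg$seed + 201L, score_matrix = score_matrix, ann = ann,
      cluster_params = fw$clustering$params)
    fc$significant <- !is.na(fc$rho) & abs(fc$rho) >= cfg$rho_threshold &
      fc$p < cfg$p_threshold
    out <- list(feature_pairs = fc)
    genetic <- if (!is.null(cfg$genetic)) read_genetic_tsv(cfg$genetic) else NULL
    essential <- if (!is.null(cfg$essential)) read_gene_list(cfg$essential) else NULL
    ar <- NULL
    if (cfg$n_random_avpcc > 0 && !is.null(score_matrix)) {
      ar <- avpcc_rand(net, score_matrix, n_random = cfg$n_random_avpcc,
                       seed = cfg$seed + 202L, min_defined = cfg$min_defined)
    }
    if (!is.null(genetic) || !is.null(essential)) {
      out$labels <- label_associations(features, genetic, essential,
                                       avpcc_rand_values = ar)
    }
    if ("evidence" %in% igraph::edge_attr_names(net)) {
      out$evidence <- evidence_type_associations(features, net)
    }
    out
  })
  bundle$correlations <- corr
  write.table(corr$feature_pairs, fp("feature_correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(corr$labels)) {
    write.table(corr$labels, fp("label_correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(corr$evidence)) {
    write.table(corr$evidence, fp("evidence_correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (!is.null(ann)) {
    enrich <- stage("enrich", {
      annotated_hubs <- intersect(features$gene[features$is_hub],
                                  names(ann$propagated))
      res <- list()
      for (cl in intersect(c("date", "party"), names(classes))) {
        tab <- go_enrichment(intersect(classes[[cl]], annotated_hubs),
                             annotated_hubs, ann, ont,
                             alpha = cfg$p_threshold)
        if (nrow(tab) > 0L) tab$class <- cl
        res[[cl]] <- tab
      }
      do.call(rbind, res)
    })
    bundle$enrichment <- enrich
    write.table(enrich, fp("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (!is.null(cfg$network2) && !is.null(cfg$orthologs)) {
    ortho <- stage("orthology", {
      net2 <- read_edge_list(cfg$network2, evidence_column = 3L)
      expr2 <- NULL
      if (!is.null(cfg$expression2)) {
        expr2 <- read_expression_tsv(cfg$expression2, cfg$expression2_design)
      }
      fw2 <- compute_world_features(net2, expr2, NULL, cfg)
      map <- read_ortholog_tsv(cfg$orthologs)
      out <- list()
      for (f in c("avpcc", "clustering", "betweenness", "participation")) {
        res <- try(ortholog_feature_correlation(
          features, fw2$features, map, f, B = cfg$B_ortholog,
          seed = cfg$seed + 301L), silent = TRUE)
        if (!inherits(res, "try-error")) {
          res$thirds <- thirds_conservation(
            features, fw2$features, map, f, B = cfg$B_ortholog,
            seed = cfg$seed + 302L)
          out[[f]] <- res
        }
      }
      out
    })
    bundle$orthology <- ortho
    write_json_report(ortho, fp("orthology.json"))
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("hubdyn")),
    config = cfg[!vapply(cfg, is.null, logical(1L))],
    n_vertices = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    hub_threshold = fw$threshold,
    n_hubs = sum(features$is_hub),
    class_sizes = lapply(classes, length),
    clustering_modularity = fw$clustering$modularity,
    clustering_params = fw$clustering$params
  )
  write_json_report(meta, fp("run_metadata.json"))
  bundle$metadata <- meta
  invisible(bundle)
}
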