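#' Configuration of a synthetic analysis world
#'
#' The generator emulates the statistical structure the hub analysis
#' assumes in real interactomes: a modular network whose intramodular
#' ("party-like") planted hubs gain extra within-module edges and whose
#' intermodular ("date-like") planted hubs spread edges over several
#' modules; a module-factor expression compendium with replicates and
#' missing values that makes intramodular hubs co-expressed with their
#' partners; module-coherent annotations; essentiality enriched among
#' intramodular hubs; genetic-interaction degree enriched among
#' intermodular hubs; and a second "organism" regenerated from the same
#' planted truth with a 1:many ortholog map.
#'
#' @param n_modules,module_size Number and size of network modules.
#' @param n_background Vertices outside any module (wired at `p_out`).
#' @param p_in,p_out Within- and between-module edge probabilities.
#' @param n_party,n_date Numbers of planted party-like and date-like hubs
#'   (drawn from module members, disjoint).
#' @param n_party_modules Number of modules hosting the party-like hubs;
#'   concentrating several party hubs per module emulates protein-complex
#'   cores whose members are mutual interaction partners.
#' @param party_coherence When `TRUE`, a module's party hubs are wired to
#'   each other before other module members (complex cores). Set `FALSE`
#'   together with `date_spread = 1` and equal loadings/rates for a
#'   fully signal-free negative-control world.
#' @param date_spread Number of foreign modules a date-like hub connects to.
#' @param target_quantile Planted hubs are boosted to this quantile of the
#'   pre-boost degree distribution (plus a small margin), so both classes
#'   share the same target degree.
#' @param n_datasets,n_conditions,replicate_count Expression compendium
#'   shape: datasets, genome-wide conditions per dataset, replicate columns
#'   per condition.
#' @param loading_party,loading_date Module-factor loadings of
#'   party-like/module genes and of date-like hubs.
#' @param noise_sd,replicate_sd Per-gene condition noise and the smaller
#'   replicate-to-replicate noise.
#' @param missing_rate Fraction of expression entries masked as missing.
#' @param essential_rate_intra,essential_rate_inter,essential_rate_background
#'   Essentiality probabilities for party-like, date-like and other genes.
#' @param genetic_rate_intra,genetic_rate_inter,genetic_rate_background
#'   Expected genetic-interaction degrees for the same three groups.
#' @param ortholog_fraction Probability a gene gets its 1:1 ortholog pair.
#' @param ortholog_many_rate Probability of an extra within-module partner,
#'   creating 1:many ortholog pairs.
#' @param seed Master seed; every generated artifact is a deterministic
#'   function of the configuration.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_modules = 20L, module_size = 80L,
                             n_background = 400L,
                             p_in = 0.15, p_out = 0.002,
                             n_party = 60L, n_date = 120L,
                             n_party_modules = 10L, party_coherence = TRUE,
                             date_spread = 8L, target_quantile = 0.95,
                             n_datasets = 3L, n_conditions = 60L,
                             replicate_count = 2L,
                             loading_party = 0.9, loading_date = 0.25,
                             noise_sd = 1, replicate_sd = 0.25,
                             missing_rate = 0.1,
                             essential_rate_intra = 0.6,
                             essential_rate_inter = 0.1,
                             essential_rate_background = 0.1,
                             genetic_rate_intra = 5, genetic_rate_inter = 30,
                             genetic_rate_background = 2,
                             ortholog_fraction = 0.8,
                             ortholog_many_rate = 0.1,
                             seed = 7L) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_in, cfg$p_out, cfg$missing_rate, cfg$essential_rate_intra,
             cfg$essential_rate_inter, cfg$essential_rate_background,
             cfg$ortholog_fraction, cfg$ortholog_many_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$loading_party >= 0, cfg$loading_party <= 1,
            cfg$loading_date >= 0, cfg$loading_date <= 1,
            cfg$n_modules > 0, cfg$module_size > 0,
            cfg$n_party + cfg$n_date <= cfg$n_modules * cfg$module_size,
            cfg$n_party_modules >= 1, cfg$n_party_modules <= cfg$n_modules,
            cfg$date_spread >= 1, cfg$date_spread <= cfg$n_modules)
  structure(cfg, class = "synthetic_config")
}

# Assign gene ids, modules and planted roles deterministically from cfg.
# Party-like hubs are concentrated in n_party_modules modules (several per
# module, like members of protein complexes); date-like hubs are spread
# evenly over all modules.
planted_truth <- function(cfg) {
  with_seed(cfg$seed, {
    n_mod_genes <- cfg$n_modules * cfg$module_size
    genes <- sprintf("G%04d", seq_len(n_mod_genes + cfg$n_background))
    module <- c(rep(seq_len(cfg$n_modules), each = cfg$module_size),
                rep(NA_integer_, cfg$n_background))
    role <- rep("background", length(genes))
    party_mods <- sort(sample(cfg$n_modules, cfg$n_party_modules))
    per_party <- ceiling(cfg$n_party / cfg$n_party_modules)
    per_date <- ceiling(cfg$n_date / cfg$n_modules)
    party <- character(0); date <- character(0)
    for (m in seq_len(cfg$n_modules)) {
      avail <- genes[module == m & !is.na(module)]
      if (m %in% party_mods && length(party) < cfg$n_party) {
        k <- min(per_party, cfg$n_party - length(party), length(avail))
        pk <- sample(avail, k)
        party <- c(party, pk)
        avail <- setdiff(avail, pk)
      }
      if (length(date) < cfg$n_date) {
        k <- min(per_date, cfg$n_date - length(date), length(avail))
        date <- c(date, sample(avail, k))
      }
    }
    role[genes %in% party] <- "party_like"
    role[genes %in% date] <- "date_like"
    data.frame(gene = genes, module = module, role = role,
               stringsAsFactors = FALSE)
  })
}

# Sample k distinct unordered pairs between two disjoint index blocks (or
# within one block when b is NULL), Bernoulli(p) per pair.
sample_block_pairs <- function(a, b = NULL, p) {
  if (is.null(b)) {
    npair <- choose(length(a), 2)
    if (npair == 0 || p == 0) return(NULL)
    k <- rbinom(1L, npair, p)
    if (k == 0L) return(NULL)
    idx <- sample(npair, k)
    # map pair index to (i < j) within a
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - (j - 1) * (j - 2) / 2
    cbind(a[i], a[j])
  } else {
    npair <- length(a) * length(b)
    if (npair == 0 || p == 0) return(NULL)
    k <- rbinom(1L, npair, p)
    if (k == 0L) return(NULL)
    idx <- sample(npair, k) - 1L
    cbind(a[idx %% length(a) + 1L], b[idx %/% length(a) + 1L])
  }
}

# Wire a network from a planted truth; separated from generate_network so
# the orthologous second world can be rewired from the same truth.
wire_network <- function(cfg, truth, seed) {
  with_seed(seed, {
    genes <- truth$gene
    idx <- seq_along(genes)
    blocks <- c(split(idx, truth$module), list(bg = idx[is.na(truth$module)]))
    from <- integer(0); to <- integer(0)
    # dense intra-module blocks
    for (m in seq_len(cfg$n_modules)) {
      pr <- sample_block_pairs(blocks[[as.character(m)]], p = cfg$p_in)
      if (!is.null(pr)) { from <- c(from, pr[, 1L]); to <- c(to, pr[, 2L]) }
    }
    # sparse everything-else (between modules, background-background,
    # module-background)
    bl <- unname(blocks)
    for (i in seq_along(bl)) {
      for (j in seq_along(bl)) {
        if (j <= i) next
        pr <- sample_block_pairs(bl[[i]], bl[[j]], p = cfg$p_out)
        if (!is.null(pr)) { from <- c(from, pr[, 1L]); to <- c(to, pr[, 2L]) }
      }
      if (identical(bl[[i]], blocks$bg)) {
        pr <- sample_block_pairs(bl[[i]], p = cfg$p_out)
        if (!is.null(pr)) { from <- c(from, pr[, 1L]); to <- c(to, pr[, 2L]) }
      }
    }
    deg0 <- tabulate(c(from, to), nbins = length(genes))
    target <- as.integer(ceiling(quantile(deg0, cfg$target_quantile))) + 2L
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    have <- new.env(hash = TRUE)
    for (k in seq_along(from)) assign(edge_key(from[k], to[k]), TRUE, envir = have)
    add_edges <- function(v, partners, k) {
      partners <- setdiff(partners, v)
      partners <- partners[!vapply(partners, function(u)
        exists(edge_key(v, u), envir = have), logical(1L))]
      if (length(partners) == 0L || k <= 0L) return(NULL)
      pick <- if (length(partners) <= k) partners else sample(partners, k)
      for (u in pick) assign(edge_key(v, u), TRUE, envir = have)
      cbind(v, pick)
    }
    deg <- deg0
    # party-like: extra intra-module edges up to the shared target degree,
    # wiring the module's party hubs to each other first (complex cores)
    party_set <- idx[truth$role == "party_like"]
    for (v in party_set) {
      need <- target - deg[v]
      if (need <= 0L) next
      members <- blocks[[as.character(truth$module[v])]]
      pools <- if (cfg$party_coherence) {
        list(intersect(members, party_set), members)
      } else list(members)
      for (pool in pools) {
        if (need <= 0L) break
        pr <- add_edges(v, pool, need)
        if (!is.null(pr)) {
          from <- c(from, pr[, 1L]); to <- c(to, pr[, 2L])
          deg[v] <- deg[v] + nrow(pr)
          deg[pr[, 2L]] <- deg[pr[, 2L]] + 1L
          need <- need - nrow(pr)
        }
      }
    }
    # date-like: extra edges spread over date_spread foreign modules
    for (v in idx[truth$role == "date_like"]) {
      need <- target - deg[v]
      if (need <= 0L) next
      foreign <- setdiff(seq_len(cfg$n_modules), truth$module[v])
      # the home module is always among the spread targets, so spread = 1
      # degenerates date-like wiring into party-like wiring
      mods <- c(truth$module[v],
                sample(foreign, min(cfg$date_spread - 1L, length(foreign))))
      per <- ceiling(need / length(mods))
      for (m in mods) {
        if (need <= 0L) break
        pr <- add_edges(v, blocks[[as.character(m)]], min(per, need))
        if (!is.null(pr)) {
          from <- c(from, pr[, 1L]); to <- c(to, pr[, 2L])
          deg[v] <- deg[v] + nrow(pr)
          need <- need - nrow(pr)
        }
      }
    }
    ga <- genes[from]; gb <- genes[to]
    same_mod <- !is.na(truth$module[from]) & !is.na(truth$module[to]) &
      truth$module[from] == truth$module[to]
    evidence <- ifelse(same_mod, "cocomplex", "y2h")
    ppi_network(ga, gb, evidence = evidence, vertices = genes)
  })
}

#' Generate the synthetic modular network
#'
#' Modules are wired as dense blocks (`p_in`) with sparse edges elsewhere
#' (`p_out`). Party-like hubs receive extra intra-module edges and
#' date-like hubs extra edges into `date_spread` foreign modules, until
#' both reach a shared top-quantile target degree, so planted classes
#' differ in wiring pattern but not degree. Intra-module edges carry the
#' evidence label `"cocomplex"`, cross-module edges `"y2h"`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `network` (an `igraph`) and `truth` (data frame
#'   `gene`, `module`, `role`).
#' @export
generate_network <- function(cfg) {
  truth <- planted_truth(cfg)
  net <- wire_network(cfg, truth, seed = cfg$seed + 1L)
  list(network = net, truth = truth)
}

#' Generate the synthetic expression compendium
#'
#' Module-factor model: for every dataset and condition, each module draws
#' a standard-normal factor; a gene's value is its loading times its home
#' module's factor plus Gaussian noise. Party-like hubs and ordinary module
#' members load at `loading_party`, date-like hubs at `loading_date`, and
#' background genes at 0, so co-expression tracks module membership.
#' Replicate columns add small replicate noise, entries are masked missing
#' at `missing_rate`, and the first dataset is emitted on an absolute
#' signal scale (`2^(x + 8)`) to exercise the log transform.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Planted truth from [generate_network()].
#' @param seed Seed; defaults to `cfg$seed + 2`.
#' @return List of raw `expression_dataset` objects.
#' @export
generate_expression <- function(cfg, truth, seed = cfg$seed + 2L) {
  with_seed(seed, {
    loading <- ifelse(truth$role == "date_like", cfg$loading_date,
                      ifelse(is.na(truth$module), 0, cfg$loading_party))
    lapply(seq_len(cfg$n_datasets), function(d) {
      vals <- list(); groups <- character(0)
      for (e in seq_len(cfg$n_conditions)) {
        fac <- rnorm(cfg$n_modules)
        base <- ifelse(is.na(truth$module), 0, loading * fac[truth$module]) +
          cfg$noise_sd * rnorm(nrow(truth))
        for (r in seq_len(cfg$replicate_count)) {
          col <- base + cfg$replicate_sd * rnorm(nrow(truth))
          vals[[length(vals) + 1L]] <- col
          groups <- c(groups, sprintf("c%03d", e))
        }
      }
      M <- do.call(cbind, vals)
      rownames(M) <- truth$gene
      colnames(M) <- sprintf("%s_r%d", groups,
                             rep(seq_len(cfg$replicate_count), cfg$n_conditions))
      M[matrix(runif(length(M)) < cfg$missing_rate, nrow(M))] <- NA_real_
      is_abs <- d == 1L
      if (is_abs) M <- 2^(M + 8)
      expression_dataset(M, replicate_groups = groups, is_absolute = is_abs,
                         id = sprintf("ds%d", d))
    })
  })
}

#' Generate the synthetic ontology, annotations and auxiliary labels
#'
#' Builds a three-namespace toy ontology whose BP branch has broad terms
#' for a metabolic-like process (parent of one term per module), a
#' regulation-like process (parent of a core term annotating date-like
#' hubs) and a transport-like process annotated at random. Module members
#' (including party-like hubs) are annotated with their module term, while
#' date-like hubs carry the regulation-core term instead, reflecting their
#' cross-module regulatory character. Essentiality is Bernoulli with a
#' higher rate for party-like hubs; genetic-interaction partners are drawn
#' so date-like hubs have the largest expected genetic degree.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Planted truth.
#' @param seed Seed; defaults to `cfg$seed + 3`.
#' @return List with `ontology`, `annotations`, `essential` (character
#'   vector) and `genetic_edges` (data frame `from`, `to`, `sign`).
#' @export
generate_annotations_and_labels <- function(cfg, truth, seed = cfg$seed + 3L) {
  with_seed(seed, {
    mod_terms <- sprintf("BP:module%02d", seq_len(cfg$n_modules))
    parents <- c(
      list("BP:root" = character(0),
           "BP:metabolic_like" = "BP:root",
           "BP:regulation_like" = "BP:root",
           "BP:transport_like" = "BP:root",
           "BP:regulation_core" = "BP:regulation_like",
           "CC:root" = character(0),
           "CC:complex_like" = "CC:root",
           "CC:membrane_like" = "CC:root",
           "MF:root" = character(0),
           "MF:binding_like" = "MF:root",
           "MF:catalysis_like" = "MF:root"),
      setNames(rep(list("BP:metabolic_like"), cfg$n_modules), mod_terms))
    ns <- setNames(sub(":.*", "", names(parents)), names(parents))
    ont <- ontology(parents, ns)
    genes <- truth$gene
    direct <- setNames(vector("list", length(genes)), genes)
    in_mod <- !is.na(truth$module)
    # annotations follow the wiring: date-like hubs are annotated as
    # cross-module regulators only when they actually are intermodular
    # (date_spread > 1); in the degenerate single-module world they are
    # ordinary module members
    date_regulates <- cfg$date_spread > 1L
    for (i in which(in_mod & (truth$role != "date_like" | !date_regulates))) {
      direct[[genes[i]]] <- mod_terms[truth$module[i]]
    }
    if (date_regulates) {
      for (i in which(truth$role == "date_like")) {
        direct[[genes[i]]] <- "BP:regulation_core"
      }
    }
    transport <- genes[runif(length(genes)) < 0.08]
    cc1 <- genes[runif(length(genes)) < 0.25]
    cc2 <- genes[runif(length(genes)) < 0.15]
    mf1 <- genes[runif(length(genes)) < 0.25]
    mf2 <- genes[runif(length(genes)) < 0.15]
    for (g in transport) direct[[g]] <- c(direct[[g]], "BP:transport_like")
    for (g in cc1) direct[[g]] <- c(direct[[g]], "CC:complex_like")
    for (g in cc2) direct[[g]] <- c(direct[[g]], "CC:membrane_like")
    for (g in mf1) direct[[g]] <- c(direct[[g]], "MF:binding_like")
    for (g in mf2) direct[[g]] <- c(direct[[g]], "MF:catalysis_like")
    direct <- direct[!vapply(direct, is.null, logical(1L))]
    ann <- annotation_set(direct, ont)
    ess_rate <- ifelse(truth$role == "party_like", cfg$essential_rate_intra,
                       ifelse(truth$role == "date_like", cfg$essential_rate_inter,
                              cfg$essential_rate_background))
    essential <- genes[runif(length(genes)) < ess_rate]
    gi_rate <- ifelse(truth$role == "party_like", cfg$genetic_rate_intra,
                      ifelse(truth$role == "date_like", cfg$genetic_rate_inter,
                             cfg$genetic_rate_background))
    n_partners <- rpois(length(genes), gi_rate)
    from <- rep(genes, n_partners)
    to <- sample(genes, sum(n_partners), replace = TRUE)
    keep <- from != to
    genetic <- data.frame(from = pmin(from, to)[keep], to = pmax(from, to)[keep],
                          stringsAsFactors = FALSE)
    genetic <- genetic[!duplicated(genetic), , drop = FALSE]
    genetic$sign <- sample(c("+", "-"), nrow(genetic), replace = TRUE,
                           prob = c(0.4, 0.6))
    list(ontology = ont, annotations = ann, essential = sort(essential),
         genetic_edges = genetic)
  })
}

#' Generate the orthologous second world
#'
#' The second "organism" network and expression compendium are regenerated
#' from the same planted truth with independent seeds (same modules and
#' roles, resampled edges and expression). The ortholog map pairs each gene
#' with its counterpart with probability `ortholog_fraction` and adds an
#' extra within-module partner with probability `ortholog_many_rate`,
#' producing one-to-many families.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Planted truth of the first world.
#' @param seed Seed; defaults to `cfg$seed + 11`.
#' @return List with `network`, `expression` (raw datasets) and `map`
#'   (data frame `gene1`, `gene2`, `family_id`).
#' @export
generate_ortholog_world <- function(cfg, truth, seed = cfg$seed + 11L) {
  net2 <- wire_network(cfg, truth, seed = seed)
  expr2 <- generate_expression(cfg, truth, seed = seed + 1L)
  map <- with_seed(seed + 2L, {
    genes <- truth$gene
    keep <- runif(length(genes)) < cfg$ortholog_fraction
    g1 <- genes[keep]; g2 <- genes[keep]
    extra <- which(keep & runif(length(genes)) < cfg$ortholog_many_rate &
                     !is.na(truth$module))
    e1 <- character(0); e2 <- character(0)
    for (i in extra) {
      mates <- setdiff(genes[!is.na(truth$module) &
                               truth$module == truth$module[i]], genes[i])
      if (length(mates) > 0L) {
        e1 <- c(e1, genes[i]); e2 <- c(e2, sample(mates, 1L))
      }
    }
    df <- data.frame(gene1 = c(g1, e1), gene2 = c(g2, e2),
                     stringsAsFactors = FALSE)
    df$family_id <- paste0("fam_", df$gene1)
    df[order(df$gene1, df$gene2), , drop = FALSE]
  })
  list(network = net2, expression = expr2, map = map)
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper producing every input the pipeline consumes:
#' network with planted truth, raw expression datasets, ontology and
#' annotations, essential genes, genetic interactions, and the orthologous
#' second world with its map.
#'
#' @param cfg A [synthetic_config()].
#' @param with_orthologs Logical; generate the second world.
#' @return List with elements `config`, `network`, `truth`, `expression`,
#'   `ontology`, `annotations`, `essential`, `genetic_edges`, and when
#'   requested `world2` (with `network`, `expression`) and `ortholog_map`.
#' @export
generate_world <- function(cfg = synthetic_config(), with_orthologs = TRUE) {
  gn <- generate_network(cfg)
  expr <- generate_expression(cfg, gn$truth)
  lab <- generate_annotations_and_labels(cfg, gn$truth)
  out <- list(config = cfg, network = gn$network, truth = gn$truth,
              expression = expr, ontology = lab$ontology,
              annotations = lab$annotations, essential = lab$essential,
              genetic_edges = lab$genetic_edges)
  if (with_orthologs) {
    ow <- generate_ortholog_world(cfg, gn$truth)
    out$world2 <- list(network = ow$network, expression = ow$expression)
    out$ortholog_map <- ow$map
  }
  out
}

#' Write a synthetic world to a directory of plain-text input files
#'
#' Emits every input format the pipeline consumes: `network.tsv` edge list
#' with evidence, `expression.tsv` + `expression_design.tsv`,
#' `ontology.tsv`, `associations.tsv`, `essential.txt`, `genetic.tsv`,
#' `orthologs.tsv` plus the second world's files, and `truth.tsv`.
#'
#' @param world From [generate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_edge_list(world$network, fp("network.tsv"))
  write_expression_tsv(world$expression, fp("expression.tsv"),
                       fp("expression_design.tsv"))
  write_ontology_tsv(world$ontology, fp("ontology.tsv"))
  write_associations_tsv(world$annotations, fp("associations.tsv"))
  writeLines(world$essential, fp("essential.txt"))
  write.table(world$genetic_edges, fp("genetic.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(world$world2)) {
    write_edge_list(world$world2$network, fp("network2.tsv"))
    write_expression_tsv(world$world2$expression, fp("expression2.tsv"),
                         fp("expression2_design.tsv"))
    write.table(world$ortholog_map, fp("orthologs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
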