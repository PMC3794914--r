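# Shared synthetic fixtures, generated once per test run and memoized.
# The small world keeps unit tests fast; the default world is reserved for
# the acceptance-style integration checks.

.world_cache <- new.env(parent = emptyenv())

small_config <- function(...) {
  base <- list(n_modules = 6L, module_size = 25L, n_background = 60L,
               p_in = 0.25, p_out = 0.006,
               n_party = 12L, n_date = 18L, n_party_modules = 3L,
               date_spread = 4L,
               n_datasets = 2L, n_conditions = 30L,
               genetic_rate_intra = 3, genetic_rate_inter = 12,
               genetic_rate_background = 1, seed = 7L)
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

small_world <- function() {
  if (is.null(.world_cache$small)) {
    .world_cache$small <- generate_world(small_config())
  }
  .world_cache$small
}

small_world_features <- function() {
  if (is.null(.world_cache$small_features)) {
    w <- small_world()
    comp <- expression_compendium(w$expression)
    sm <- coexpression_matrix(comp, genes = igraph::V(w$network)$name)
    .world_cache$small_features <- list(
      world = w, score_matrix = sm,
      fw = compute_hub_features(w$network, scores = sm,
                                annotations = w$annotations))
  }
  .world_cache$small_features
}

default_world <- function() {
  if (is.null(.world_cache$default)) {
    .world_cache$default <- generate_world(synthetic_config())
  }
  .world_cache$default
}

default_world_features <- function() {
  if (is.null(.world_cache$default_features)) {
    w <- default_world()
    comp <- expression_compendium(w$expression)
    sm <- coexpression_matrix(comp, genes = igraph::V(w$network)$name)
    .world_cache$default_features <- list(
      world = w, score_matrix = sm,
      fw = compute_hub_features(w$network, scores = sm,
                                annotations = w$annotations))
  }
  .world_cache$default_features
}

default_world2_features <- function() {
  if (is.null(.world_cache$default2)) {
    w <- default_world()
    comp2 <- expression_compendium(w$world2$expression)
    sm2 <- coexpression_matrix(comp2,
                               genes = igraph::V(w$world2$network)$name)
    .world_cache$default2 <- compute_hub_features(
      w$world2$network, scores = sm2, annotations = w$annotations)
  }
  .world_cache$default2
}

# signal-free configuration: equal loadings, equal label rates, date hubs
# collapsed onto their home module, no complex-core wiring preference
null_config <- function() {
  synthetic_config(loading_party = 0.5, loading_date = 0.5,
                   essential_rate_intra = 0.1, essential_rate_inter = 0.1,
                   essential_rate_background = 0.1,
                   genetic_rate_intra = 5, genetic_rate_inter = 5,
                   genetic_rate_background = 5,
                   date_spread = 1L, party_coherence = FALSE)
}

null_world_features <- function() {
  if (is.null(.world_cache$nullw)) {
    w <- generate_world(null_config(), with_orthologs = FALSE)
    comp <- expression_compendium(w$expression)
    sm <- coexpression_matrix(comp, genes = igraph::V(w$network)$name)
    .world_cache$nullw <- list(
      world = w,
      fw = compute_hub_features(w$network, scores = sm,
                                annotations = w$annotations))
  }
  .world_cache$nullw
}

planted_roles <- function(world) {
  split(world$truth$gene, world$truth$role)
}

planted_truth_test <- function(cfg) {
  hubdyn:::planted_truth(cfg)
}
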