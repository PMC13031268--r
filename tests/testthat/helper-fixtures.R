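# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Two-study collection, small but with enough signal to classify.
tiny_collection <- function() cached("tiny", {
  generate_collection(collection_config(
    n_studies = 2, cells_per_study = c(100L, 100L), n_genes = 150,
    n_types = 3, n_subtypes_per_type = 1, marker_genes_per_type = 8,
    lowq_cell_fraction = 0, seed = 11
  ))
})

# Four-study collection for grid tests.
grid_collection <- function() cached("grid", {
  generate_collection(collection_config(
    n_studies = 4, cells_per_study = rep(90L, 4), n_genes = 150,
    n_types = 3, n_subtypes_per_type = 1, marker_genes_per_type = 8,
    lowq_cell_fraction = 0, seed = 21
  ))
})

grid_prep <- function() cached("grid_prep", {
  preprocess_collection(grid_collection(), n_hvg = 60)
})

# Fast hyperparameters for structural tests (override any field via ...).
tiny_hp <- function(...) {
  args <- list(hidden_sizes = c(16L, 8L), epochs = 3L, batch_size = 32L,
               validation_fraction = 0, seed = 5L)
  over <- list(...)
  args[names(over)] <- over
  do.call(mlp_hyperparams, args)
}

# Small linearly separable two-class toy problem.
toy_problem <- function(n = 60, seed = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2, -2), ncol = 2),
             matrix(rnorm(n * 2, 2), ncol = 2))
  list(x = x, y = rep(c("a", "b"), each = n))
}

# A study built directly from a dense count matrix.
study_from_counts <- function(counts, gene_ids, labels = NULL, id = "T1") {
  new_swarm_study(
    study_id = id, counts = counts, gene_ids = gene_ids,
    cell_ids = sprintf("%s_c%d", id, seq_len(nrow(counts))),
    labels_type = labels %||% rep("X", nrow(counts))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
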