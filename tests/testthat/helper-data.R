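# Small fixtures built in code.

# Linearly separable 2-class toy set: class A expresses genes 1-2, class B
# genes 3-4, with mild noise. Returns zscored matrix ready for training.
make_toy_separable <- function(n_per_class = 10L, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * 4L, sd = 0.3), n, 4L,
              dimnames = list(sprintf("c%02d", 1:n), paste0("g", 1:4)))
  X[1:n_per_class, 1:2] <- X[1:n_per_class, 1:2] + 3
  X[(n_per_class + 1):n, 3:4] <- X[(n_per_class + 1):n, 3:4] + 3
  y <- rep(c("A", "B"), each = n_per_class)
  list(X = scale(X), y = y)
}

# A small trained pathway model on a tiny synthetic dataset, cached per
# session (used across encoding / interpret tests).
tiny_trained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ds <- generate_dataset(synthetic_config(
      n_cell_types = 3L, cells_per_type = 40L, n_genes = 200L,
      n_pathways = 8L, genes_per_pathway = 20L,
      active_pathways_per_type = 2L, seed = 7L))
    inter <- intersect_gene_space(ds$expression, ds$gene_sets, "biological_only")
    mask <- build_mask(colnames(inter$expression), inter$collection)
    pp <- preprocess_expression(inter$expression, "zscore")
    cfg <- network_config(colnames(inter$expression), n_classes = 3L, seed = 7L)
    model <- build_network(cfg, mask)
    model <- train_network(model, pp$expression, ds$labels,
                           training_config(epochs = 30L, seed = 7L))
    model$preprocess_stats <- pp$stats
    cache <<- list(model = model, X = pp$expression, raw = inter$expression,
                   labels = ds$labels, mask = mask,
                   collection = inter$collection, truth = ds$truth)
    cache
  }
})

write_tmp_gmt <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
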