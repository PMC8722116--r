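test_that("stratified split follows largest-remainder apportionment", {
  y <- rep(c("A", "B"), c(60, 40))
  sp <- stratified_split(y, 0.30, seed = 1L)
  expect_equal(sum(y[sp$test] == "A"), 18L)
  expect_equal(sum(y[sp$test] == "B"), 12L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(y))

  # every class keeps at least one training cell
  y2 <- rep(c("A", "B"), c(2, 20))
  sp2 <- stratified_split(y2, 0.5, seed = 2L)
  expect_gte(sum(y2[sp2$train] == "A"), 1L)

  expect_error(stratified_split(c("A", "B", "B"), 0.3), "single member")
})

test_that("repeated holdout trains per repeat with train-fitted statistics", {
  tt <- tiny_trained()
  cfg <- network_config(colnames(tt$raw), n_classes = 3L, seed = 1L)
  plan <- holdout_plan(repeats = 3L, test_size = 0.30, base_seed = 50L)
  rep <- repeated_stratified_holdout(tt$raw, tt$labels, cfg,
                                     training_config(epochs = 15L, seed = 1L),
                                     plan, tt$mask)
  expect_s3_class(rep, "pathnn_report")
  expect_equal(nrow(rep$records), 3L)
  expect_equal(rep$records$seed, 50L + 1:3)

  # summary mean recomputable from records
  expect_equal(rep$summary$mean$accuracy, mean(rep$records$accuracy))

  # leakage guard: recorded stats checksum equals the train-only refit and
  # differs from a test-inclusive fit
  r <- 1L
  sp <- stratified_split(tt$labels, 0.30, seed = 50L + r)
  train_stats <- preprocess_expression(tt$raw[sp$train, ], "zscore")$stats
  full_stats <- preprocess_expression(tt$raw, "zscore")$stats
  checksum <- function(s) sum(unlist(Filter(is.numeric, s)))
  expect_equal(rep$records$stats_checksum[r], checksum(train_stats))
  expect_false(isTRUE(all.equal(checksum(train_stats), checksum(full_stats))))

  # the separable synthetic types classify well out of sample
  expect_gt(rep$summary$mean$accuracy, 0.9)
})

test_that("LPGO holds out whole cell types and clusters their encodings", {
  tt <- tiny_trained()
  cfg <- network_config(colnames(tt$raw), n_classes = 3L, seed = 1L)
  plan <- lpgo_plan(P = 2L, repeats = 3L, base_seed = 9L)
  expect_error(lpgo_protocol(tt$raw, tt$labels, cfg, training_config(), plan,
                             tt$mask),
               "training fold needs")

  # 5-type dataset allows P = 2 with 3 training classes
  ds <- generate_dataset(synthetic_config(
    n_cell_types = 5L, cells_per_type = 30L, n_genes = 200L, n_pathways = 8L,
    genes_per_pathway = 20L, active_pathways_per_type = 2L, seed = 15L))
  inter <- intersect_gene_space(ds$expression, ds$gene_sets, "biological_only")
  mask <- build_mask(colnames(inter$expression), inter$collection)
  cfg5 <- network_config(colnames(inter$expression), n_classes = 5L, seed = 2L)
  rep <- lpgo_protocol(inter$expression, ds$labels, cfg5,
                       training_config(epochs = 15L, seed = 2L),
                       lpgo_plan(P = 2L, repeats = 3L, base_seed = 9L), mask)
  expect_equal(nrow(rep$records), 3L)
  # held-out classes never seen in training (recorded list has P entries)
  held <- strsplit(rep$records$held_out, ",")
  expect_true(all(lengths(held) == 2L))
  # same base seed reproduces the same class selections
  rep2 <- lpgo_protocol(inter$expression, ds$labels, cfg5,
                        training_config(epochs = 15L, seed = 2L),
                        lpgo_plan(P = 2L, repeats = 3L, base_seed = 9L), mask)
  expect_identical(rep$records$held_out, rep2$records$held_out)
  expect_equal(rep$records$ari, rep2$records$ari)
})

test_that("retrieval protocol scores disjoint learning/retrieval sets", {
  ds <- generate_dataset(synthetic_config(
    n_cell_types = 3L, cells_per_type = 40L, n_genes = 200L, n_pathways = 8L,
    genes_per_pathway = 20L, active_pathways_per_type = 2L, seed = 33L))
  inter <- intersect_gene_space(ds$expression, ds$gene_sets, "biological_only")
  mask <- build_mask(colnames(inter$expression), inter$collection)
  set.seed(33)
  idx <- sample(nrow(inter$expression), 60L)
  cfg <- network_config(colnames(inter$expression), n_classes = 3L, seed = 3L)
  expect_warning(
    rep <- retrieval_protocol(
      list(expression = inter$expression[idx, ], labels = ds$labels[idx]),
      list(expression = inter$expression[-idx, ], labels = ds$labels[-idx]),
      cfg, training_config(epochs = 20L, seed = 3L),
      retrieval_config(k = 100L), mask),
    "clamped")  # reference has 60 < 100 cells
  expect_gte(rep$mean_map, 0.9)

  # retrieval-only class is reported with MAP 0
  y2 <- ds$labels[-idx]
  y2[1:10] <- "unseen_type"
  expect_warning(rep2 <- retrieval_protocol(
    list(expression = inter$expression[idx, ], labels = ds$labels[idx]),
    list(expression = inter$expression[-idx, ], labels = y2),
    cfg, training_config(epochs = 20L, seed = 3L),
    retrieval_config(k = 100L), mask), "clamped")
  expect_equal(rep2$records$map[rep2$records$class == "unseen_type"], 0)
})

test_that("hyperband schedule reproduces the successive-halving arithmetic", {
  s <- hyperband_schedule(9L, 3L)
  b2 <- s[s$bracket == 2, ]
  expect_equal(b2$n_configs, c(9L, 3L, 1L))
  expect_equal(b2$epochs, c(1L, 3L, 9L))
  b0 <- s[s$bracket == 0, ]
  expect_equal(b0$epochs, 9L)
})

test_that("hyperband returns a seeded, reproducible best configuration", {
  toy <- make_toy_separable(n_per_class = 15L)
  cfg <- network_config(colnames(toy$X), n_classes = 2L, dense_nodes = 3L,
                        seed = 4L)
  plan <- hyperband_plan(max_resource = 9L, eta = 3L, seed = 4L)
  r1 <- hyperband_tune(toy$X, toy$y, cfg, plan, preprocess = "none")
  r2 <- hyperband_tune(toy$X, toy$y, cfg, plan, preprocess = "none")
  expect_s3_class(r1$best, "training_config")
  expect_identical(r1$trials, r2$trials)
  expect_gte(r1$best_score, 0.5)
  # single-point space returns that configuration
  plan1 <- hyperband_plan(max_resource = 3L, eta = 3L,
                          lr_range = c(0.01, 0.01),
                          momentum_range = c(0.9, 0.9),
                          decay_range = c(1e-6, 1e-6), seed = 4L)
  r3 <- hyperband_tune(toy$X, toy$y, cfg, plan1, preprocess = "none")
  expect_equal(r3$best$learning_rate, 0.01, tolerance = 1e-12)
  expect_equal(r3$best$momentum, 0.9, tolerance = 1e-12)
})
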