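#' Stratified train/test split
#'
#' Per-class test counts follow largest-remainder apportionment of
#' `test_size` (so a 60/40 split of 100 cells at 0.30 gives exactly 18 and 12
#' test cells), capped so every class keeps at least one training cell.
#'
#' @param y label vector.
#' @param test_size test fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_size = 0.30, seed = 1L) {
  stopifnot(test_size > 0, test_size < 1)
  y <- as.character(y)
  n <- length(y)
  classes <- sort(unique(y))
  counts <- vapply(classes, function(c0) sum(y == c0), integer(1L))
  if (any(counts < 2L)) {
    stop("class(es) with a single member cannot be stratified: ",
         paste(classes[counts < 2L], collapse = ", "))
  }
  quota <- counts * test_size
  take <- floor(quota)
  target <- round(n * test_size)
  rem <- target - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  take <- pmin(take, counts - 1L)  # every class keeps >= 1 training cell
  set.seed(seed)
  test <- unlist(lapply(seq_along(classes), function(i) {
    idx <- which(y == classes[i])
    if (take[i] == 0L) integer() else sample(idx, take[i])
  }), use.names = FALSE)
  list(train = setdiff(seq_len(n), test), test = sort(test))
}

#' Validation plans
#'
#' `holdout_plan`: repeated stratified holdout (default 100 repeats, test
#' fraction 0.30). `lpgo_plan`: leave-P-groups-out over cell types (default
#' 20 repeats). `hyperband_plan`: hyperband search over the SGD learning
#' rate (log-uniform), momentum (uniform) and decay (log-uniform).
#'
#' @param repeats number of repetitions.
#' @param test_size holdout test fraction.
#' @param base_seed integer; repeat r uses seed `base_seed + r`.
#' @return a plan object.
#' @export
holdout_plan <- function(repeats = 100L, test_size = 0.30, base_seed = 1L) {
  stopifnot(repeats >= 1L, test_size > 0, test_size < 1)
  structure(list(repeats = as.integer(repeats), test_size = test_size,
                 base_seed = as.integer(base_seed)),
            class = "holdout_plan")
}

#' @rdname holdout_plan
#' @param P number of cell types held out per repeat (must be < number of
#'   classes, and leave at least 2 training classes).
#' @export
lpgo_plan <- function(P, repeats = 20L, base_seed = 1L) {
  stopifnot(P >= 2L, repeats >= 1L)
  structure(list(P = as.integer(P), repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed)),
            class = "lpgo_plan")
}

#' @rdname holdout_plan
#' @param max_resource maximum training epochs a configuration may receive.
#' @param eta halving factor (>= 2).
#' @param lr_range,momentum_range,decay_range search-space bounds.
#' @param seed integer seed for configuration sampling.
#' @export
hyperband_plan <- function(max_resource = 27L, eta = 3L,
                           lr_range = c(1e-4, 1e-1),
                           momentum_range = c(0, 0.99),
                           decay_range = c(1e-6, 1e-2), seed = 1L) {
  stopifnot(eta >= 2L, max_resource >= eta)
  structure(list(max_resource = as.integer(max_resource), eta = as.integer(eta),
                 lr_range = lr_range, momentum_range = momentum_range,
                 decay_range = decay_range, seed = as.integer(seed)),
            class = "hyperband_plan")
}

#' @export
print.pathnn_report <- function(x, ...) {
  cat("pathnn_report:", x$protocol, "-", nrow(x$records), "record(s)\n")
  num <- vapply(x$summary$mean, is.numeric, logical(1L))
  means <- unlist(x$summary$mean[num])
  print(round(means, 4))
  invisible(x)
}

make_report <- function(protocol, records, config) {
  num_cols <- vapply(records, is.numeric, logical(1L))
  num_cols[names(records) %in% c("repeat_id", "seed")] <- FALSE
  nums <- records[, num_cols, drop = FALSE]
  summary <- list(mean = as.list(colMeans(nums)),
                  median = as.list(apply(nums, 2L, stats::median)))
  structure(list(protocol = protocol, records = records, summary = summary,
                 config = config),
            class = "pathnn_report")
}

# Rebuild a network_config template with a per-repeat seed / class count.
derive_config <- function(net_cfg, seed, n_classes = net_cfg$n_classes) {
  network_config(net_cfg$input_genes, n_classes,
                 activation = net_cfg$activation,
                 dense_nodes = net_cfg$dense_nodes,
                 hidden = net_cfg$hidden, seed = seed)
}

derive_tcfg <- function(train_cfg, seed) {
  training_config(train_cfg$optimizer, train_cfg$learning_rate,
                  train_cfg$momentum, train_cfg$decay, train_cfg$epochs,
                  train_cfg$batch_size, seed = seed)
}

#' Repeated stratified holdout validation
#'
#' Per repeat: stratified split (seeded `base_seed + r`), preprocessing fit on
#' the training fold only and reused on the test fold, supervised training,
#' and classification metrics on the held-out cells.
#'
#' @param X raw cells x genes matrix (columns in `net_cfg$input_genes` order).
#' @param y labels aligned to rows of `X`.
#' @param net_cfg a [network_config()] template (its seed is offset per
#'   repeat).
#' @param train_cfg a [training_config()] template.
#' @param plan a [holdout_plan()].
#' @param mask optional prior mask for the first layer.
#' @param preprocess preprocessing method, see [preprocess_expression()].
#' @return a `pathnn_report` whose `records` hold one row of metrics per
#'   repeat (plus the repeat seed and a checksum of the train-fitted
#'   preprocessing statistics).
#' @export
repeated_stratified_holdout <- function(X, y, net_cfg, train_cfg,
                                        plan = holdout_plan(), mask = NULL,
                                        preprocess = "zscore") {
  y <- as.character(y)
  records <- vector("list", plan$repeats)
  for (r in seq_len(plan$repeats)) {
    seed_r <- plan$base_seed + r
    sp <- stratified_split(y, plan$test_size, seed = seed_r)
    pp <- preprocess_expression(X[sp$train, , drop = FALSE], preprocess)
    ppt <- preprocess_expression(X[sp$test, , drop = FALSE], preprocess,
                                 stats = pp$stats)
    model <- build_network(derive_config(net_cfg, net_cfg$seed + r), mask)
    model <- train_network(model, pp$expression, y[sp$train],
                           derive_tcfg(train_cfg, train_cfg$seed + r))
    pred <- predict_proba(model, ppt$expression)
    m <- supervised_metrics(y[sp$test], pred$predicted)
    checksum <- sum(unlist(Filter(is.numeric, pp$stats)))
    records[[r]] <- data.frame(repeat_id = r, seed = seed_r,
                               stats_checksum = checksum,
                               as.data.frame(m))
  }
  make_report("holdout", do.call(rbind, records),
              list(plan = unclass(plan), preprocess = preprocess,
                   network = unclass(net_cfg)[names(net_cfg) != "input_genes"],
                   training = unclass(train_cfg)))
}

#' Leave-P-groups-out clustering validation
#'
#' Per repeat: P cell types are drawn (seeded, without replacement) and all
#' their cells form the test fold; the network is trained on the remaining
#' types, the held-out cells are encoded with the output layer detached,
#' K-Means with K = P clusters the encodings, and the six clustering indices
#' compare clusters with the never-seen true types.
#'
#' @inheritParams repeated_stratified_holdout
#' @param plan an [lpgo_plan()].
#' @return a `pathnn_report`; `records` also keep the held-out types.
#' @export
lpgo_protocol <- function(X, y, net_cfg, train_cfg, plan, mask = NULL,
                          preprocess = "zscore") {
  stopifnot(inherits(plan, "lpgo_plan"))
  y <- as.character(y)
  classes <- sort(unique(y))
  M <- length(classes)
  if (plan$P >= M) stop("P = ", plan$P, " must be < number of classes (", M, ")")
  if (M - plan$P < 2L) stop("training fold needs >= 2 classes; reduce P")
  records <- vector("list", plan$repeats)
  for (r in seq_len(plan$repeats)) {
    seed_r <- plan$base_seed + r
    set.seed(seed_r)
    held_out <- sort(sample(classes, plan$P))
    test_idx <- which(y %in% held_out)
    train_idx <- which(!(y %in% held_out))
    stopifnot(length(intersect(unique(y[train_idx]), held_out)) == 0L)

    pp <- preprocess_expression(X[train_idx, , drop = FALSE], preprocess)
    ppt <- preprocess_expression(X[test_idx, , drop = FALSE], preprocess,
                                 stats = pp$stats)
    cfg_r <- derive_config(net_cfg, net_cfg$seed + r, n_classes = M - plan$P)
    model <- build_network(cfg_r, mask)
    model <- train_network(model, pp$expression, y[train_idx],
                           derive_tcfg(train_cfg, train_cfg$seed + r))
    enc <- encode(model, ppt$expression)
    clusters <- kmeans_cluster(enc, K = plan$P, seed = seed_r)
    m <- clustering_metrics(y[test_idx], clusters)
    records[[r]] <- data.frame(repeat_id = r, seed = seed_r,
                               held_out = paste(held_out, collapse = ","),
                               as.data.frame(m))
  }
  make_report("lpgo", do.call(rbind, records),
              list(plan = unclass(plan), preprocess = preprocess,
                   network = unclass(net_cfg)[names(net_cfg) != "input_genes"],
                   training = unclass(train_cfg)))
}

#' Retrieval validation on disjoint learning / retrieval sets
#'
#' The model is fitted on the full learning set; both sets are encoded; each
#' retrieval cell queries the learning encodings for its k nearest neighbours
#' and per-class mean average precision is reported. Gene spaces are
#' intersected to the common genes before training.
#'
#' @param learning,retrieval lists with elements `expression` and `labels`.
#' @param rcfg a [retrieval_config()].
#' @inheritParams repeated_stratified_holdout
#' @return a `pathnn_report` with per-class MAP records and mean.
#' @export
retrieval_protocol <- function(learning, retrieval, net_cfg, train_cfg,
                               rcfg = retrieval_config(), mask = NULL,
                               preprocess = "zscore") {
  common <- intersect(colnames(learning$expression),
                      colnames(retrieval$expression))
  if (length(common) == 0L) stop("empty common gene space")
  common <- colnames(learning$expression)[colnames(learning$expression) %in% common]
  Xl <- learning$expression[, common, drop = FALSE]
  Xr <- retrieval$expression[, common, drop = FALSE]
  if (!identical(common, net_cfg$input_genes)) {
    net_cfg <- network_config(common, net_cfg$n_classes,
                              activation = net_cfg$activation,
                              dense_nodes = net_cfg$dense_nodes,
                              hidden = net_cfg$hidden, seed = net_cfg$seed)
    if (!is.null(mask)) mask <- mask[common, , drop = FALSE]
  }
  pp <- preprocess_expression(Xl, preprocess)
  ppr <- preprocess_expression(Xr, preprocess, stats = pp$stats)
  model <- build_network(net_cfg, mask)
  model <- train_network(model, pp$expression, learning$labels, train_cfg)
  enc_ref <- encode(model, pp$expression)
  enc_query <- encode(model, ppr$expression)
  res <- retrieval_map(enc_ref, learning$labels, enc_query, retrieval$labels,
                       rcfg)
  records <- res$per_class
  records$repeat_id <- 1L
  rep <- make_report("retrieval", records,
                     list(k = rcfg$k, preprocess = preprocess,
                          network = unclass(net_cfg)[names(net_cfg) != "input_genes"],
                          training = unclass(train_cfg)))
  rep$mean_map <- res$mean
  rep$model <- model
  rep
}

#' Hyperband bracket schedule
#'
#' Standard hyperband arithmetic: `s_max = floor(log_eta(R))`; bracket `s`
#' starts `n = ceil((s_max + 1) / (s + 1) * eta^s)` configurations at
#' `R / eta^s` epochs and successively keeps the top `1/eta` fraction while
#' multiplying the budget by `eta`.
#'
#' @param max_resource maximum epochs `R`.
#' @param eta halving factor.
#' @return data.frame with columns `bracket`, `rung`, `n_configs`, `epochs`.
#' @export
hyperband_schedule <- function(max_resource, eta = 3L) {
  s_max <- floor(log(max_resource) / log(eta))
  rows <- list()
  for (s in s_max:0) {
    n <- ceiling((s_max + 1) / (s + 1) * eta^s)
    r <- max_resource / eta^s
    for (i in 0:s) {
      rows[[length(rows) + 1L]] <- data.frame(
        bracket = s, rung = i,
        n_configs = max(1L, floor(n / eta^i)),
        epochs = max(1L, as.integer(round(r * eta^i))))
    }
  }
  do.call(rbind, rows)
}

#' Hyperband tuning of SGD hyperparameters
#'
#' Searches learning rate (log-uniform), momentum (uniform) and decay
#' (log-uniform) with successive halving brackets. The objective is evaluated
#' on an internal stratified 80/20 validation split of the supplied data, so
#' any external evaluation set is never touched. Models are retrained from
#' scratch at each rung's epoch budget; everything is seeded, so the trial
#' log is reproducible.
#'
#' @inheritParams repeated_stratified_holdout
#' @param plan a [hyperband_plan()].
#' @param objective `function(model, X_val, y_val) -> scalar` (higher is
#'   better); defaults to validation accuracy.
#' @return list with `best` (a [training_config()]), `best_score` and
#'   `trials` (data.frame log).
#' @export
hyperband_tune <- function(X, y, net_cfg, plan = hyperband_plan(),
                           mask = NULL, preprocess = "zscore",
                           objective = NULL, batch_size = 10L) {
  y <- as.character(y)
  if (is.null(objective)) {
    objective <- function(model, X_val, y_val) {
      mean(predict_proba(model, X_val)$predicted == y_val)
    }
  }
  sp <- stratified_split(y, 0.20, seed = plan$seed)
  pp <- preprocess_expression(X[sp$train, , drop = FALSE], preprocess)
  ppv <- preprocess_expression(X[sp$test, , drop = FALSE], preprocess,
                               stats = pp$stats)
  Xtr <- pp$expression; ytr <- y[sp$train]
  Xval <- ppv$expression; yval <- y[sp$test]

  sched <- hyperband_schedule(plan$max_resource, plan$eta)
  trials <- list()
  best <- NULL; best_score <- -Inf
  for (s in unique(sched$bracket)) {
    rungs <- sched[sched$bracket == s, ]
    set.seed(plan$seed + s)
    n0 <- rungs$n_configs[1L]
    confs <- data.frame(
      id = paste0("b", s, "c", seq_len(n0)),
      learning_rate = exp(stats::runif(n0, log(plan$lr_range[1L]),
                                       log(plan$lr_range[2L]))),
      momentum = stats::runif(n0, plan$momentum_range[1L],
                              plan$momentum_range[2L]),
      decay = exp(stats::runif(n0, log(plan$decay_range[1L]),
                               log(plan$decay_range[2L]))),
      stringsAsFactors = FALSE)
    alive <- seq_len(n0)
    for (ri in seq_len(nrow(rungs))) {
      keep_n <- rungs$n_configs[ri]
      alive <- alive[seq_len(min(keep_n, length(alive)))]
      scores <- vapply(alive, function(ci) {
        tc <- training_config("sgd", confs$learning_rate[ci],
                              confs$momentum[ci], confs$decay[ci],
                              epochs = rungs$epochs[ri],
                              batch_size = batch_size, seed = plan$seed)
        model <- build_network(net_cfg, mask)
        model <- train_network(model, Xtr, ytr, tc)
        objective(model, Xval, yval)
      }, numeric(1L))
      trials[[length(trials) + 1L]] <- data.frame(
        bracket = s, rung = rungs$rung[ri], config = confs$id[alive],
        learning_rate = confs$learning_rate[alive],
        momentum = confs$momentum[alive], decay = confs$decay[alive],
        epochs = rungs$epochs[ri], score = scores,
        stringsAsFactors = FALSE)
      alive <- alive[order(scores, decreasing = TRUE)]
      if (ri == nrow(rungs)) {
        top <- alive[1L]
        sc <- max(scores)
        if (sc > best_score) {
          best_score <- sc
          best <- training_config("sgd", confs$learning_rate[top],
                                  confs$momentum[top], confs$decay[top],
                                  epochs = plan$max_resource,
                                  batch_size = batch_size, seed = plan$seed)
        }
      }
    }
  }
  list(best = best, best_score = best_score, trials = do.call(rbind, trials))
}
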