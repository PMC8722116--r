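test_that("activations match their closed forms", {
  expect_equal(apply_activation(0, "tanh"), 0)
  expect_equal(apply_activation(-3, "relu"), 0)
  expect_equal(apply_activation(c(0, 0), "softmax"), c(0.5, 0.5))
  x <- c(1, 2, 3)
  expect_equal(apply_activation(x, "softmax"), oracle_softmax(x),
               tolerance = 1e-12)
  # tanh as printed: (1 - e^-2x) / (1 + e^-2x)
  xs <- seq(-3, 3, by = 0.5)
  expect_equal(apply_activation(xs, "tanh"),
               (1 - exp(-2 * xs)) / (1 + exp(-2 * xs)), tolerance = 1e-12)
  # max-shift makes softmax stable for large logits
  expect_equal(sum(apply_activation(c(1000, 1000), "softmax")), 1)
  expect_warning(apply_activation(c(NaN, 1), "relu"), "NaN")
})

test_that("cross-entropy matches closed forms and is sample-order invariant", {
  expect_equal(cross_entropy(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
  expect_equal(cross_entropy(matrix(c(1, 0, 0, 0), 1),
                             matrix(rep(0.25, 4), 1)), log(4))
  Y <- diag(3); P <- matrix(c(.7, .2, .1, .1, .8, .1, .2, .2, .6), 3,
                            byrow = TRUE)
  perm <- c(3, 1, 2)
  expect_equal(cross_entropy(Y, P), cross_entropy(Y[perm, ], P[perm, ]))
  expect_error(cross_entropy(diag(2), P), "shapes differ")
})

test_that("network building is seeded, Glorot-bounded and mask-aware", {
  genes <- paste0("g", 1:6)
  gs <- gene_set_collection(list(S1 = c("g1", "g2"), S2 = "g3"))
  mask <- build_mask(genes, gs)
  cfg <- network_config(genes, n_classes = 2L, seed = 9L)
  m1 <- build_network(cfg, mask)
  m2 <- build_network(cfg, mask)
  expect_identical(m1$weights, m2$weights)  # determinism

  # free first-layer weights on the biological block == mask ones
  expect_equal(sum(m1$weights[[1L]] != 0), sum(mask))
  lim <- sqrt(6 / (6 + 2))
  expect_true(all(abs(m1$weights[[1L]]) <= lim))
  expect_true(all(m1$biases[[1L]] == 0))

  # all-ones mask is bitwise identical to the dense network of same widths
  ones <- matrix(1, 6, 2, dimnames = list(genes, c("S1", "S2")))
  m_ones <- build_network(cfg, ones)
  cfg_dense <- network_config(genes, n_classes = 2L, dense_nodes = 2L, seed = 9L)
  m_dense <- build_network(cfg_dense)
  expect_equal(unname(m_ones$weights[[1L]]), unname(m_dense$weights[[1L]]))
  expect_identical(m_ones$weights[[2L]], m_dense$weights[[2L]])

  expect_error(build_network(cfg, mask[rev(genes), ]), "row order")
})

test_that("training separates a separable toy set with decreasing loss", {
  toy <- make_toy_separable()
  cfg <- network_config(colnames(toy$X), n_classes = 2L, dense_nodes = 4L,
                        seed = 3L)
  model <- build_network(cfg)
  model <- train_network(model, toy$X, toy$y,
                         training_config(epochs = 30L, seed = 3L))
  expect_true(all(diff(model$history$loss[1:5]) < 0))
  pred <- predict_proba(model, toy$X)
  expect_equal(mean(pred$predicted == toy$y), 1.0)

  # determinism of the whole trajectory
  model2 <- train_network(build_network(cfg), toy$X, toy$y,
                          training_config(epochs = 30L, seed = 3L))
  expect_identical(model$weights, model2$weights)
})

test_that("adam optimizer also learns the toy problem", {
  toy <- make_toy_separable()
  cfg <- network_config(colnames(toy$X), n_classes = 2L, dense_nodes = 4L,
                        seed = 3L)
  model <- train_network(build_network(cfg), toy$X, toy$y,
                         training_config("adam", epochs = 30L, seed = 3L))
  expect_equal(mean(predict_proba(model, toy$X)$predicted == toy$y), 1.0)
})

test_that("masked weights stay exactly zero through training (incl. mid-epoch)", {
  tt <- tiny_trained()
  model <- tt$model
  expect_equal(max(abs(model$weights[[1L]][model$mask == 0])), 0)

  # via callback on a short rerun
  seen <- c()
  cb <- function(epoch, m, loss) {
    seen <<- c(seen, max(abs(m$weights[[1L]][m$mask == 0])))
  }
  cfg <- network_config(tt$model$config$input_genes, n_classes = 3L, seed = 7L)
  invisible(train_network(build_network(cfg, tt$mask), tt$X, tt$labels,
                          training_config(epochs = 3L, seed = 7L),
                          callback = cb))
  expect_equal(seen, rep(0, 3L))
})

test_that("all-ones-mask training trajectory equals the dense network", {
  toy <- make_toy_separable()
  ones <- matrix(1, 4, 3, dimnames = list(colnames(toy$X), paste0("S", 1:3)))
  cfg_m <- network_config(colnames(toy$X), n_classes = 2L, seed = 5L)
  cfg_d <- network_config(colnames(toy$X), n_classes = 2L, dense_nodes = 3L,
                          seed = 5L)
  tcfg <- training_config(epochs = 3L, seed = 5L)
  mm <- train_network(build_network(cfg_m, ones), toy$X, toy$y, tcfg)
  md <- train_network(build_network(cfg_d), toy$X, toy$y, tcfg)
  for (i in seq_along(mm$weights)) {
    expect_equal(unname(mm$weights[[i]]), unname(md$weights[[i]]),
                 tolerance = 1e-6)
  }
})

test_that("predict_proba rows are stochastic and match a manual forward pass", {
  tt <- tiny_trained()
  p <- predict_proba(tt$model, tt$X)$probabilities
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))

  # independent forward pass composed from plain matrix ops
  W <- tt$model$weights; B <- tt$model$biases
  h <- tanh(sweep(tt$X %*% W[[1L]], 2L, B[[1L]], "+"))
  z <- sweep(h %*% W[[2L]], 2L, B[[2L]], "+")
  pm <- t(apply(z, 1L, oracle_softmax))
  expect_equal(unname(p), unname(pm), tolerance = 1e-6)

  # shuffled columns are realigned; missing genes error with names
  shuf <- tt$X[, rev(colnames(tt$X))]
  expect_equal(predict_proba(tt$model, shuf)$probabilities, p)
  expect_error(predict_proba(tt$model, tt$X[, -1]), "missing model gene")
})

test_that("argmax ties break toward the lowest class index", {
  tt <- tiny_trained()
  model <- tt$model
  # force identical logits by zeroing the output layer
  model$weights[[2L]][] <- 0
  model$biases[[2L]][] <- 0
  pred <- predict_proba(model, tt$X[1:3, , drop = FALSE])
  expect_true(all(pred$predicted == model$class_order[1L]))
})

test_that("effective parameter count matches brute-force free-weight counts", {
  # 4 genes, sets {g1,g2},{g3}: 3 mask ones + 2 biases + 2*2 output + 2
  genes <- paste0("g", 1:4)
  gs <- gene_set_collection(list(S1 = c("g1", "g2"), S2 = "g3"))
  mask <- build_mask(genes, gs)
  cfg <- network_config(genes, n_classes = 2L)
  expect_equal(count_effective_parameters(cfg, mask), 11L)

  # all-ones mask equals the dense count of the same widths
  ones <- matrix(1, 4, 2, dimnames = list(genes, c("a", "b")))
  cfg_dense <- network_config(genes, n_classes = 2L, dense_nodes = 2L)
  expect_equal(count_effective_parameters(cfg, ones),
               count_effective_parameters(cfg_dense))

  # randomized masks against brute-force enumeration
  set.seed(11)
  for (i in 1:100) {
    ng <- sample(3:8, 1); nn <- sample(1:4, 1); M <- sample(2:5, 1)
    h2 <- if (runif(1) < 0.5) integer() else sample(2:6, 1)
    mk <- matrix(rbinom(ng * nn, 1, 0.6), ng, nn,
                 dimnames = list(paste0("g", 1:ng), paste0("S", 1:nn)))
    mk[cbind(sample(ng, nn, replace = TRUE), 1:nn)] <- 1  # no empty node
    cfg_i <- network_config(paste0("g", 1:ng), n_classes = M, hidden = h2)
    widths <- c(nn, h2, M)
    brute <- sum(mk == 1) + nn +
      sum(widths[-length(widths)] * widths[-1L]) + sum(widths[-1L])
    expect_equal(count_effective_parameters(cfg_i, mk), brute)
  }
})
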