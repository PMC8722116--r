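#' Activation functions
#'
#' `tanh(x) = (1 - e^(-2x)) / (1 + e^(-2x))`, `relu(x) = max(0, x)`,
#' `sigmoid(x) = 1 / (1 + e^(-x))`, `linear(x) = x`, and a numerically stable
#' (max-shifted) `softmax`. `softmax` normalises the whole vector; the others
#' are elementwise.
#'
#' @param x numeric vector.
#' @param kind activation name.
#' @return numeric vector of the same length.
#' @export
apply_activation <- function(x, kind = c("tanh", "relu", "sigmoid", "linear",
                                         "softmax")) {
  kind <- match.arg(kind)
  if (anyNA(x)) warning("NaN/NA in activation input; propagated")
  switch(kind,
    tanh = base::tanh(x),
    relu = pmax(x, 0),
    sigmoid = 1 / (1 + exp(-x)),
    linear = x,
    softmax = {
      e <- exp(x - max(x))
      e / sum(e)
    })
}

# Row-wise stable softmax for a matrix of logits.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Elementwise activation on a matrix.
act_fun <- function(z, kind) {
  switch(kind,
    tanh = base::tanh(z),
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    linear = z)
}

# Derivative of the activation expressed through the activation value a
# (and pre-activation z for relu's kink).
act_deriv <- function(a, z, kind) {
  switch(kind,
    tanh = 1 - a * a,
    relu = (z > 0) * 1,
    sigmoid = a * (1 - a),
    linear = array(1, dim = dim(a)))
}

#' Network architecture specification
#'
#' The first hidden layer may combine `dense_nodes` fully connected nodes with
#' one biological node per gene set of a prior mask (supplied at
#' [build_network()] time); columns are ordered dense first, then biological.
#' Any further hidden layers (`hidden`) are dense. Only the first hidden layer
#' may carry a mask.
#'
#' @param input_genes ordered gene identifiers of the input layer.
#' @param n_classes number of cell types M (>= 2).
#' @param activation hidden-layer activation: `"tanh"` (default, the choice
#'   that works best with standardised inputs), `"relu"`, `"sigmoid"` or
#'   `"linear"`. The output layer is always softmax.
#' @param dense_nodes number of unconstrained first-layer nodes (0 for a pure
#'   pathway layer).
#' @param hidden integer vector of widths of additional dense hidden layers
#'   (empty for a 1-hidden-layer design).
#' @param seed integer seed for Glorot initialisation.
#' @return an object of class `network_config`.
#' @export
network_config <- function(input_genes, n_classes,
                           activation = c("tanh", "relu", "sigmoid", "linear"),
                           dense_nodes = 0L, hidden = integer(), seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(length(input_genes) >= 1L, n_classes >= 2L, dense_nodes >= 0L)
  if (length(hidden) > 0L && any(hidden < 1L)) stop("hidden widths must be >= 1")
  structure(list(input_genes = as.character(input_genes),
                 n_classes = as.integer(n_classes),
                 activation = activation,
                 dense_nodes = as.integer(dense_nodes),
                 hidden = as.integer(hidden),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Training hyperparameters
#'
#' Defaults follow common practice for this architecture: 100 epochs with
#' mini-batches of 10; SGD with learning rate 0.01, momentum 0.9 and no decay
#' (decay `d` applies the classic schedule `lr_t = lr / (1 + d * t)` over
#' global steps `t`); Adam uses learning rate 0.001.
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param learning_rate,momentum,decay non-negative reals (momentum and decay
#'   are SGD-only).
#' @param epochs,batch_size positive integers.
#' @param seed integer seed for epoch shuffling.
#' @return an object of class `training_config`.
#' @export
training_config <- function(optimizer = c("sgd", "adam"),
                            learning_rate = NULL, momentum = 0.9, decay = 0,
                            epochs = 100L, batch_size = 10L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (is.null(learning_rate)) {
    learning_rate <- if (optimizer == "sgd") 0.01 else 0.001
  }
  stopifnot(learning_rate > 0, momentum >= 0, decay >= 0,
            epochs >= 1L, batch_size >= 1L)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, decay = decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Build an untrained knowledge-masked network
#'
#' Weights are Glorot-uniform initialised (limit `sqrt(6 / (fan_in + fan_out))`,
#' biases zero), deterministically under `config$seed`. When a mask is given,
#' the biological block of the first-layer weight matrix is multiplied
#' elementwise by the mask, so weights from genes outside a node's gene set
#' are exactly zero from the start; dense first-layer nodes stay fully
#' connected to all input genes. The full first-layer matrix is drawn before
#' masking, so an all-ones mask yields bitwise the same initialisation as an
#' unmasked dense layer of equal width.
#'
#' @param config a [network_config()].
#' @param mask optional binary genes x nodes matrix from [build_mask()]; its
#'   row order must equal `config$input_genes`.
#' @return an object of class `pathnn_model` (untrained).
#' @export
build_network <- function(config, mask = NULL) {
  stopifnot(inherits(config, "network_config"))
  n_in <- length(config$input_genes)
  n_bio <- 0L
  if (!is.null(mask)) {
    if (nrow(mask) != n_in || !identical(rownames(mask), config$input_genes)) {
      stop("mask row order must equal config$input_genes")
    }
    if (any(colSums(mask) == 0)) stop("mask has a node with zero covered genes")
    n_bio <- ncol(mask)
  }
  w1 <- config$dense_nodes + n_bio
  if (w1 < 1L) stop("first hidden layer is empty: give dense_nodes > 0 or a mask")
  widths <- c(n_in, w1, config$hidden, config$n_classes)

  set.seed(config$seed)
  weights <- vector("list", length(widths) - 1L)
  biases <- vector("list", length(widths) - 1L)
  for (i in seq_along(weights)) {
    fan_in <- widths[i]; fan_out <- widths[i + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    weights[[i]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                           nrow = fan_in, ncol = fan_out)
    biases[[i]] <- numeric(fan_out)
  }

  full_mask <- NULL
  bio_cols <- integer()
  node_names <- if (config$dense_nodes > 0L)
    paste0("dense_", seq_len(config$dense_nodes)) else character()
  if (!is.null(mask)) {
    full_mask <- cbind(matrix(1, n_in, config$dense_nodes),
                       unname(mask))
    bio_cols <- config$dense_nodes + seq_len(n_bio)
    node_names <- c(node_names, colnames(mask))
    weights[[1L]] <- weights[[1L]] * full_mask
  }
  colnames(weights[[1L]]) <- node_names
  rownames(weights[[1L]]) <- config$input_genes

  structure(list(weights = weights, biases = biases,
                 mask = full_mask, bio_cols = bio_cols,
                 node_names = node_names,
                 config = config, class_order = NULL,
                 preprocess_stats = NULL, history = NULL, trained = FALSE),
            class = "pathnn_model")
}

#' @export
print.pathnn_model <- function(x, ...) {
  widths <- c(length(x$config$input_genes),
              vapply(x$weights, ncol, integer(1L)))
  cat("pathnn_model:", paste(widths, collapse = " -> "),
      sprintf("(%s hidden, softmax output)%s\n", x$config$activation,
              if (x$trained) ", trained" else ", untrained"))
  if (length(x$bio_cols) > 0L) {
    cat("  first layer:", length(x$bio_cols), "biological node(s),",
        x$config$dense_nodes, "dense node(s);",
        sum(x$mask[, x$bio_cols]), "unmasked gene->node weights\n")
  }
  if (!is.null(x$class_order)) {
    cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  }
  invisible(x)
}

# Forward pass; returns list of per-layer activations (hidden) and
# probabilities. X is cells x genes in model input order.
forward_pass <- function(model, X, keep = FALSE) {
  act <- model$config$activation
  nh <- length(model$weights) - 1L
  a <- X
  hidden <- if (keep) vector("list", nh) else NULL
  zs <- if (keep) vector("list", nh) else NULL
  for (i in seq_len(nh)) {
    z <- a %*% model$weights[[i]]
    z <- sweep(z, 2L, model$biases[[i]], "+")
    a <- act_fun(z, act)
    if (keep) { hidden[[i]] <- a; zs[[i]] <- z }
  }
  zo <- sweep(a %*% model$weights[[nh + 1L]], 2L, model$biases[[nh + 1L]], "+")
  p <- softmax_rows(zo)
  list(p = p, hidden = hidden, z = zs)
}

# Align columns of X to the model's input gene order; error listing offenders.
align_genes <- function(model, X) {
  genes <- model$config$input_genes
  if (identical(colnames(X), genes)) return(X)
  missing <- setdiff(genes, colnames(X))
  if (length(missing) > 0L) {
    stop("input is missing model gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  }
  X[, genes, drop = FALSE]
}

#' Cross-entropy loss
#'
#' Mean over samples of `-sum_c y_oc log(p_oc)`, with probabilities clipped to
#' `[1e-12, 1]` before the logarithm.
#'
#' @param y_onehot samples x classes binary indicator matrix.
#' @param p samples x classes predicted probability matrix.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(y_onehot, p) {
  if (!all(dim(y_onehot) == dim(p))) stop("y_onehot and p shapes differ")
  p <- pmin(pmax(p, 1e-12), 1)
  mean(-rowSums(y_onehot * log(p)))
}

#' Train a masked network by mini-batch backpropagation
#'
#' Minimises the multiclass cross-entropy with epoch-shuffled mini-batches.
#' Gradients into masked first-layer positions are zeroed and the weights are
#' defensively re-multiplied by the mask after every optimizer step, so masked
#' weights are exactly zero throughout training. The class order is the
#' lexicographic sort of the training labels. No early stopping: the
#' final-epoch model is returned, with the per-epoch mean training loss in
#' `$history`.
#'
#' @param model untrained model from [build_network()].
#' @param X preprocessed cells x genes matrix (columns in model input order).
#' @param y cell-type labels aligned to the rows of `X`.
#' @param tcfg a [training_config()].
#' @param callback optional `function(epoch, model, loss)` invoked after each
#'   epoch (used e.g. to assert the mask invariant mid-training).
#' @return the trained `pathnn_model`.
#' @export
train_network <- function(model, X, y, tcfg = training_config(),
                          callback = NULL) {
  stopifnot(inherits(model, "pathnn_model"), inherits(tcfg, "training_config"))
  X <- align_genes(model, X)
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("labels not aligned to expression rows")
  classes <- sort(unique(y))
  if (length(classes) != model$config$n_classes) {
    stop("config declares ", model$config$n_classes, " classes but labels have ",
         length(classes))
  }
  n <- nrow(X)
  Y <- matrix(0, n, length(classes))
  Y[cbind(seq_len(n), match(y, classes))] <- 1

  W <- model$weights; B <- model$biases
  L <- length(W)
  act <- model$config$activation
  msk <- model$mask

  # optimizer state
  vW <- lapply(W, function(w) w * 0); vB <- lapply(B, function(b) b * 0)
  if (tcfg$optimizer == "adam") {
    mW <- vW; mB <- vB
    uW <- vW; uB <- vB
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  }
  step <- 0L
  losses <- numeric(tcfg$epochs)

  set.seed(tcfg$seed)
  for (epoch in seq_len(tcfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = tcfg$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + tcfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      nb <- length(idx)

      # forward, keeping activations
      a_prev <- Xb
      As <- vector("list", L - 1L); Zs <- vector("list", L - 1L)
      for (i in seq_len(L - 1L)) {
        z <- sweep(a_prev %*% W[[i]], 2L, B[[i]], "+")
        a_prev <- act_fun(z, act)
        As[[i]] <- a_prev; Zs[[i]] <- z
      }
      P <- softmax_rows(sweep(a_prev %*% W[[L]], 2L, B[[L]], "+"))
      epoch_loss <- epoch_loss + cross_entropy(Yb, P) * nb

      # backward
      gW <- vector("list", L); gB <- vector("list", L)
      delta <- (P - Yb) / nb
      for (i in L:1) {
        a_in <- if (i == 1L) Xb else As[[i - 1L]]
        gW[[i]] <- crossprod(a_in, delta)
        gB[[i]] <- colSums(delta)
        if (i > 1L) {
          delta <- (delta %*% t(W[[i]])) * act_deriv(As[[i - 1L]], Zs[[i - 1L]], act)
        }
      }
      if (!is.null(msk)) gW[[1L]] <- gW[[1L]] * msk

      # update
      step <- step + 1L
      if (tcfg$optimizer == "sgd") {
        lr_t <- tcfg$learning_rate / (1 + tcfg$decay * (step - 1L))
        for (i in seq_len(L)) {
          vW[[i]] <- tcfg$momentum * vW[[i]] - lr_t * gW[[i]]
          vB[[i]] <- tcfg$momentum * vB[[i]] - lr_t * gB[[i]]
          W[[i]] <- W[[i]] + vW[[i]]
          B[[i]] <- B[[i]] + vB[[i]]
        }
      } else {
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        for (i in seq_len(L)) {
          mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gW[[i]]
          uW[[i]] <- beta2 * uW[[i]] + (1 - beta2) * gW[[i]]^2
          mB[[i]] <- beta1 * mB[[i]] + (1 - beta1) * gB[[i]]
          uB[[i]] <- beta2 * uB[[i]] + (1 - beta2) * gB[[i]]^2
          W[[i]] <- W[[i]] - tcfg$learning_rate * (mW[[i]] / bc1) /
            (sqrt(uW[[i]] / bc2) + eps)
          B[[i]] <- B[[i]] - tcfg$learning_rate * (mB[[i]] / bc1) /
            (sqrt(uB[[i]] / bc2) + eps)
        }
      }
      if (!is.null(msk)) W[[1L]] <- W[[1L]] * msk
    }
    losses[epoch] <- epoch_loss / n
    if (!is.null(callback)) {
      model$weights <- W; model$biases <- B
      callback(epoch, model, losses[epoch])
    }
  }

  model$weights <- W; model$biases <- B
  model$class_order <- classes
  model$history <- data.frame(epoch = seq_len(tcfg$epochs), loss = losses)
  model$training_config <- tcfg
  model$trained <- TRUE
  model
}

#' Predict cell-type probabilities
#'
#' Softmax output of the full network. Argmax ties are broken by the lowest
#' class index in the model's (lexicographic) class order.
#'
#' @param model a trained `pathnn_model`.
#' @param X preprocessed cells x genes matrix; columns are reordered to the
#'   model's input genes, and missing genes raise an error naming them.
#' @return list with `probabilities` (cells x M, rows sum to 1) and
#'   `predicted` (character vector of class labels).
#' @export
predict_proba <- function(model, X) {
  if (!model$trained) stop("model is not trained")
  X <- align_genes(model, X)
  p <- forward_pass(model, X)$p
  colnames(p) <- model$class_order
  rownames(p) <- rownames(X)
  list(probabilities = p,
       predicted = model$class_order[max.col(p, ties.method = "first")])
}

#' Count effective (free) parameters
#'
#' Free weights (mask ones for the biological block, everything for dense
#' blocks and layers) plus all biases, output layer included. This is the
#' size measure under which pathway-masked designs are roughly ten times
#' smaller than an equally wide dense network.
#'
#' @param config a [network_config()].
#' @param mask optional binary genes x nodes matrix.
#' @return integer count.
#' @export
count_effective_parameters <- function(config, mask = NULL) {
  stopifnot(inherits(config, "network_config"))
  n_in <- length(config$input_genes)
  n_bio <- if (is.null(mask)) 0L else ncol(mask)
  w1 <- config$dense_nodes + n_bio
  if (w1 < 1L) stop("first hidden layer is empty")
  first <- n_in * config$dense_nodes +
    (if (is.null(mask)) 0 else sum(mask != 0)) + w1
  widths <- c(w1, config$hidden, config$n_classes)
  rest <- sum(widths[-length(widths)] * widths[-1L] + widths[-1L])
  as.integer(first + rest)
}
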