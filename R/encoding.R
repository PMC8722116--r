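#' Extract the learned encoding of cells
#'
#' The encoding is the activation of the last hidden layer, obtained by
#' detaching the output layer at inference time. It is a low-dimensional,
#' model-derived representation used downstream for clustering, retrieval and
#' 2-D visualisation.
#'
#' @param model a trained `pathnn_model`.
#' @param X preprocessed cells x genes matrix in (or reorderable to) model
#'   input order.
#' @return cells x H numeric matrix (H = last hidden layer width) with cell
#'   ids as rownames and hidden node names as colnames.
#' @export
encode <- function(model, X) {
  if (!model$trained) stop("model is not trained")
  X <- align_genes(model, X)
  fp <- forward_pass(model, X, keep = TRUE)
  enc <- fp$hidden[[length(fp$hidden)]]
  rownames(enc) <- rownames(X)
  if (length(fp$hidden) == 1L) colnames(enc) <- model$node_names
  enc
}

#' Pathway activities of the first hidden layer
#'
#' Stops the forward computation at the first hidden layer and returns the
#' activations of the biological nodes only (dense nodes of a hybrid first
#' layer are excluded). Each column is one gene set / pathway.
#'
#' @inheritParams encode
#' @return cells x n_pathways matrix with pathway names as colnames.
#' @export
pathway_activities <- function(model, X) {
  if (!model$trained) stop("model is not trained")
  if (length(model$bio_cols) == 0L) {
    stop("model has no biological nodes (purely dense first layer)")
  }
  X <- align_genes(model, X)
  fp <- forward_pass(model, X, keep = TRUE)
  act <- fp$hidden[[1L]][, model$bio_cols, drop = FALSE]
  rownames(act) <- rownames(X)
  colnames(act) <- model$node_names[model$bio_cols]
  act
}

#' Mean pathway activity per cell group
#'
#' @param activities matrix from [pathway_activities()].
#' @param labels grouping vector aligned to rows (e.g. cell types).
#' @return groups x pathways matrix of mean activities.
#' @export
summarize_activities <- function(activities, labels) {
  stopifnot(length(labels) == nrow(activities))
  grp <- sort(unique(as.character(labels)))
  out <- t(vapply(grp,
                  function(g) colMeans(activities[labels == g, , drop = FALSE]),
                  numeric(ncol(activities))))
  rownames(out) <- grp
  out
}

#' Top-weighted biological nodes per cell type
#'
#' For each output class, hidden biological nodes are ranked by the magnitude
#' of the weight connecting them to that class's output node (set
#' `use_abs = FALSE` for signed descending order). Magnitude is the default
#' because with an odd hidden activation and sign-symmetric initialisation,
#' jointly flipping a hidden node's incoming and outgoing weights leaves the
#' network unchanged — the sign of an output weight is arbitrary, only its
#' size is meaningful. For 2-hidden-layer designs the
#' default `"path"` strategy scores first-layer node j for class c by the
#' summed product-path magnitude `sum_h |W2[j,h] * W3[h,c]|`; the literal
#' `"output"` strategy ranks last-hidden-layer nodes by the output weights
#' instead.
#'
#' @param model a trained `pathnn_model` with biological nodes.
#' @param n how many nodes per class (clamped to the node count with a
#'   warning).
#' @param strategy `"auto"` (output weights for 1-hidden-layer models, path
#'   products otherwise), `"output"`, or `"path"`.
#' @param use_abs rank by absolute weight (default) instead of signed weight
#'   (ignored by `"path"`, which is magnitude-based by construction).
#' @return named list (one element per class) of data.frames with columns
#'   `node` and `weight`, weights non-increasing.
#' @export
top_nodes_per_class <- function(model, n = 10L,
                                strategy = c("auto", "output", "path"),
                                use_abs = TRUE) {
  if (!model$trained) stop("model is not trained")
  strategy <- match.arg(strategy)
  L <- length(model$weights)
  if (strategy == "auto") strategy <- if (L == 2L) "output" else "path"
  if (strategy == "output") {
    # rank last-hidden nodes by the weight into each output node
    scores <- model$weights[[L]]
    node_names <- if (L == 2L) model$node_names else
      paste0("h", L - 1L, "_", seq_len(nrow(scores)))
    keep <- if (L == 2L && length(model$bio_cols) > 0L) model$bio_cols
            else seq_len(nrow(scores))
  } else {
    if (L < 3L) stop("path strategy needs at least 2 hidden layers")
    if (length(model$bio_cols) == 0L) stop("model has no biological nodes")
    # |W2| %*% ... %*% |Wout|, summed over intermediate nodes
    scores <- abs(model$weights[[2L]])
    if (L > 3L) for (i in 3L:(L - 1L)) scores <- scores %*% abs(model$weights[[i]])
    scores <- scores %*% abs(model$weights[[L]])
    node_names <- model$node_names
    keep <- model$bio_cols
  }
  scores <- scores[keep, , drop = FALSE]
  node_names <- node_names[keep]
  if (n > nrow(scores)) {
    warning("n = ", n, " exceeds node count ", nrow(scores), "; clamped")
    n <- nrow(scores)
  }
  rank_by <- if (use_abs && strategy == "output") abs(scores) else scores
  out <- lapply(seq_len(ncol(scores)), function(c) {
    ord <- order(rank_by[, c], decreasing = TRUE)[seq_len(n)]
    data.frame(node = node_names[ord], weight = scores[ord, c],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- model$class_order
  out
}

#' 2-D embedding of an encoding
#'
#' Projects an encoding to two dimensions for visualisation, with either PCA
#' (deterministic) or an exact t-SNE (seeded; perplexity calibrated per cell by
#' bisection, early exaggeration, momentum gradient descent).
#'
#' @param enc cells x H encoding matrix.
#' @param method `"pca"` or `"tsne"`.
#' @param seed integer seed (t-SNE initialisation).
#' @param perplexity t-SNE perplexity, clamped to `(cells - 1) / 3`.
#' @param max_iter t-SNE iterations.
#' @return cells x 2 coordinate matrix (rownames preserved).
#' @export
embed_2d <- function(enc, method = c("pca", "tsne"), seed = 1L,
                     perplexity = 30, max_iter = 1000L) {
  method <- match.arg(method)
  if (nrow(enc) < 3L) stop("need at least 3 cells to embed")
  coords <- if (method == "pca") {
    pc <- stats::prcomp(enc, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    out <- matrix(0, nrow(enc), 2L)
    out[, seq_len(k)] <- pc$x[, seq_len(k)]
    out
  } else {
    tsne_exact(enc, perplexity = perplexity, max_iter = max_iter, seed = seed)
  }
  dimnames(coords) <- list(rownames(enc), c("dim1", "dim2"))
  coords
}

# Exact t-SNE (dense pairwise affinities; suitable for the few thousand cells
# an encoding holds). Perplexity is calibrated per point by bisection on the
# Gaussian bandwidth; optimisation uses early exaggeration (x4 for the first
# 100 iterations) and momentum 0.5 -> 0.8 after iteration 250.
tsne_exact <- function(X, perplexity = 30, max_iter = 1000L, seed = 1L) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  if (perplexity < 1) perplexity <- 1
  D2 <- as.matrix(stats::dist(X))^2

  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in seq_len(50L)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; pr <- w } else {
        pr <- w / sw
        H <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- pr
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
  inc <- matrix(0, n, 2L)
  momentum <- 0.5; eta <- 200
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100L) P * 4 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    G <- 4 * ((Pe - Q) * num)
    grad <- (diag(rowSums(G)) - G) %*% Y
    if (iter == 250L) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y), "-")
  }
  Y
}
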