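#' Supervised classification metrics
#'
#' Accuracy, balanced accuracy (mean per-class recall over classes present in
#' the truth), and precision / recall / F1 under macro, micro and weighted
#' averaging. Classes are the sorted union of true and predicted labels;
#' zero-division cases (e.g. a class never predicted) contribute 0.
#' For single-label classification micro precision = micro recall = micro F1
#' = accuracy.
#'
#' @param y_true,y_pred aligned label vectors.
#' @param per_class also return the per-class table.
#' @return named list of metrics (and `per_class` data.frame if requested).
#' @export
supervised_metrics <- function(y_true, y_pred, per_class = FALSE) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  classes <- sort(unique(c(y_true, y_pred)))
  tp <- fp <- fn <- numeric(length(classes))
  for (i in seq_along(classes)) {
    c0 <- classes[i]
    tp[i] <- sum(y_true == c0 & y_pred == c0)
    fp[i] <- sum(y_true != c0 & y_pred == c0)
    fn[i] <- sum(y_true == c0 & y_pred != c0)
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  support <- tp + fn

  present <- support > 0
  accuracy <- mean(y_true == y_pred)
  balanced_accuracy <- mean(rec[present])
  micro <- safe_div(sum(tp), sum(tp) + sum(fp))  # == accuracy single-label
  wts <- support / sum(support)
  out <- list(
    accuracy = accuracy,
    balanced_accuracy = balanced_accuracy,
    precision_macro = mean(prec), precision_micro = micro,
    precision_weighted = sum(wts * prec),
    recall_macro = mean(rec), recall_micro = micro,
    recall_weighted = sum(wts * rec),
    f1_macro = mean(f1), f1_micro = micro,
    f1_weighted = sum(wts * f1))
  if (per_class) {
    out$per_class <- data.frame(class = classes, support = support,
                                precision = prec, recall = rec, f1 = f1,
                                stringsAsFactors = FALSE)
  }
  out
}

#' K-Means clustering of an encoding
#'
#' Best of `n_init` seeded restarts by within-cluster sum of squares,
#' deterministic under `seed`.
#'
#' @param enc cells x H encoding matrix.
#' @param K number of clusters (`K <= cells`).
#' @param seed integer seed.
#' @param n_init number of random restarts.
#' @return integer cluster labels in `1..K`.
#' @export
kmeans_cluster <- function(enc, K, seed = 1L, n_init = 10L) {
  n <- nrow(enc)
  if (K > n) stop("K = ", K, " exceeds the number of cells (", n, ")")
  if (K == n) return(seq_len(n))
  set.seed(seed)
  km <- stats::kmeans(enc, centers = K, nstart = n_init, iter.max = 100L)
  as.integer(km$cluster)
}

# Contingency table helpers (shared by the clustering indices).
cluster_contingency <- function(y_true, clusters) {
  table(factor(y_true), factor(clusters))
}

entropy_nat <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# Expected mutual information under the permutation (hypergeometric) model,
# computed from lgamma terms.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
          lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
          lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
          lgamma(n - ai - bj + nij + 1)
        emi <- emi + (nij / n) * log(n * nij / (ai * bj)) * exp(lp)
      }
    }
  }
  emi
}

#' External clustering indices
#'
#' Compares a clustering against ground-truth classes with the six standard
#' indices — homogeneity, completeness, V-measure, adjusted Rand index (ARI),
#' adjusted mutual information (AMI, arithmetic-mean normalisation) and
#' Fowlkes-Mallows — plus their arithmetic mean. Entropy-based scores use the
#' natural logarithm. All six are invariant to label renaming.
#'
#' @param y_true ground-truth class labels.
#' @param clusters cluster assignments, aligned to `y_true`.
#' @return named list: `homogeneity`, `completeness`, `v_measure`, `ari`,
#'   `ami`, `fowlkes_mallows`, `average`.
#' @export
clustering_metrics <- function(y_true, clusters) {
  if (length(y_true) != length(clusters)) stop("inputs not aligned")
  n <- length(y_true)
  if (n < 2L) stop("need at least 2 samples")
  ct <- cluster_contingency(y_true, clusters)
  a <- rowSums(ct); b <- colSums(ct)
  hC <- entropy_nat(a); hK <- entropy_nat(b)
  nz <- ct[ct > 0]
  ij <- which(ct > 0, arr.ind = TRUE)
  mi <- sum((nz / n) * (log(nz * n) - log(a[ij[, 1L]] * b[ij[, 2L]])))
  mi <- max(mi, 0)

  homogeneity <- if (hC == 0) 1 else mi / hC
  completeness <- if (hK == 0) 1 else mi / hK
  v_measure <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)

  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(as.numeric(ct)))
  sum_a <- sum(comb2(a)); sum_b <- sum(comb2(b))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else (sum_ij - expected) / (max_idx - expected)

  emi <- expected_mi(a, b, n)
  denom <- (hC + hK) / 2 - emi
  ami <- if (hC == 0 && hK == 0) 1
         else if (abs(denom) < .Machine$double.eps) 1
         else (mi - emi) / denom

  fm_den <- sqrt(sum_a * sum_b)
  fowlkes_mallows <- if (fm_den == 0) 0 else sum_ij / fm_den

  scores <- c(homogeneity = homogeneity, completeness = completeness,
              v_measure = v_measure, ari = ari, ami = ami,
              fowlkes_mallows = fowlkes_mallows)
  c(as.list(scores), list(average = mean(scores)))
}

#' Average precision of a ranked neighbour list
#'
#' `AP = (1/R) * sum_{i<=k} precision@i * rel(i)` where `rel(i)` marks
#' neighbours of the query's class and `R` is the number of relevant
#' neighbours among the top `k` (0 relevant gives AP 0). Set `total_relevant`
#' to normalise by the total number of relevant items in the reference
#' instead.
#'
#' @param query_class the query cell's class.
#' @param ranked_neighbor_classes classes of the neighbours, best first.
#' @param k truncation depth.
#' @param total_relevant optional alternative normaliser.
#' @return a value in `[0, 1]`.
#' @export
average_precision <- function(query_class, ranked_neighbor_classes,
                              k = length(ranked_neighbor_classes),
                              total_relevant = NULL) {
  rel <- as.integer(utils::head(ranked_neighbor_classes, k) == query_class)
  if (length(rel) == 0L) return(0)
  R <- if (is.null(total_relevant)) sum(rel) else total_relevant
  if (R == 0) return(0)
  prec_at <- cumsum(rel) / seq_along(rel)
  sum(prec_at * rel) / R
}

#' Retrieval configuration
#'
#' @param k neighbours per query (default 100, clamped to the reference size
#'   with a warning at evaluation time).
#' @param exclude_self drop a reference neighbour with the same id as the
#'   query (for self-retrieval runs where the sets overlap).
#' @return an object of class `retrieval_config`.
#' @export
retrieval_config <- function(k = 100L, exclude_self = FALSE) {
  stopifnot(k >= 1L)
  structure(list(k = as.integer(k), exclude_self = exclude_self,
                 distance = "euclidean"),
            class = "retrieval_config")
}

#' Nearest-neighbour retrieval scored by mean average precision
#'
#' For every query cell the `k` euclidean nearest reference encodings are
#' found (distance ties broken by ascending reference index) and the average
#' precision of same-class matches is computed; APs are averaged per query
#' class and the overall `mean` is the unweighted mean over classes. Query
#' classes absent from the reference score 0 by definition.
#'
#' @param ref_enc,query_enc encodings from the same model (same width).
#' @param ref_labels,query_labels class labels aligned to the encodings.
#' @param cfg a [retrieval_config()].
#' @return list with `per_class` (data.frame class / n_queries / map) and
#'   `mean`.
#' @export
retrieval_map <- function(ref_enc, ref_labels, query_enc, query_labels,
                          cfg = retrieval_config()) {
  if (ncol(ref_enc) != ncol(query_enc)) stop("encoding dimensions differ")
  if (nrow(ref_enc) != length(ref_labels)) stop("reference labels not aligned")
  if (nrow(query_enc) != length(query_labels)) stop("query labels not aligned")
  ref_labels <- as.character(ref_labels)
  query_labels <- as.character(query_labels)
  k <- cfg$k
  if (k > nrow(ref_enc)) {
    warning("k = ", k, " exceeds reference size ", nrow(ref_enc), "; clamped")
    k <- nrow(ref_enc)
  }
  # squared euclidean distances query x reference
  d2 <- outer(rowSums(query_enc^2), rowSums(ref_enc^2), "+") -
    2 * tcrossprod(query_enc, ref_enc)
  ap <- numeric(nrow(query_enc))
  for (q in seq_len(nrow(query_enc))) {
    ord <- order(d2[q, ])  # stable: ties keep ascending reference index
    if (cfg$exclude_self && !is.null(rownames(query_enc)) &&
        !is.null(rownames(ref_enc))) {
      ord <- ord[rownames(ref_enc)[ord] != rownames(query_enc)[q]]
    }
    ap[q] <- average_precision(query_labels[q],
                               ref_labels[ord[seq_len(min(k, length(ord)))]],
                               k = k)
  }
  classes <- sort(unique(query_labels))
  per_class <- data.frame(
    class = classes,
    n_queries = vapply(classes, function(c0) sum(query_labels == c0), integer(1L)),
    map = vapply(classes, function(c0) mean(ap[query_labels == c0]), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_class = per_class, mean = mean(per_class$map))
}
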