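# Independent textbook-formula oracles, deliberately written from the
# definitions (pair counting, direct entropy sums, dhyper tails) and not
# sharing code with the package implementations they check.

oracle_softmax <- function(x) exp(x) / sum(exp(x))

oracle_supervised <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  per <- lapply(classes, function(c0) {
    tp <- sum(y_pred == c0 & y_true == c0)
    predicted <- sum(y_pred == c0)
    actual <- sum(y_true == c0)
    p <- if (predicted > 0) tp / predicted else 0
    r <- if (actual > 0) tp / actual else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(tp = tp, predicted = predicted, actual = actual, p = p, r = r, f = f)
  })
  per <- do.call(rbind, per)
  acc <- sum(per[, "tp"]) / length(y_true)
  w <- per[, "actual"] / sum(per[, "actual"])
  list(accuracy = acc,
       balanced_accuracy = mean(per[per[, "actual"] > 0, "r"]),
       precision_macro = mean(per[, "p"]), recall_macro = mean(per[, "r"]),
       f1_macro = mean(per[, "f"]),
       precision_weighted = sum(w * per[, "p"]),
       recall_weighted = sum(w * per[, "r"]),
       f1_weighted = sum(w * per[, "f"]),
       micro = acc)
}

# All-pairs clustering agreement counts (O(n^2) enumeration).
oracle_pair_counts <- function(y_true, clusters) {
  n <- length(y_true)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- y_true[i] == y_true[j]
      same_c <- clusters[i] == clusters[j]
      if (same_t && same_c) ss <- ss + 1
      else if (same_t && !same_c) sd <- sd + 1
      else if (!same_t && same_c) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  c(ss = ss, sd = sd, ds = ds, dd = dd)
}

oracle_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  -sum(ifelse(p > 0, p * log(p), 0))
}

oracle_mutual_information <- function(y_true, clusters) {
  n <- length(y_true)
  mi <- 0
  for (u in unique(y_true)) {
    for (v in unique(clusters)) {
      nij <- sum(y_true == u & clusters == v)
      if (nij == 0) next
      mi <- mi + (nij / n) *
        log((nij / n) / ((sum(y_true == u) / n) * (sum(clusters == v) / n)))
    }
  }
  mi
}

# Expected MI under the permutation model, via dhyper probabilities.
oracle_expected_mi <- function(y_true, clusters) {
  n <- length(y_true)
  a <- as.numeric(table(y_true)); b <- as.numeric(table(clusters))
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      for (nij in max(1, ai + bj - n):min(ai, bj)) {
        if (nij < max(1, ai + bj - n)) next
        pr <- dhyper(nij, ai, n - ai, bj)
        emi <- emi + pr * (nij / n) * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

oracle_clustering <- function(y_true, clusters) {
  pc <- oracle_pair_counts(y_true, clusters)
  hC <- oracle_entropy(y_true); hK <- oracle_entropy(clusters)
  mi <- oracle_mutual_information(y_true, clusters)
  hom <- if (hC == 0) 1 else mi / hC
  com <- if (hK == 0) 1 else mi / hK
  v <- if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
  ss <- pc[["ss"]]; sd_ <- pc[["sd"]]; ds <- pc[["ds"]]; dd <- pc[["dd"]]
  npairs <- ss + sd_ + ds + dd
  # ARI from pair counts (Hubert & Arabie)
  sum_ij <- ss
  sum_a <- ss + sd_; sum_b <- ss + ds
  expected <- sum_a * sum_b / npairs
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else (sum_ij - expected) / (max_idx - expected)
  fm <- if (sum_a == 0 || sum_b == 0) 0 else ss / sqrt(sum_a * sum_b)
  emi <- oracle_expected_mi(y_true, clusters)
  denom <- (hC + hK) / 2 - emi
  ami <- if (hC == 0 && hK == 0) 1 else if (abs(denom) < 1e-15) 1 else
    (mi - emi) / denom
  list(homogeneity = hom, completeness = com, v_measure = v, ari = ari,
       ami = ami, fowlkes_mallows = fm)
}

oracle_average_precision <- function(query_class, neighbors, k) {
  neighbors <- neighbors[seq_len(min(k, length(neighbors)))]
  hits <- 0; total <- 0
  for (i in seq_along(neighbors)) {
    if (neighbors[i] == query_class) {
      hits <- hits + 1
      total <- total + hits / i
    }
  }
  if (hits == 0) 0 else total / hits
}

# Upper-tail hypergeometric by explicit enumeration with choose().
oracle_hyper_upper <- function(overlap, term_size, query_size, universe_size) {
  ks <- overlap:min(term_size, query_size)
  sum(choose(term_size, ks) *
        choose(universe_size - term_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# BH step-up by hand: sorted p * m / rank, running minimum from the largest p.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}
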