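#' Hypergeometric term enrichment with BH correction
#'
#' For each annotation term, the one-sided upper-tail hypergeometric
#' probability `P(X >= overlap)` of drawing the observed overlap between the
#' query gene list and the term, given the universe, is computed (`X ~
#' Hypergeom(N = |universe|, K = |term|, n = |query|)`). P-values are adjusted
#' across all tested terms with the Benjamini-Hochberg step-up procedure;
#' terms with zero overlap are kept (p = 1) so the adjustment's m equals the
#' number of tested terms. Query genes outside the universe are dropped with
#' a warning. The universe should normally be the model's input gene space —
#' the genes the network could possibly have used.
#'
#' @param query character vector of genes of interest.
#' @param annotation a [gene_set_collection()] of terms.
#' @param universe character vector of background genes.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return data.frame sorted by q then p with columns `term`, `description`,
#'   `overlap`, `query_size`, `term_size`, `universe_size`, `p`, `q`,
#'   `significant`.
#' @export
hypergeometric_enrichment <- function(query, annotation, universe,
                                      alpha = 0.05) {
  stopifnot(inherits(annotation, "gene_set_collection"))
  universe <- unique(trimws(as.character(universe)))
  if (length(universe) < 2L) stop("universe must contain at least 2 genes")
  query <- unique(trimws(as.character(query)))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("empty query after universe filtering")
  N <- length(universe); n <- length(query)
  terms <- names(annotation$sets)
  rows <- lapply(terms, function(t) {
    members <- intersect(annotation$sets[[t]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, description = annotation$descriptions[[t]],
               overlap = k, query_size = n, term_size = K, universe_size = N,
               p = p, row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q <= alpha
  res[order(res$q, res$p, res$term), , drop = FALSE]
}

#' Genes covered by the top-ranked nodes of one cell type
#'
#' Union of the member genes of the ranked gene sets; with
#' `mask_aware = TRUE` the union is restricted to the model's input genes
#' (the genes the mask actually wired into the network).
#'
#' @param ranking one element of [top_nodes_per_class()] output (data.frame
#'   with a `node` column), or a character vector of node names.
#' @param collection the [gene_set_collection()] the nodes came from.
#' @param input_genes model input genes, required when `mask_aware`.
#' @param mask_aware restrict to `input_genes`.
#' @return character vector of genes.
#' @export
genes_from_top_nodes <- function(ranking, collection, input_genes = NULL,
                                 mask_aware = FALSE) {
  nodes <- if (is.data.frame(ranking)) ranking$node else as.character(ranking)
  unknown <- setdiff(nodes, names(collection$sets))
  if (length(unknown) > 0L) {
    stop("unknown node name(s): ", paste(unknown, collapse = ", "))
  }
  genes <- unique(unlist(collection$sets[nodes], use.names = FALSE))
  if (mask_aware) {
    if (is.null(input_genes)) stop("mask_aware = TRUE requires input_genes")
    genes <- genes[genes %in% input_genes]
  }
  genes
}
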