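#' Gene-set collections
#'
#' A gene-set collection holds named groups of genes ("pathways" in the KEGG
#' sense, but any functional grouping — PPI clusters, regulons — is accepted).
#' Each set becomes one node of the first hidden layer of a pathway-primed
#' network.
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled to the number of sets.
#' @return an object of class `gene_set_collection` with elements `sets`
#'   (named list, member duplicates collapsed, order preserved) and
#'   `descriptions`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L) stop("collection must contain at least one gene set")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("every gene set must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- trimws(as.character(g))
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s): ", paste(nm[lengths(sets) == 0L], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- nm
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets,",
      length(unique(unlist(x$sets, use.names = FALSE))), "distinct genes\n")
  shown <- utils::head(names(x$sets), 5L)
  for (s in shown) cat("  ", s, " (", length(x$sets[[s]]), " genes)\n", sep = "")
  if (length(x$sets) > 5L) cat("  ...\n")
  invisible(x)
}

#' Read a GMT file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line, fields
#' are name, description, then member genes.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], " (needs >= 3 tab-separated fields): ",
         substr(lines[bad[1L]], 1L, 60L))
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' Reads a cells x genes expression matrix from either a dense delimited file
#' (header row = gene identifiers, first column = cell identifiers; tab- or
#' comma-separated by file extension) or a MatrixMarket coordinate triplet with
#' one-identifier-per-line gene and cell sidecar files. Triplet indices are
#' 1-based per the MatrixMarket standard.
#'
#' @param path path to the matrix file.
#' @param format `"dense"` or `"mtx"`.
#' @param genes_file,cells_file sidecar identifier lists, required for
#'   `format = "mtx"`.
#' @param transpose set `TRUE` when the source is stored genes x cells.
#' @param na_as_zero replace missing values with 0 instead of failing.
#' @return numeric matrix, cells in rows (rownames = cell ids), genes in
#'   columns (colnames = gene ids).
#' @export
read_expression <- function(path, format = c("dense", "mtx"),
                            genes_file = NULL, cells_file = NULL,
                            transpose = FALSE, na_as_zero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "dense") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    cn <- names(df)[-1L]  # before subsetting: `[.data.frame` dedups names
    m <- as.matrix(df[-1L])
    storage.mode(m) <- "double"
    dimnames(m) <- list(ids, cn)
  } else {
    if (is.null(genes_file) || is.null(cells_file)) {
      stop("mtx format requires genes_file and cells_file sidecars")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- trimws(readLines(genes_file, warn = FALSE))
    cells <- trimws(readLines(cells_file, warn = FALSE))
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (!transpose) {
      if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
        stop("mtx dimensions (", nrow(m), " x ", ncol(m),
             ") do not match sidecars (", length(cells), " cells, ",
             length(genes), " genes)")
      }
      dimnames(m) <- list(cells, genes)
    } else {
      if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
        stop("mtx dimensions (", nrow(m), " x ", ncol(m),
             ") do not match sidecars (", length(genes), " genes, ",
             length(cells), " cells)")
      }
      dimnames(m) <- list(genes, cells)
    }
  }
  if (transpose) m <- t(m)
  colnames(m) <- trimws(colnames(m))
  rownames(m) <- trimws(rownames(m))
  if (anyDuplicated(colnames(m))) {
    stop("duplicate gene identifier(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate cell identifier(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyNA(m)) {
    if (na_as_zero) m[is.na(m)] <- 0 else
      stop("expression matrix contains missing values ",
           "(use na_as_zero = TRUE to impute as zero)")
  }
  m
}

#' Write an expression matrix as dense TSV
#'
#' @param expr cells x genes numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(cell_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cell-type labels
#'
#' Labels are stored as a two-column TSV (cell id, cell type) with a header.
#'
#' @param path path to the label file.
#' @return named character vector of labels (names = cell ids).
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file must have two columns (cell id, label)")
  labels <- as.character(df[[2L]])
  names(labels) <- trimws(as.character(df[[1L]]))
  labels
}

#' @rdname read_labels
#' @param labels named character vector (names = cell ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(cell_id = names(labels), cell_type = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect measured genes with a gene-set collection
#'
#' `biological_only` restricts the gene space to measured genes that belong to
#' at least one set (this is what shrinks the input layer of a pure pathway
#' network); `full` keeps all measured genes and only prunes unmeasured set
#' members. Sets left empty after pruning are dropped with a warning.
#'
#' @param expr cells x genes matrix.
#' @param collection a [gene_set_collection()].
#' @param mode `"biological_only"` or `"full"`.
#' @return list with elements `expression` and `collection`.
#' @export
intersect_gene_space <- function(expr, collection,
                                 mode = c("biological_only", "full")) {
  mode <- match.arg(mode)
  measured <- colnames(expr)
  pruned <- lapply(collection$sets, function(g) g[g %in% measured])
  keep <- lengths(pruned) > 0L
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " gene set(s) with no measured member: ",
            paste(utils::head(names(pruned)[!keep], 5L), collapse = ", "))
  }
  if (!any(keep)) stop("no gene set has any measured member gene")
  pruned <- pruned[keep]
  if (mode == "biological_only") {
    in_sets <- unique(unlist(pruned, use.names = FALSE))
    genes <- measured[measured %in% in_sets]
    if (length(genes) == 0L) stop("empty intersection of measured genes and gene sets")
    expr <- expr[, genes, drop = FALSE]
  }
  list(expression = expr,
       collection = gene_set_collection(pruned,
                                        collection$descriptions[names(pruned)]))
}

#' Build the binary prior mask
#'
#' The mask is the genes x nodes incidence matrix of the collection: entry
#' (i, j) is 1 iff gene i belongs to set j. A first-layer weight from gene i to
#' biological node j may be nonzero only where the mask is 1.
#'
#' @param gene_ids ordered gene identifiers (the model's input order).
#' @param collection a [gene_set_collection()]; every set must have at least
#'   one member among `gene_ids` (intersect first).
#' @return binary matrix with rownames `gene_ids` and colnames the set names.
#' @export
build_mask <- function(gene_ids, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (anyDuplicated(gene_ids)) stop("gene_ids contain duplicates")
  m <- vapply(collection$sets,
              function(g) as.numeric(gene_ids %in% g),
              numeric(length(gene_ids)))
  m <- matrix(m, nrow = length(gene_ids),
              dimnames = list(gene_ids, names(collection$sets)))
  covered <- colSums(m)
  if (any(covered == 0)) {
    stop("gene set(s) with zero covered genes: ",
         paste(colnames(m)[covered == 0], collapse = ", "),
         " (intersect_gene_space first)")
  }
  m
}

#' Preprocess an expression matrix
#'
#' Supported transforms: `log1p` (elementwise log(1 + x)), `zscore` (per-gene
#' standardisation; zero-variance genes map to 0), `minmax_sym` (per-gene
#' affine map of the training range onto \[-1, 1\], out-of-range test values
#' clipped), and `none`. For `zscore` and `minmax_sym` the statistics must be
#' fit on the training split and reused on test data via `stats`.
#'
#' @param expr cells x genes matrix.
#' @param method one of `"log1p"`, `"zscore"`, `"minmax_sym"`, `"none"`.
#' @param stats statistics returned by a previous call on training data; when
#'   `NULL` they are fit on `expr`.
#' @return list with elements `expression` (transformed matrix) and `stats`.
#' @export
preprocess_expression <- function(expr,
                                  method = c("zscore", "log1p", "minmax_sym", "none"),
                                  stats = NULL) {
  method <- match.arg(method)
  if (!is.null(stats) && !identical(stats$method, method)) {
    stop("supplied stats were fit with method '", stats$method, "'")
  }
  out <- switch(method,
    none = {
      stats <- list(method = "none")
      expr
    },
    log1p = {
      if (any(expr < 0)) stop("log1p requires non-negative input")
      stats <- list(method = "log1p")
      log1p(expr)
    },
    zscore = {
      if (is.null(stats)) {
        mu <- colMeans(expr)
        sdv <- apply(expr, 2L, stats::sd)
        stats <- list(method = "zscore", center = mu, scale = sdv)
      }
      scl <- ifelse(stats$scale > 0, 1 / stats$scale, 0)
      sweep(sweep(expr, 2L, stats$center, "-"), 2L, scl, "*")
    },
    minmax_sym = {
      if (is.null(stats)) {
        lo <- apply(expr, 2L, min)
        hi <- apply(expr, 2L, max)
        stats <- list(method = "minmax_sym", min = lo, max = hi)
      }
      rng <- stats$max - stats$min
      scl <- ifelse(rng > 0, 2 / rng, 0)
      z <- sweep(sweep(expr, 2L, stats$min, "-"), 2L, scl, "*") - 1
      z[z == -1 & rep(rng == 0, each = nrow(expr))] <- 0  # constant genes -> 0
      pmin(pmax(z, -1), 1)
    })
  list(expression = out, stats = stats)
}
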