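#' Save / load a trained model
#'
#' Serialises the whole model — architecture, weights, biases, mask, class
#' order and fitted preprocessing statistics — to a single JSON file (full
#' double precision). A round trip reproduces predictions to numerical
#' precision.
#'
#' @param model a `pathnn_model`.
#' @param path output path (conventionally `model.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pathnn_model"))
  obj <- list(
    package = "pathnn",
    config = unclass(model$config),
    weights = lapply(model$weights, function(w) unname(as.matrix(w))),
    biases = model$biases,
    mask = if (is.null(model$mask)) NULL else unname(model$mask),
    bio_cols = model$bio_cols,
    node_names = model$node_names,
    class_order = model$class_order,
    preprocess_stats = model$preprocess_stats,
    trained = model$trained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$package, "pathnn")) stop("not a pathnn model file: ", path)
  cfg <- network_config(obj$config$input_genes, obj$config$n_classes,
                        activation = obj$config$activation,
                        dense_nodes = obj$config$dense_nodes,
                        hidden = as.integer(obj$config$hidden %||% integer()),
                        seed = obj$config$seed)
  weights <- lapply(obj$weights, function(w) matrix(w, nrow = nrow(w)))
  weights[[1L]] <- matrix(obj$weights[[1L]], nrow = length(cfg$input_genes),
                          dimnames = list(cfg$input_genes, obj$node_names))
  biases <- lapply(obj$biases, as.numeric)
  mask <- if (is.null(obj$mask)) NULL else
    matrix(obj$mask, nrow = length(cfg$input_genes))
  stats <- obj$preprocess_stats
  if (!is.null(stats)) stats <- lapply(stats, function(x)
    if (is.list(x)) unlist(x) else x)
  structure(list(weights = weights, biases = biases, mask = mask,
                 bio_cols = as.integer(obj$bio_cols),
                 node_names = as.character(obj$node_names),
                 config = cfg, class_order = obj$class_order,
                 preprocess_stats = stats, history = NULL,
                 trained = isTRUE(obj$trained)),
            class = "pathnn_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
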