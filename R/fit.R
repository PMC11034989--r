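# User-facing model fit: gpgcn() returns a classed object with the usual
# print/summary/coef/predict/plot methods.

# Encode sequences into graphs under a config. With window = 0 each sequence
# is one graph; with window = w each sequence is cut into non-overlapping
# length-w windows (a sequence shorter than w stays whole). `record` maps
# each graph back to its source record.
.encode_dataset <- function(sequences, config) {
  graphs <- list()
  record <- integer(0)
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (config$window > 0 && nchar(s) > config$window) {
      nw <- nchar(s) %/% config$window   # trailing partial window dropped
      pieces <- substring(s, (seq_len(nw) - 1L) * config$window + 1L,
                          seq_len(nw) * config$window)
    } else {
      pieces <- s
    }
    for (p in pieces) {
      graphs[[length(graphs) + 1L]] <-
        build_gpg(p, k = config$k, d = config$d, binning = config$binning)
      record <- c(record, i)
    }
  }
  list(graphs = graphs, record = record)
}

# Average window-level probabilities back to record level.
.pool_records <- function(mat, record, n) {
  out <- matrix(0, n, ncol(mat))
  cnt <- tabulate(record, nbins = n)
  for (j in seq_len(ncol(mat)))
    out[, j] <- as.vector(rowsum(mat[, j], record, reorder = TRUE)) / cnt
  out
}

#' Fit a gapped-pattern graph convolutional classifier
#'
#' Encodes every sequence of a labeled dataset as a gapped pattern graph,
#' then trains the graph-convolution network (or the no-GCN ablation) by
#' mini-batch Adam on the softmax cross-entropy, drawing batches with
#' inverse-class-frequency weights so imbalanced classes are seen equally
#' often. The weights with the best validation loss are kept.
#'
#' @param dataset A [gpg_dataset()]; if it has no split assignment yet it is
#'   split 80/10/10 (stratified) with the training seed.
#' @param config A [gpgcn_config()]; `n_classes` and `aux_dim` must match
#'   the dataset.
#' @param training A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return Object of class `gpgcn`: the best weights (`params`), the
#'   per-epoch `history`, record-level `fitted_prob`, and the data split.
#' @seealso [predict.gpgcn()], [grid_search()], [score_motifs()]
#' @export
gpgcn <- function(dataset, config = gpgcn_config(),
                  training = train_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "gpg_dataset"),
            inherits(config, "gpgcn_config"),
            inherits(training, "gpg_train_config"))
  if (all(is.na(dataset$split)))
    dataset <- split_dataset(dataset, seed = training$seed)
  if (length(dataset$classes) != config$n_classes)
    stop("dataset has ", length(dataset$classes), " classes but config says ",
         config$n_classes, call. = FALSE)
  aux_dim <- if (is.null(dataset$aux)) 0L else ncol(dataset$aux)
  if (aux_dim != config$aux_dim)
    stop("dataset aux dimension (", aux_dim, ") does not match config (",
         config$aux_dim, ")", call. = FALSE)
  if (!any(dataset$split == "train") || !any(dataset$split == "val"))
    stop("dataset needs non-empty train and val splits", call. = FALSE)

  enc <- .encode_dataset(dataset$sequences, config)
  glabels <- dataset$labels[enc$record]
  gaux <- .aux_rows(dataset$aux, enc$record)
  gsplit <- dataset$split[enc$record]
  topo <- build_topology(config$k)
  params <- init_weights(config)
  res <- .train_loop(params, enc$graphs, gaux, glabels,
                     which(gsplit == "train"), which(gsplit == "val"),
                     config, training, topo, verbose = verbose)
  gp <- .predict_probs(enc$graphs, gaux, res$params, config, topo)
  fitted_prob <- .pool_records(gp, enc$record, length(dataset$sequences))
  colnames(fitted_prob) <- dataset$classes
  structure(list(config = config, training = training,
                 params = res$params, history = res$history,
                 best_epoch = res$best_epoch,
                 classes = dataset$classes, labels = dataset$labels,
                 ids = dataset$ids, dataset_split = dataset$split,
                 fitted_prob = fitted_prob,
                 call = match.call()),
            class = "gpgcn")
}

#' @export
print.gpgcn <- function(x, ...) {
  cat("Fitted gapped-pattern GCN (", x$config$architecture, ")\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  k =", x$config$k, ", d =", x$config$d,
      ", layers =", x$config$layers, "\n")
  if (nrow(x$history) > 0)
    cat("  trained", max(x$history$epoch), "epochs; best epoch",
        x$best_epoch, sprintf("(val loss %.4f)",
                              min(x$history$val_loss)), "\n")
  invisible(x)
}

#' @export
summary.gpgcn <- function(object, ...) {
  print(object)
  pred <- max.col(object$fitted_prob) - 1L
  for (sp in c("train", "val", "test")) {
    idx <- which(object$dataset_split == sp)
    if (length(idx) == 0) next
    acc <- mean(pred[idx] == object$labels[idx])
    cat(sprintf("  %-5s accuracy: %.3f  (n = %d)\n", sp, acc, length(idx)))
  }
  invisible(object)
}

#' @export
coef.gpgcn <- function(object, ...) object$params

#' Plot training history
#'
#' Training and validation loss per epoch, with the best-validation epoch
#' marked.
#'
#' @param x A fitted `gpgcn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gpgcn <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict from a fitted gapped-pattern GCN
#'
#' @param object A fitted `gpgcn`.
#' @param newdata Character vector of DNA sequences, a [gpg_dataset()], or a
#'   list of prebuilt `gpg` graphs (which must match the model's `k`/`d`).
#' @param aux Auxiliary feature matrix (required if the model was trained
#'   with auxiliary features and `newdata` is not a dataset carrying them).
#' @param type `"prob"` for class probabilities, `"class"` for labels,
#'   `"embedding"` for the pre-MLP embedding vectors.
#' @param ... Unused.
#' @return Matrix of probabilities or embeddings, or a character vector of
#'   class labels; one row/element per input record.
#' @export
predict.gpgcn <- function(object, newdata, aux = NULL,
                          type = c("prob", "class", "embedding"), ...) {
  type <- match.arg(type)
  config <- object$config
  if (inherits(newdata, "gpg_dataset")) {
    aux <- aux %||% newdata$aux
    newdata <- newdata$sequences
  }
  if (is.list(newdata) && all(vapply(newdata, inherits, logical(1), "gpg"))) {
    graphs <- newdata
    record <- seq_along(graphs)
  } else {
    enc <- .encode_dataset(as.character(newdata), config)
    graphs <- enc$graphs
    record <- enc$record
  }
  n <- max(record)
  topo <- build_topology(config$k)
  if (type == "embedding") {
    if (config$architecture != "gpgcn")
      stop("the ablation model has no embedding stage", call. = FALSE)
    em <- t(vapply(graphs, gcn_embed, numeric(config$embed_dim),
                   params = object$params, config = config,
                   topology = topo))
    return(.pool_records(em, record, n))
  }
  gaux <- .aux_rows(aux, record)
  probs <- .predict_probs(graphs, gaux, object$params, config, topo)
  probs <- .pool_records(probs, record, n)
  colnames(probs) <- object$classes
  if (type == "class") object$classes[max.col(probs)] else probs
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the full fitted object — configuration, weights,
#' seed and training history — and round-trips bit-exactly.
#'
#' @param object A fitted `gpgcn`.
#' @param path File path.
#' @return `save_gpgcn` returns `path` invisibly; `load_gpgcn` returns the
#'   restored `gpgcn` object.
#' @export
save_gpgcn <- function(object, path) {
  stopifnot(inherits(object, "gpgcn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_gpgcn
#' @export
load_gpgcn <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "gpgcn")) stop("not a gpgcn checkpoint", call. = FALSE)
  obj
}

#' Export sequence embeddings to TSV
#'
#' One row per record (id + embedding coordinates), suitable for external
#' projection tools such as UMAP.
#'
#' @param object Fitted `gpgcn`.
#' @param newdata Sequences or dataset to embed.
#' @param path Output TSV path.
#' @param ids Row identifiers; defaults to dataset ids or `seq_<i>`.
#' @return The embedding matrix, invisibly.
#' @export
export_embeddings <- function(object, newdata, path, ids = NULL) {
  if (inherits(newdata, "gpg_dataset") && is.null(ids)) ids <- newdata$ids
  em <- predict(object, newdata, type = "embedding")
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(em)))
  df <- data.frame(id = ids, em)
  names(df) <- c("id", paste0("e", seq_len(ncol(em))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(em)
}
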