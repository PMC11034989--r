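# Dataset containers, class-imbalance-aware sampling, cross-entropy with
# Adam, early stopping, and hyperparameter grid search.

#' Labeled sequence dataset
#'
#' Bundles sequences, integer class labels, optional per-record auxiliary
#' feature vectors and (after [split_dataset()]) a train/val/test assignment.
#'
#' @param sequences Character vector of DNA sequences.
#' @param labels Class labels: factor, character, or integers in `[0, K)`.
#' @param aux Optional numeric matrix, one row per record.
#' @param ids Record identifiers; default names of `sequences` or `seq_1...`.
#' @return Object of class `gpg_dataset` with fields `ids`, `sequences`,
#'   `labels` (0-based integer), `classes`, `aux`, `split`.
#' @export
gpg_dataset <- function(sequences, labels, aux = NULL, ids = NULL) {
  n <- length(sequences)
  if (length(labels) != n)
    stop("one label per sequence required", call. = FALSE)
  if (is.null(ids)) ids <- names(sequences) %||% paste0("seq_", seq_len(n))
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    classes <- levels(f)
    y <- as.integer(f) - 1L
  } else {
    y <- as.integer(labels)
    if (any(y < 0)) stop("integer labels must be >= 0", call. = FALSE)
    classes <- as.character(sort(unique(y)))
  }
  if (!is.null(aux)) {
    aux <- as.matrix(aux)
    if (nrow(aux) != n)
      stop("aux feature table must have one row per record", call. = FALSE)
  }
  structure(list(ids = ids, sequences = unname(sequences), labels = y,
                 classes = classes, aux = aux,
                 split = rep(NA_character_, n)),
            class = "gpg_dataset")
}

#' @export
print.gpg_dataset <- function(x, ...) {
  cat("gpg_dataset:", length(x$sequences), "records,",
      length(x$classes), "classes\n")
  print(table(class = x$classes[x$labels + 1L],
              split = factor(x$split, c("train", "val", "test")),
              useNA = "ifany"))
  invisible(x)
}

#' Assign train/validation/test membership
#'
#' Deterministic given the seed. Stratified mode (the default) splits each
#' class separately so class proportions carry over to every split; split
#' sizes match the requested ratios up to largest-remainder rounding.
#'
#' @param dataset A [gpg_dataset()].
#' @param ratios Numeric triple (train, val, test) summing to 1; the common
#'   80/10/10 is the default, and `c(0.9, 0.1, 0)` gives a train/validation
#'   split with an external test set.
#' @param seed Integer seed.
#' @param stratified Preserve class proportions per split.
#' @return The dataset with its `split` field filled in.
#' @export
split_dataset <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 1,
                          stratified = TRUE) {
  stopifnot(inherits(dataset, "gpg_dataset"))
  if (length(ratios) != 3 || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("`ratios` must be three non-negative numbers summing to 1",
         call. = FALSE)
  n <- length(dataset$sequences)
  split <- character(n)
  set.seed(seed)
  groups <- if (stratified) split(seq_len(n), dataset$labels)
            else list(seq_len(n))
  for (g in groups) {
    m <- length(g)
    sizes <- .largest_remainder(m, ratios)
    lab <- rep(c("train", "val", "test"), times = sizes)
    split[g] <- sample(lab)   # random permutation within the stratum
  }
  dataset$split <- split
  dataset
}

# Integer apportionment of n into round(n * ratios) preserving the total.
.largest_remainder <- function(n, ratios) {
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Inverse-frequency sampling weights
#'
#' Weight of a record with class `c` is `1 / count(c)` in the supplied
#' labels; sampling records with replacement proportionally to these weights
#' draws every class with equal probability `1/K`.
#'
#' @param labels Integer (0-based) or factor class labels.
#' @return Numeric weight per record.
#' @export
sample_weights <- function(labels) {
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  f <- as.character(labels)
  cnt <- table(f)
  as.numeric(1 / cnt[f])
}

#' Multiclass cross-entropy loss
#'
#' Mean over the batch of the negative log predicted probability of the true
#' class, with a configurable probability floor inside the log for numerical
#' safety.
#'
#' @param prob Matrix of class probabilities (rows sum to 1) or a single
#'   probability vector.
#' @param labels True classes, 0-based integers.
#' @param eps Probability floor (default 1e-12).
#' @return Scalar loss.
#' @examples
#' cross_entropy(matrix(0.5, 2, 2), c(0, 1))  # log(2)
#' @export
cross_entropy <- function(prob, labels, eps = 1e-12) {
  if (is.vector(prob)) prob <- matrix(prob, nrow = 1)
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= ncol(prob)))
    stop("labels out of range [0, K)", call. = FALSE)
  p_true <- prob[cbind(seq_len(nrow(prob)), labels + 1L)]
  mean(-log(pmax(p_true, eps)))
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience on validation loss (epochs);
#'   `Inf` disables early stopping.
#' @param seed Seed for sampling and any other training randomness.
#' @param metric Validation metric used for model selection in
#'   [grid_search()]: overall accuracy or macro-averaged F1.
#' @return Object of class `gpg_train_config`.
#' @export
train_config <- function(batch_size = 32, lr = 1e-4, epochs = 100,
                         patience = 10, seed = 1,
                         metric = c("accuracy", "macro_f1")) {
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed), metric = match.arg(metric)),
            class = "gpg_train_config")
}

# --- Adam -------------------------------------------------------------------

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

# --- core training loop -----------------------------------------------------

.aux_rows <- function(aux, idx) {
  if (is.null(aux)) NULL else aux[idx, , drop = FALSE]
}

# Probabilities for a list of graphs. aux: matrix (rows align) or NULL.
.predict_probs <- function(graphs, aux, params, config, topo) {
  K <- config$n_classes
  out <- matrix(NA_real_, length(graphs), K)
  for (i in seq_along(graphs)) {
    a <- if (config$aux_dim > 0) aux[i, ] else NULL
    out[i, ] <- .model_forward(graphs[[i]], a, params, config, topo)$prob
  }
  out
}

.macro_f1 <- function(truth, pred, K) {
  f1 <- vapply(seq_len(K) - 1L, function(c) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# Work-horse: trains `params` on pre-encoded graphs. Returns best-validation
# weights and the per-epoch history.
.train_loop <- function(params, graphs, aux, labels, train_idx, val_idx,
                        config, tc, topo, verbose = FALSE) {
  K <- config$n_classes
  theta <- unlist(params, use.names = FALSE)
  skeleton <- unclass(params)
  state <- .adam_init(length(theta))
  w <- sample_weights(labels[train_idx])
  steps <- max(1L, ceiling(length(train_idx) / tc$batch_size))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  set.seed(tc$seed)
  if (tc$epochs < 1)
    return(list(params = params, history = history, best_epoch = 0L))
  for (epoch in seq_len(tc$epochs)) {
    epoch_loss <- 0
    for (s in seq_len(steps)) {
      batch <- sample(train_idx, tc$batch_size, replace = TRUE, prob = w)
      gacc <- NULL
      bloss <- 0
      for (i in batch) {
        a <- if (config$aux_dim > 0) aux[i, ] else NULL
        fw <- .model_forward(graphs[[i]], a, params, config, topo)
        p <- fw$prob
        bloss <- bloss - log(max(p[labels[i] + 1L], 1e-12))
        dlogits <- p
        dlogits[labels[i] + 1L] <- dlogits[labels[i] + 1L] - 1
        g <- unlist(.model_backward(fw, dlogits / tc$batch_size,
                                    params, config, topo),
                    use.names = FALSE)
        gacc <- if (is.null(gacc)) g else gacc + g
      }
      bloss <- bloss / tc$batch_size
      if (!is.finite(bloss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      state <- .adam_step(state, gacc, tc$lr)
      theta <- theta - state$delta
      params <- utils::relist(theta, skeleton)
      epoch_loss <- epoch_loss + bloss
    }
    vp <- .predict_probs(graphs[val_idx], .aux_rows(aux, val_idx),
                         params, config, topo)
    val_loss <- cross_entropy(vp, labels[val_idx])
    val_acc <- mean(max.col(vp) - 1L == labels[val_idx])
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = epoch_loss / steps,
                                val_loss = val_loss, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, epoch_loss / steps, val_loss, val_acc))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, theta = theta, epoch = epoch)
    } else if (epoch - best$epoch >= tc$patience) {
      break
    }
  }
  params <- utils::relist(best$theta, skeleton)
  class(params) <- "gpgcn_weights"
  list(params = params, history = history, best_epoch = best$epoch)
}

#' Hyperparameter grid search
#'
#' Trains one model per cell of the expanded grid and selects the cell with
#' the best validation metric; ties break toward the earlier cell. Every
#' cell's score is reported.
#'
#' @param dataset A split [gpg_dataset()].
#' @param grid Named list of candidate values for [gpgcn_config()] arguments
#'   (e.g. `list(d = c(0, 2), layers = c(1, 3))`).
#' @param config Base configuration supplying all non-gridded arguments.
#' @param training A [train_config()].
#' @param verbose Print per-cell progress.
#' @return List with `best_config`, `best_index`, `scores` (data.frame of
#'   all cells with their validation metric), and `fits` (per-cell fitted
#'   models).
#' @export
grid_search <- function(dataset, grid, config = gpgcn_config(),
                        training = train_config(), verbose = FALSE) {
  if (length(grid) == 0 || any(lengths(grid) == 0))
    stop("`grid` must name at least one non-empty candidate list",
         call. = FALSE)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  args <- .config_args(config)
  scores <- numeric(nrow(cells))
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell_args <- utils::modifyList(args, as.list(cells[i, , drop = FALSE]))
    cfg <- do.call(gpgcn_config, cell_args)
    fit <- gpgcn(dataset, config = cfg, training = training,
                 verbose = verbose)
    scores[i] <- .val_metric(fit, training$metric)
    fits[[i]] <- fit
    if (verbose)
      message(sprintf("grid cell %d/%d: %s = %.4f", i, nrow(cells),
                      training$metric, scores[i]))
  }
  best <- which.max(scores)   # first maximum wins
  list(best_config = fits[[best]]$config, best_index = best,
       scores = cbind(cells, score = scores), fits = fits)
}

.config_args <- function(config) {
  keep <- c("k", "d", "layers", "hidden", "conv_channels", "conv_kernel",
            "conv_stride", "embed_dim", "mlp_hidden", "n_classes",
            "aux_dim", "window", "activation", "architecture", "seed")
  unclass(config)[keep]
}

.val_metric <- function(fit, metric) {
  idx <- which(fit$dataset_split == "val")
  truth <- fit$labels[idx]
  pred <- max.col(fit$fitted_prob[idx, , drop = FALSE]) - 1L
  if (metric == "accuracy") mean(pred == truth)
  else .macro_f1(truth, pred, fit$config$n_classes)
}
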