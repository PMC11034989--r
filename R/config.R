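# Model hyperparameter container and validation.

#' Model configuration
#'
#' Collects every architectural hyperparameter of the gapped-pattern GCN:
#' graph shape (`k`, `d`, gap binning), convolution depth and width, the
#' 1-D convolutional head that reduces the concatenated pair features to an
#' embedding, the task MLP, and auxiliary-feature fusion.
#'
#' @param k k-mer length (default 3).
#' @param d Maximum gap length (default 2).
#' @param binning Optional [gap_binning()]; default identity over `0:d`.
#' @param layers Number of two-step graph-convolution levels (`l >= 1`).
#' @param hidden Hidden feature width per level (scalar, or vector of
#'   length `layers`).
#' @param conv_channels Channel sizes of the two 1-D convolution layers in
#'   the head.
#' @param conv_kernel,conv_stride Kernel width and stride shared by the
#'   head's convolution layers.
#' @param embed_dim Embedding dimension produced by the head.
#' @param mlp_hidden Integer vector of MLP hidden-layer sizes (may be
#'   `integer(0)` for a linear softmax classifier).
#' @param n_classes Number of task classes `K >= 2`.
#' @param aux_dim Length of the per-sequence auxiliary feature vector fused
#'   into the first MLP layer (0 for none).
#' @param window Window length `w`: 0 encodes the whole sequence as one
#'   graph; `w > 0` cuts sequences into non-overlapping length-`w` windows,
#'   each encoded separately (sequence-level predictions average over
#'   windows).
#' @param activation Nonlinearity, `"relu"` (default) or `"identity"`
#'   (for reference computations).
#' @param architecture `"gpgcn"` (graph convolution + head + MLP) or
#'   `"edge_mlp"` (the no-GCN ablation: flattened pair features straight
#'   into a fully connected classifier).
#' @param seed Integer seed controlling weight initialization.
#' @return Object of class `gpgcn_config`.
#' @export
gpgcn_config <- function(k = 3, d = 2, binning = NULL,
                         layers = 2, hidden = 8,
                         conv_channels = c(32, 8),
                         conv_kernel = 8, conv_stride = 4,
                         embed_dim = 128,
                         mlp_hidden = c(256, 64),
                         n_classes = 2, aux_dim = 0, window = 0,
                         activation = c("relu", "identity"),
                         architecture = c("gpgcn", "edge_mlp"),
                         seed = 1) {
  k <- .check_k(k)
  d <- .check_d(d)
  if (is.null(binning)) binning <- gap_binning(d)
  stopifnot(inherits(binning, "gap_binning"))
  if (binning$d != d) stop("binning range does not match `d`", call. = FALSE)
  architecture <- match.arg(architecture)
  activation <- match.arg(activation)
  layers <- as.integer(layers)
  if (layers < 1) stop("`layers` must be >= 1", call. = FALSE)
  hidden <- as.integer(rep(hidden, length.out = layers))
  if (any(hidden < 1)) stop("hidden sizes must be positive", call. = FALSE)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  aux_dim <- as.integer(aux_dim)
  if (aux_dim < 0) stop("`aux_dim` must be >= 0", call. = FALSE)
  window <- as.integer(window)
  if (window < 0) stop("`window` must be >= 0", call. = FALSE)
  if (window > 0 && window < 2 * k + d)
    stop("`window` shorter than one gapped pattern (2k + d)", call. = FALSE)
  conv_channels <- as.integer(conv_channels)
  if (length(conv_channels) != 2 || any(conv_channels < 1))
    stop("`conv_channels` must be two positive integers", call. = FALSE)
  embed_dim <- as.integer(embed_dim)
  mlp_hidden <- as.integer(mlp_hidden)
  if (embed_dim < 1 || any(mlp_hidden < 1))
    stop("all dimensions must be positive", call. = FALSE)

  cfg <- structure(list(k = k, d = d, binning = binning, B = binning$B,
                        layers = layers, hidden = hidden,
                        conv_channels = conv_channels,
                        conv_kernel = as.integer(conv_kernel),
                        conv_stride = as.integer(conv_stride),
                        embed_dim = embed_dim, mlp_hidden = mlp_hidden,
                        n_classes = n_classes, aux_dim = aux_dim,
                        window = window, activation = activation,
                        architecture = architecture,
                        seed = as.integer(seed)),
                   class = "gpgcn_config")
  if (architecture == "gpgcn") .head_shape(cfg)  # validates positions > 0
  cfg
}

# Positions surviving each convolution of the head; errors if the pair
# axis is too short for the configured kernel/stride.
.head_shape <- function(config) {
  np <- as.integer(4^(2 * config$k))
  p1 <- (np - config$conv_kernel) %/% config$conv_stride + 1L
  if (p1 < 1) stop("conv head kernel exceeds the pair axis (4^(2k))", call. = FALSE)
  p2 <- (p1 - config$conv_kernel) %/% config$conv_stride + 1L
  if (p2 < 1) stop("second conv layer has no output positions; shrink kernel/stride",
                   call. = FALSE)
  list(np = np, p1 = p1, p2 = p2)
}

#' @export
print.gpgcn_config <- function(x, ...) {
  cat("gpgcn config:", x$architecture, "\n")
  cat("  graph: k =", x$k, ", d =", x$d, ", bins =", x$B,
      if (x$window > 0) paste0(", window = ", x$window) else "", "\n")
  if (x$architecture == "gpgcn") {
    cat("  gcn: layers =", x$layers, ", hidden =", paste(x$hidden, collapse = "/"), "\n")
    cat("  head: conv", paste(x$conv_channels, collapse = "->"),
        "kernel", x$conv_kernel, "stride", x$conv_stride,
        "-> embedding", x$embed_dim, "\n")
  }
  cat("  mlp:", if (length(x$mlp_hidden)) paste(x$mlp_hidden, collapse = ", ") else "(linear)",
      "->", x$n_classes, "classes; aux dim", x$aux_dim, "\n")
  invisible(x)
}
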