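# Forward and reverse-mode computation of the gapped-pattern GCN:
# two-step graph-convolution levels over the fixed bipartite topology,
# a 1-D convolutional head over the concatenated pair features, and the
# task MLP. Gradients are hand-derived; Adam consumes the flattened trees.

.act <- function(a, activation) {
  if (activation == "relu") a * (a > 0) else a
}

.act_grad <- function(a, activation) {
  if (activation == "relu") (a > 0) * 1 else array(1, dim = dim(a))
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

.runif_mat <- function(nr, nc, fan_in) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model weights
#'
#' Draws every weight matrix uniformly in `(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' under the configuration seed; biases start at zero. The same config always
#' yields bit-identical weights.
#'
#' @param config A [gpgcn_config()].
#' @return Nested list of weight tensors (class `gpgcn_weights`).
#' @export
init_weights <- function(config) {
  stopifnot(inherits(config, "gpgcn_config"))
  set.seed(config$seed)
  params <- list()
  if (config$architecture == "gpgcn") {
    a_in <- 1L            # k-mer feature width entering level 1
    b_in <- config$B      # pair feature width entering level 1
    gcn <- vector("list", config$layers)
    for (l in seq_len(config$layers)) {
      h <- config$hidden[l]
      gcn[[l]] <- list(W1 = .runif_mat(h, b_in, b_in),
                       B1 = .runif_mat(h, a_in, a_in),
                       W2 = .runif_mat(h, h, h),
                       B2 = .runif_mat(h, b_in, b_in))
      a_in <- h
      b_in <- h
    }
    params$gcn <- gcn
    sh <- .head_shape(config)
    K <- config$conv_kernel
    c1 <- config$conv_channels[1]
    c2 <- config$conv_channels[2]
    h_f <- config$hidden[config$layers]
    params$conv1 <- list(W = .runif_mat(c1, K * h_f, K * h_f), b = numeric(c1))
    params$conv2 <- list(W = .runif_mat(c2, K * c1, K * c1), b = numeric(c2))
    zlen <- c2 + sh$p2 * c2
    params$proj <- list(W = .runif_mat(config$embed_dim, zlen, zlen),
                        b = numeric(config$embed_dim))
    mlp_in <- config$embed_dim + config$aux_dim
  } else {
    mlp_in <- as.integer(4^(2 * config$k)) * config$B + config$aux_dim
  }
  dims <- c(mlp_in, config$mlp_hidden, config$n_classes)
  params$mlp <- lapply(seq_len(length(dims) - 1L), function(i)
    list(W = .runif_mat(dims[i + 1L], dims[i], dims[i]), b = numeric(dims[i + 1L])))
  class(params) <- "gpgcn_weights"
  params
}

#' One two-step graph-convolution level
#'
#' First updates every k-mer vertex from the mean of its pair-vertex
#' neighbors, then updates every pair vertex from the mean of its (already
#' updated) k-mer endpoints:
#' \deqn{h_u' = \sigma(B_1 h_u + W_1 \, \mathrm{mean}\{h_v : v \in N(u)\})}
#' \deqn{h_v' = \sigma(B_2 h_v + W_2 \, \mathrm{mean}\{h_u' : u \in N(v)\})}
#' The second step deliberately consumes the updated \eqn{h_u'}.
#'
#' @param H_u k-mer vertex features, `4^k x a` matrix.
#' @param H_v Pair vertex features, `4^(2k) x b` matrix.
#' @param weights List with matrices `W1 (h x b)`, `B1 (h x a)`,
#'   `W2 (h x h)`, `B2 (h x b)`.
#' @param topology A [build_topology()] object for the same `k`.
#' @param activation `"relu"` or `"identity"`.
#' @return List with updated `H_u` (`4^k x h`) and `H_v` (`4^(2k) x h`).
#' @export
layer_forward <- function(H_u, H_v, weights, topology,
                          activation = "relu") {
  fw <- .layer_forward_cached(H_u, H_v, weights, topology, activation)
  list(H_u = fw$Hu_out, H_v = fw$Hv_out)
}

.layer_forward_cached <- function(H_u, H_v, w, topo, activation) {
  if (nrow(H_u) != topo$n_kmer || nrow(H_v) != topo$n_pair)
    stop("feature matrices do not match the topology", call. = FALSE)
  if (ncol(H_v) != ncol(w$W1) || ncol(H_u) != ncol(w$B1))
    stop("feature widths do not match weight shapes", call. = FALSE)
  Mu <- as.matrix(topo$agg_uv %*% H_v)        # mean pair features at each u
  Au <- H_u %*% t(w$B1) + Mu %*% t(w$W1)
  Hu_out <- .act(Au, activation)
  Mv <- as.matrix(topo$agg_vu %*% Hu_out)     # mean updated u features at each v
  Av <- H_v %*% t(w$B2) + Mv %*% t(w$W2)
  Hv_out <- .act(Av, activation)
  list(Hu_in = H_u, Hv_in = H_v, Mu = Mu, Au = Au, Hu_out = Hu_out,
       Mv = Mv, Av = Av, Hv_out = Hv_out)
}

# Reverse one level. dHu_out/dHv_out are gradients w.r.t. the level outputs.
.layer_backward <- function(cache, dHu_out, dHv_out, w, topo, activation) {
  dAv <- dHv_out * .act_grad(cache$Av, activation)
  dB2 <- t(dAv) %*% cache$Hv_in
  dW2 <- t(dAv) %*% cache$Mv
  dHv_in <- dAv %*% w$B2
  dHu_out_tot <- dHu_out + as.matrix(topo$agg_vu_t %*% (dAv %*% w$W2))
  dAu <- dHu_out_tot * .act_grad(cache$Au, activation)
  dB1 <- t(dAu) %*% cache$Hu_in
  dW1 <- t(dAu) %*% cache$Mu
  dHu_in <- dAu %*% w$B1
  dHv_in <- dHv_in + as.matrix(topo$agg_uv_t %*% (dAu %*% w$W1))
  list(grad = list(W1 = dW1, B1 = dB1, W2 = dW2, B2 = dB2),
       dHu_in = dHu_in, dHv_in = dHv_in)
}

# --- 1-D convolution over the pair axis -------------------------------------

# Receptive-field row indices for an input of P positions.
.conv_index <- function(P, kernel, stride) {
  p_out <- (P - kernel) %/% stride + 1L
  starts <- 1L + (seq_len(p_out) - 1L) * stride
  outer(starts, 0:(kernel - 1L), `+`)   # p_out x kernel
}

.conv_forward <- function(X, W, b, idx, activation) {
  p_out <- nrow(idx)
  Xcol <- X[as.vector(idx), , drop = FALSE]
  dim(Xcol) <- c(p_out, ncol(W))        # (p_out) x (kernel * channels_in)
  A <- Xcol %*% t(W) + rep(b, each = p_out)
  list(Xcol = Xcol, A = A, Y = .act(A, activation))
}

.conv_backward <- function(cache, dY, W, idx, P, C_in, activation) {
  dA <- dY * .act_grad(cache$A, activation)
  dW <- t(dA) %*% cache$Xcol
  db <- colSums(dA)
  dXcol <- dA %*% W
  p_out <- nrow(idx)
  kernel <- ncol(idx)
  dX <- matrix(0, P, C_in)
  dim(dXcol) <- c(p_out * kernel, C_in)
  for (j in seq_len(kernel)) {
    rows <- (j - 1L) * p_out + seq_len(p_out)
    dX[idx[, j], ] <- dX[idx[, j], ] + dXcol[rows, , drop = FALSE]
  }
  list(W = dW, b = db, dX = dX)
}

# --- embedding head ---------------------------------------------------------

.head_forward <- function(Hv, params, config) {
  sh <- .head_shape(config)
  act <- config$activation
  idx1 <- .conv_index(sh$np, config$conv_kernel, config$conv_stride)
  c1 <- .conv_forward(Hv, params$conv1$W, params$conv1$b, idx1, act)
  idx2 <- .conv_index(sh$p1, config$conv_kernel, config$conv_stride)
  c2 <- .conv_forward(c1$Y, params$conv2$W, params$conv2$b, idx2, act)
  amax <- max.col(t(c2$Y), ties.method = "first")   # argmax position per channel
  mx <- c2$Y[cbind(amax, seq_len(ncol(c2$Y)))]
  z <- c(mx, as.vector(c2$Y))
  e <- as.vector(params$proj$W %*% z + params$proj$b)
  list(idx1 = idx1, idx2 = idx2, c1 = c1, c2 = c2, amax = amax, z = z,
       embedding = e)
}

.head_backward <- function(cache, de, params, config) {
  act <- config$activation
  c2ch <- config$conv_channels[2]
  dz <- as.vector(t(params$proj$W) %*% de)
  gproj <- list(W = outer(de, cache$z), b = de)
  dY2 <- matrix(dz[-seq_len(c2ch)], nrow = nrow(cache$c2$Y), ncol = c2ch)
  dmx <- dz[seq_len(c2ch)]
  dY2[cbind(cache$amax, seq_len(c2ch))] <-
    dY2[cbind(cache$amax, seq_len(c2ch))] + dmx
  b2 <- .conv_backward(cache$c2, dY2, params$conv2$W, cache$idx2,
                       nrow(cache$c1$Y), config$conv_channels[1], act)
  b1 <- .conv_backward(cache$c1, b2$dX, params$conv1$W, cache$idx1,
                       .head_shape(config)$np,
                       config$hidden[config$layers], act)
  list(conv1 = list(W = b1$W, b = b1$b), conv2 = list(W = b2$W, b = b2$b),
       proj = gproj, dHv = b1$dX)
}

# --- MLP --------------------------------------------------------------------

.mlp_forward <- function(x, layers, activation) {
  n <- length(layers)
  xs <- vector("list", n)   # inputs to each layer
  as <- vector("list", n)
  for (i in seq_len(n)) {
    xs[[i]] <- x
    a <- as.vector(layers[[i]]$W %*% x + layers[[i]]$b)
    as[[i]] <- a
    x <- if (i < n) .act(a, activation) else a   # last layer: raw logits
  }
  list(xs = xs, as = as, logits = x)
}

.mlp_backward <- function(cache, dlogits, layers, activation) {
  n <- length(layers)
  grads <- vector("list", n)
  da <- dlogits
  for (i in rev(seq_len(n))) {
    grads[[i]] <- list(W = outer(da, cache$xs[[i]]), b = da)
    dx <- as.vector(t(layers[[i]]$W) %*% da)
    if (i > 1L) {
      ga <- .act_grad(cache$as[[i - 1L]], activation)
      da <- dx * as.vector(ga)
    } else {
      da <- dx   # gradient w.r.t. the MLP input
    }
  }
  list(grads = grads, dx = da)
}

# --- full models ------------------------------------------------------------

#' Embed a gapped pattern graph
#'
#' Runs the stacked two-step graph-convolution levels and the convolutional
#' head, returning the sequence embedding. Deterministic given weights.
#' Graph frequencies enter the first level as enrichment relative to a
#' uniform background (vertex features times 4^k, pair features times
#' 4^(2k)); this fixed rescaling only re-parameterizes the first-layer
#' weights but keeps inputs at unit scale for optimization.
#'
#' @param graph A `gpg` built with the config's `k`, `d` and binning.
#' @param params Weights from [init_weights()] or a fitted model.
#' @param config The matching [gpgcn_config()].
#' @param topology Optional precomputed [build_topology()] for `config$k`.
#' @return Numeric embedding vector of length `config$embed_dim`.
#' @export
gcn_embed <- function(graph, params, config, topology = NULL) {
  fw <- .model_forward(graph, NULL, params, config,
                       topology %||% build_topology(config$k))
  fw$head$embedding
}

#' Classify an embedding
#'
#' Applies the task MLP to an embedding, with optional auxiliary features
#' concatenated at the first layer, and returns softmax class probabilities.
#'
#' @param embedding Numeric vector.
#' @param aux_features Numeric vector of auxiliary features (`NULL` or
#'   length 0 when the model uses none).
#' @param mlp_weights List of MLP layers (`W`, `b`) as in
#'   `init_weights(config)$mlp`.
#' @param activation Hidden-layer nonlinearity.
#' @return Probability vector (non-negative, sums to 1).
#' @export
classify <- function(embedding, aux_features, mlp_weights,
                     activation = "relu") {
  x <- c(embedding, aux_features)
  if (length(x) != ncol(mlp_weights[[1]]$W))
    stop("embedding + aux length does not match the first MLP layer",
         call. = FALSE)
  .softmax(.mlp_forward(x, mlp_weights, activation)$logits)
}

#' Forward pass of the no-GCN ablation model
#'
#' Flattens the graph's pair-feature matrix (the gapped-pattern frequencies)
#' and feeds it, together with any auxiliary features, straight into a fully
#' connected classifier — no graph convolution, no convolutional head.
#'
#' @param graph A `gpg`.
#' @param params Weights initialized with `architecture = "edge_mlp"`.
#' @param aux_features Optional auxiliary feature vector.
#' @param activation Hidden-layer nonlinearity.
#' @return Probability vector over the classes.
#' @export
ablation_forward <- function(graph, params, aux_features = NULL,
                             activation = "relu") {
  classify(as.vector(graph$pair), aux_features, params$mlp, activation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full forward pass with caches; graph features enter as H_u = vertex column,
# H_v = pair matrix.
.model_forward <- function(graph, aux, params, config, topo) {
  if (graph$k != config$k || ncol(graph$pair) != config$B)
    stop("graph shape does not match the model configuration", call. = FALSE)
  if (config$aux_dim > 0 && length(aux) != config$aux_dim)
    stop("auxiliary feature length does not match `aux_dim`", call. = FALSE)
  act <- config$activation
  # Frequencies enter as enrichment over the uniform background (x 4^k for
  # vertices, x 4^(2k) for pairs) so first-layer inputs have unit scale; a
  # pure re-parameterization of the first-layer weights that keeps gradient
  # magnitudes usable.
  Hu <- matrix(graph$vertex * 4^config$k, ncol = 1)
  Hv <- graph$pair * 4^(2 * config$k)
  if (config$architecture == "edge_mlp") {
    x <- c(as.vector(Hv), if (config$aux_dim > 0) aux)
    mlp <- .mlp_forward(x, params$mlp, act)
    return(list(mlp = mlp, prob = .softmax(mlp$logits)))
  }
  caches <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    caches[[l]] <- .layer_forward_cached(Hu, Hv, params$gcn[[l]], topo, act)
    Hu <- caches[[l]]$Hu_out
    Hv <- caches[[l]]$Hv_out
  }
  head <- .head_forward(Hv, params, config)
  x <- c(head$embedding, if (config$aux_dim > 0) aux)
  mlp <- .mlp_forward(x, params$mlp, act)
  list(gcn = caches, head = head, mlp = mlp, prob = .softmax(mlp$logits))
}

# Reverse pass; dlogits is the gradient at the MLP output. Returns a
# gradient tree shaped like `params`.
.model_backward <- function(fw, dlogits, params, config, topo) {
  act <- config$activation
  mb <- .mlp_backward(fw$mlp, dlogits, params$mlp, act)
  grads <- list()
  if (config$architecture == "edge_mlp") {
    grads$mlp <- mb$grads
    return(grads)
  }
  de <- mb$dx[seq_len(config$embed_dim)]   # aux part of dx is discarded
  hb <- .head_backward(fw$head, de, params, config)
  dHv <- hb$dHv
  h_last <- config$hidden[config$layers]
  dHu <- matrix(0, topo$n_kmer, h_last)
  ggcn <- vector("list", config$layers)
  for (l in rev(seq_len(config$layers))) {
    lb <- .layer_backward(fw$gcn[[l]], dHu, dHv, params$gcn[[l]], topo, act)
    ggcn[[l]] <- lb$grad
    dHu <- lb$dHu_in
    dHv <- lb$dHv_in
  }
  grads$gcn <- ggcn
  grads$conv1 <- hb$conv1
  grads$conv2 <- hb$conv2
  grads$proj <- hb$proj
  grads$mlp <- mb$grads
  grads
}
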