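# Independent brute-force references used across the suite. These stay
# deliberately naive (string enumeration, explicit neighbor loops, dense
# adjacency) so they share no code path with the implementation.

rand_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# Tally every length-k substring by direct enumeration.
oracle_count_kmers <- function(sequence, k) {
  out <- stats::setNames(numeric(4^k), all_kmers(k))
  L <- nchar(sequence)
  if (L >= k) for (i in 1:(L - k + 1)) {
    w <- substr(sequence, i, i + k - 1)
    if (grepl("^[ACGT]+$", w)) out[w] <- out[w] + 1
  }
  out
}

# Enumerate every substring of length 2k+g and decompose it as s.x.t.
oracle_count_pairs <- function(sequence, k, d) {
  km <- all_kmers(k)
  out <- array(0, dim = c(4^k, 4^k, d + 1), dimnames = list(km, km, 0:d))
  L <- nchar(sequence)
  for (g in 0:d) {
    span <- 2 * k + g
    if (L < span) next
    for (i in 1:(L - span + 1)) {
      w <- substr(sequence, i, i + span - 1)   # whole s.x.t span clean
      if (grepl("^[ACGT]+$", w)) {
        s <- substr(w, 1, k)
        t <- substr(w, k + g + 1, span)
        out[s, t, g + 1] <- out[s, t, g + 1] + 1
      }
    }
  }
  out
}

# Dense reference for one two-step convolution level: explicit neighbor
# lists and loop-computed means. `shuffle` permutes each neighbor list to
# demonstrate order invariance of the aggregation.
oracle_layer_forward <- function(H_u, H_v, w, k, activation = "relu",
                                 shuffle = FALSE) {
  nk <- 4^k
  act <- function(a) if (activation == "relu") pmax(a, 0) else a
  pair_members <- function(p) {        # 1-based k-mer endpoints of pair p
    unique(c((p - 1) %/% nk + 1, (p - 1) %% nk + 1))
  }
  Hu_new <- matrix(0, nk, nrow(w$W1))
  for (u in 1:nk) {
    nb <- which(vapply(1:(nk * nk), function(p) u %in% pair_members(p),
                       logical(1)))
    if (shuffle) nb <- nb[sample.int(length(nb))]
    m <- colMeans(H_v[nb, , drop = FALSE])
    Hu_new[u, ] <- act(w$B1 %*% H_u[u, ] + w$W1 %*% m)
  }
  Hv_new <- matrix(0, nk * nk, nrow(w$W2))
  for (p in 1:(nk * nk)) {
    nb <- pair_members(p)
    if (shuffle) nb <- nb[sample.int(length(nb))]
    m <- colMeans(Hu_new[nb, , drop = FALSE])   # uses the UPDATED h_u
    Hv_new[p, ] <- act(w$B2 %*% H_v[p, ] + w$W2 %*% m)
  }
  list(H_u = Hu_new, H_v = Hv_new)
}

# Naive strided 1-D convolution + ReLU, looped position by position.
oracle_conv1d <- function(X, W, b, kernel, stride, activation = "relu") {
  p_out <- (nrow(X) - kernel) %/% stride + 1
  out <- matrix(0, p_out, nrow(W))
  for (p in seq_len(p_out)) {
    start <- (p - 1) * stride + 1
    patch <- as.vector(X[start:(start + kernel - 1), ])
    a <- W %*% patch + b
    out[p, ] <- if (activation == "relu") pmax(a, 0) else a
  }
  out
}

# All gapped patterns of a motif by expanding the IUPAC consensus into
# concrete strings first, then sliding every s.x.t decomposition.
oracle_motif_patterns <- function(motif, k, d) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  opts <- lapply(strsplit(motif, "")[[1]], function(ch) iupac[[ch]])
  concrete <- apply(expand.grid(opts, stringsAsFactors = FALSE), 1, paste,
                    collapse = "")
  seen <- character(0)
  for (s in concrete) {
    L <- nchar(s)
    for (g in 0:d) {
      span <- 2 * k + g
      if (span > L) next
      for (i in 1:(L - span + 1))
        seen <- c(seen, paste(substr(s, i, i + k - 1), g,
                              substr(s, i + k + g, i + span - 1)))
    }
  }
  sort(unique(seen))
}

pattern_key <- function(patterns) {
  sort(paste(patterns$s, patterns$gap, patterns$t))
}
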