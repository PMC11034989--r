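# Fixed bipartite message-passing topology between k-mer-pair vertices and
# k-mer vertices. Depends only on k; shared by every sequence graph.

#' Build the bipartite pair/k-mer topology
#'
#' The 4^(2k) pair vertices (one per ordered k-mer pair, lexicographic by
#' (index(s), index(t))) connect to their constituent k-mer vertices in both
#' directions: pair (s, t) touches s and t (a single neighbor when s = t),
#' and k-mer u touches every pair containing u (2*4^k - 1 of them).
#'
#' The mean-aggregation steps of the convolution are precomputed as sparse
#' row-stochastic operators: `agg_uv` (4^k x 4^(2k)) averages pair features
#' into k-mer vertices, `agg_vu` (4^(2k) x 4^k) averages k-mer features into
#' pair vertices.
#'
#' @param k k-mer length, 1--8.
#' @return Object of class `gpg_topology` with fields `k`, `n_kmer`,
#'   `n_pair`, `agg_uv`, `agg_vu`.
#' @export
build_topology <- function(k) {
  k <- .check_k(k)
  nk <- as.integer(4^k)
  np <- nk * nk
  s <- rep(seq_len(nk), each = nk)      # 1-based left k-mer of pair row
  t <- rep(seq_len(nk), times = nk)     # 1-based right k-mer

  # pair -> k-mer edges: pair p(s,t) is a neighbor of both s and t; when
  # s == t it is listed once (sets, not multisets).
  self <- s == t
  ku <- c(s, t[!self])                  # k-mer endpoint
  pv <- c(seq_len(np), which(!self))    # pair vertex
  deg_u <- 2L * nk - 1L                 # pairs containing any fixed u
  agg_uv <- Matrix::sparseMatrix(i = ku, j = pv, x = 1 / deg_u,
                                 dims = c(nk, np))

  # k-mer -> pair edges: mean over {s, t} (singleton when s == t).
  w <- ifelse(self, 1, 0.5)
  agg_vu <- Matrix::sparseMatrix(i = c(seq_len(np), which(!self)),
                                 j = c(s, t[!self]),
                                 x = c(w, rep(0.5, sum(!self))),
                                 dims = c(np, nk))

  structure(list(k = k, n_kmer = nk, n_pair = np,
                 agg_uv = agg_uv, agg_vu = agg_vu,
                 # transposes precomputed for the reverse pass
                 agg_uv_t = Matrix::t(agg_uv), agg_vu_t = Matrix::t(agg_vu)),
            class = "gpg_topology")
}

#' @export
print.gpg_topology <- function(x, ...) {
  cat("bipartite GPG topology: k =", x$k, "(", x$n_kmer, "k-mer vertices,",
      x$n_pair, "pair vertices )\n")
  invisible(x)
}
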