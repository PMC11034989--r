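# Gapped pattern graph construction: k-mer counting, gapped k-mer-pair
# counting, per-gap normalization, and gap-range binning.

#' Gap-length binning scheme
#'
#' Partitions the gap lengths `{0, ..., d}` into `B` contiguous bins. With the
#' default identity binning every gap length keeps its own bin (`B = d + 1`);
#' for large `d` coarser bins compress the pair-feature width while conserving
#' total counts.
#'
#' @param d Maximum gap length (non-negative integer).
#' @param bins Optional list of integer vectors, each a contiguous run of gap
#'   lengths; together they must cover `0:d` exactly, in order. `NULL` selects
#'   identity binning.
#' @return An object of class `gap_binning` with fields `d`, `starts`, `ends`
#'   and `B`.
#' @examples
#' gap_binning(2)                          # identity: {0},{1},{2}
#' gap_binning(4, list(0, 1:2, 3:4))       # three bins
#' @export
gap_binning <- function(d, bins = NULL) {
  d <- .check_d(d)
  if (is.null(bins)) bins <- as.list(0:d)
  bins <- lapply(bins, function(b) sort(as.integer(b)))
  flat <- unlist(bins)
  if (!identical(flat, 0:d))
    stop("bins must be contiguous, disjoint and cover exactly {0,...,d}",
         call. = FALSE)
  for (b in bins) {
    if (length(b) == 0L || !identical(b, b[1]:b[length(b)]))
      stop("each bin must be a contiguous range of gap lengths", call. = FALSE)
  }
  structure(list(d = d,
                 starts = vapply(bins, min, integer(1)),
                 ends = vapply(bins, max, integer(1)),
                 B = length(bins)),
            class = "gap_binning")
}

#' @export
print.gap_binning <- function(x, ...) {
  rng <- ifelse(x$starts == x$ends, x$starts,
                paste0(x$starts, "-", x$ends))
  cat("gap binning: d =", x$d, "; bins:", paste(rng, collapse = ", "), "\n")
  invisible(x)
}

is_identity_binning <- function(binning) binning$B == binning$d + 1L

# Which bin (1-based) each gap length 0..d falls into.
.gap_to_bin <- function(binning) {
  rep(seq_len(binning$B), binning$ends - binning$starts + 1L)
}

#' Count k-mer occurrences
#'
#' Tallies every length-`k` window of the sequence into the canonical
#' index order of [all_kmers()]. Windows overlapping a non-ACGT character
#' (e.g. N) contribute nothing. Sequences shorter than `k` give an all-zero
#' vector.
#'
#' @param sequence DNA string.
#' @param k k-mer length (positive integer).
#' @return Named numeric vector of length 4^k, names in canonical k-mer order.
#' @examples
#' cnt <- count_kmers("ATGATGC", 3)
#' cnt[cnt > 0]   # ATG=2, GAT=1, TGA=1, TGC=1
#' @export
count_kmers <- function(sequence, k) {
  k <- .check_k(k)
  codes <- dna_codes(sequence)
  idx <- .kmer_indices(codes, k)
  idx <- idx[!is.na(idx)]
  out <- as.numeric(tabulate(idx + 1L, nbins = 4^k))
  names(out) <- all_kmers(k)
  out
}

#' Count gapped k-mer pairs
#'
#' Entry `[s, t, g+1]` is the number of occurrences of the gapped pattern
#' `s x t` in the sequence, where `x` is any spacer of exactly `g` characters
#' (`0 <= g <= d`). `d = 0` recovers the plain pattern-graph edges (exact
#' k-mer concatenations). Windows overlapping a non-ACGT character are
#' skipped.
#'
#' @param sequence DNA string.
#' @param k k-mer length.
#' @param d Maximum gap length.
#' @return Numeric array of dimension `4^k x 4^k x (d+1)` with dimnames
#'   (left k-mer, right k-mer, gap length).
#' @examples
#' arr <- count_gapped_pairs("ATGATGC", 3, 0)
#' which(arr > 0)   # ATG->ATG and TGA->TGC at gap 0
#' @export
count_gapped_pairs <- function(sequence, k, d) {
  k <- .check_k(k)
  d <- .check_d(d)
  nk <- 4^k
  codes <- dna_codes(sequence)
  kidx <- .kmer_indices(codes, k)
  # prefix counts of ambiguous positions, to reject windows whose spacer
  # overlaps one (the whole s.x.t span must be clean)
  nbad <- cumsum(c(0L, is.na(codes)))
  out <- array(0, dim = c(nk, nk, d + 1L),
               dimnames = list(all_kmers(k), all_kmers(k), 0:d))
  for (g in 0:d) {
    m <- length(codes) - 2L * k - g + 1L   # valid left-window starts
    if (m < 1L) next
    i <- seq_len(m)
    si <- kidx[i]
    ti <- kidx[i + k + g]
    pid <- si * nk + ti                     # 0-based (s major, t minor)
    if (g > 0L) pid[nbad[i + k + g] - nbad[i + k] > 0L] <- NA
    pid <- pid[!is.na(pid)]
    cnt <- tabulate(pid + 1L, nbins = nk * nk)
    # pid = s*nk + t: s is the major digit, so fill a (t, s) matrix and
    # transpose to land counts at [s, t].
    out[, , g + 1L] <- t(matrix(cnt, nrow = nk, ncol = nk))
  }
  out
}

#' Sum a per-gap pair tensor into gap bins
#'
#' @param pairs Array from [count_gapped_pairs()] (one slice per gap length).
#' @param binning A [gap_binning()] covering the tensor's gap range.
#' @return Array of dimension `4^k x 4^k x B`; total mass is conserved.
#' @export
bin_gaps <- function(pairs, binning) {
  stopifnot(inherits(binning, "gap_binning"))
  d <- dim(pairs)[3] - 1L
  if (binning$d != d)
    stop("binning covers {0,...,", binning$d, "} but tensor has gaps {0,...,",
         d, "}", call. = FALSE)
  if (is_identity_binning(binning)) return(pairs)
  nk <- dim(pairs)[1]
  out <- array(0, dim = c(nk, nk, binning$B),
               dimnames = list(dimnames(pairs)[[1]], dimnames(pairs)[[2]],
                               paste0(binning$starts, "-", binning$ends)))
  bin_of <- .gap_to_bin(binning)
  for (g in 0:d) out[, , bin_of[g + 1L]] <- out[, , bin_of[g + 1L]] + pairs[, , g + 1L]
  out
}

#' Build the gapped pattern graph of a sequence
#'
#' Composes k-mer counting, gapped-pair counting, per-gap normalization and
#' gap binning into the graph feature container consumed by the network.
#' All 4^k vertices and all 4^(2k) x B pair entries are always present
#' (zero where the pattern does not occur), so every sequence maps to
#' features of identical shape.
#'
#' Normalization divides vertex counts by the number of k-mer occurrences
#' `L - k + 1` and the gap-`g` pair counts by the number of length-`(2k+g)`
#' windows `max(1, L - 2k - g + 1)`; it is applied before binning, so binned
#' entries are sums of normalized per-gap frequencies. Runtime is linear in
#' the sequence length at fixed `k` and `d`.
#'
#' @param sequence DNA string (ambiguity characters allowed; windows
#'   overlapping them are skipped).
#' @param k k-mer length (default 3).
#' @param d Maximum gap length (default 2).
#' @param binning A [gap_binning()]; default identity over `0:d`.
#' @param normalize Use normalized frequencies (default) rather than
#'   absolute counts.
#' @param id Optional sequence identifier carried on the graph.
#' @return An object of class `gpg`: list with `k`, `d`, `binning`, `L`,
#'   `normalized`, `vertex` (length-4^k numeric) and `pair`
#'   (`4^(2k) x B` matrix, rows in lexicographic (s, t) order).
#' @examples
#' g <- build_gpg("ATGATGC", k = 3, d = 0, normalize = FALSE)
#' sum(g$vertex > 0)  # 4 distinct 3-mers
#' sum(g$pair > 0)    # 2 pattern-graph edges
#' @export
build_gpg <- function(sequence, k = 3, d = 2, binning = gap_binning(d),
                      normalize = TRUE, id = NULL) {
  k <- .check_k(k)
  d <- .check_d(d)
  stopifnot(inherits(binning, "gap_binning"))
  if (binning$d != d)
    stop("binning range does not match `d`", call. = FALSE)
  L <- nchar(sequence)
  vertex <- count_kmers(sequence, k)
  pairs <- count_gapped_pairs(sequence, k, d)
  if (normalize) {
    vertex <- vertex / max(1L, L - k + 1L)
    for (g in 0:d) pairs[, , g + 1L] <- pairs[, , g + 1L] / max(1L, L - 2L * k - g + 1L)
  }
  pairs <- bin_gaps(pairs, binning)
  structure(list(k = k, d = d, binning = binning, L = L,
                 normalized = normalize, id = id,
                 vertex = vertex,
                 pair = .pairs_to_matrix(pairs)),
            class = "gpg")
}

# (s, t, bin) array -> (4^(2k) x B) matrix with row r = s*4^k + t + 1
# (lexicographic by (index(s), index(t))).
.pairs_to_matrix <- function(pairs) {
  nk <- dim(pairs)[1]
  B <- dim(pairs)[3]
  out <- matrix(0, nrow = nk * nk, ncol = B)
  for (b in seq_len(B)) out[, b] <- as.vector(t(pairs[, , b]))
  colnames(out) <- dimnames(pairs)[[3]]
  out
}

#' Normalize an absolute-count gapped pattern graph
#'
#' Divides vertex counts by `L - k + 1` and gap-`g` pair counts by
#' `max(1, L - 2k - g + 1)`. Requires identity binning (the per-gap
#' denominators are otherwise lost); [build_gpg()] normalizes before binning
#' for that reason. Normalizing an already-normalized graph is an error, not
#' a silent no-op.
#'
#' @param graph A `gpg` in absolute mode with identity binning.
#' @return The graph with `normalized = TRUE`.
#' @export
normalize_gpg <- function(graph) {
  stopifnot(inherits(graph, "gpg"))
  if (graph$normalized)
    stop("graph is already normalized", call. = FALSE)
  if (!is_identity_binning(graph$binning))
    stop("per-gap normalization needs identity binning; normalize before binning",
         call. = FALSE)
  L <- graph$L
  graph$vertex <- graph$vertex / max(1L, L - graph$k + 1L)
  for (g in 0:graph$d)
    graph$pair[, g + 1L] <- graph$pair[, g + 1L] / max(1L, L - 2L * graph$k - g + 1L)
  graph$normalized <- TRUE
  graph
}

#' @export
print.gpg <- function(x, ...) {
  cat("gapped pattern graph: k =", x$k, ", d =", x$d,
      ", bins =", x$binning$B, "\n")
  cat("  source length", x$L, ";",
      if (x$normalized) "normalized" else "absolute", "counts\n")
  cat("  nonzero vertices:", sum(x$vertex > 0), "/", length(x$vertex), "\n")
  cat("  nonzero pair entries:", sum(x$pair > 0), "/", length(x$pair), "\n")
  invisible(x)
}

#' Tabulate the nonzero entries of a gapped pattern graph
#'
#' Long-format view used for inspection and the TSV export: one row per
#' nonzero vertex (`type = "vertex"`, `kmer_t` and `gap_bin` empty) and one
#' row per nonzero pair entry (`type = "edge"`).
#'
#' @param x A `gpg`.
#' @param ... Unused.
#' @return data.frame with columns `type, kmer_s, kmer_t, gap_bin, value`.
#' @export
as.data.frame.gpg <- function(x, ...) {
  k <- x$k
  nk <- 4^k
  km <- all_kmers(k)
  vi <- which(x$vertex > 0)
  vdf <- data.frame(type = rep("vertex", length(vi)),
                    kmer_s = km[vi], kmer_t = NA_character_,
                    gap_bin = NA_character_,
                    value = unname(x$vertex[vi]),
                    stringsAsFactors = FALSE)
  ei <- which(x$pair > 0, arr.ind = TRUE)
  bins <- colnames(x$pair)
  if (is.null(bins)) bins <- as.character(seq_len(ncol(x$pair)) - 1L)
  edf <- data.frame(type = rep("edge", nrow(ei)),
                    kmer_s = km[(ei[, 1] - 1L) %/% nk + 1L],
                    kmer_t = km[(ei[, 1] - 1L) %% nk + 1L],
                    gap_bin = bins[ei[, 2]],
                    value = x$pair[ei],
                    stringsAsFactors = FALSE)
  rbind(vdf, edf)
}

#' Write a gapped pattern graph to TSV
#'
#' @param graph A `gpg`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gpg_tsv <- function(graph, path) {
  utils::write.table(as.data.frame(graph), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
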