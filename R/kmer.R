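# Base-4 encoding of DNA and the canonical k-mer index.
# Alphabet order is fixed A < C < G < T; a k-mer maps to the integer whose
# base-4 digits are its letters, giving a bijection onto [0, 4^k).

.dna_code_table <- local({
  tab <- rep(NA_integer_, 256L)
  tab[as.integer(charToRaw("A")) + 1L] <- 0L
  tab[as.integer(charToRaw("C")) + 1L] <- 1L
  tab[as.integer(charToRaw("G")) + 1L] <- 2L
  tab[as.integer(charToRaw("T")) + 1L] <- 3L
  tab[as.integer(charToRaw("a")) + 1L] <- 0L
  tab[as.integer(charToRaw("c")) + 1L] <- 1L
  tab[as.integer(charToRaw("g")) + 1L] <- 2L
  tab[as.integer(charToRaw("t")) + 1L] <- 3L
  tab
})

#' Encode a DNA string as integer base codes
#'
#' Maps A, C, G, T (either case) to 0, 1, 2, 3; every other character
#' (ambiguity codes such as N, gaps, whitespace) becomes `NA`, which
#' downstream counting treats as "skip any window overlapping this position".
#'
#' @param sequence A single character string over the DNA alphabet.
#' @return Integer vector of length `nchar(sequence)` with values 0--3 or `NA`.
#' @keywords internal
dna_codes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(integer(0))
  .dna_code_table[as.integer(charToRaw(sequence)) + 1L]
}

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k))
    stop("`k` must be a positive integer", call. = FALSE)
  if (k > 8)
    stop("`k` > 8 is not supported (4^(2k) pair features explode)", call. = FALSE)
  as.integer(k)
}

.check_d <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d != floor(d))
    stop("`d` must be a non-negative integer", call. = FALSE)
  as.integer(d)
}

#' Convert k-mer strings to canonical indices
#'
#' The index is the base-4 number spelled by the k-mer under A=0, C=1, G=2,
#' T=3, i.e. a lexicographic ordering with A < C < G < T. Indices run over
#' `[0, 4^k)` and the mapping is a bijection with [index_to_kmer()].
#'
#' @param kmers Character vector of equal-length DNA strings.
#' @return Integer vector of 0-based indices (`NA` for strings containing
#'   non-ACGT characters).
#' @examples
#' kmer_to_index(c("AAA", "ATG", "TTT"))
#' @export
kmer_to_index <- function(kmers) {
  if (length(kmers) == 0L) return(integer(0))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("all k-mers must have the same length", call. = FALSE)
  k <- .check_k(k)
  out <- vapply(kmers, function(s) {
    cc <- dna_codes(s)
    if (anyNA(cc)) return(NA_integer_)
    idx <- 0L
    for (c in cc) idx <- idx * 4L + c
    idx
  }, integer(1), USE.NAMES = FALSE)
  out
}

#' Convert canonical indices back to k-mer strings
#'
#' @param index Integer vector of 0-based indices in `[0, 4^k)`.
#' @param k k-mer length.
#' @return Character vector of k-mers.
#' @examples
#' index_to_kmer(0:3, 1)
#' @export
index_to_kmer <- function(index, k) {
  k <- .check_k(k)
  if (any(index < 0 | index >= 4^k, na.rm = TRUE))
    stop("index out of range [0, 4^k)", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  vapply(index, function(i) {
    if (is.na(i)) return(NA_character_)
    digits <- integer(k)
    for (j in k:1) {
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    paste0(bases[digits + 1L], collapse = "")
  }, character(1))
}

.kmer_cache <- new.env(parent = emptyenv())

#' All k-mers in canonical index order
#'
#' @param k k-mer length.
#' @return Character vector of the 4^k k-mers, position i holding index i-1.
#' @export
all_kmers <- function(k) {
  k <- .check_k(k)
  key <- as.character(k)
  if (is.null(.kmer_cache[[key]]))
    .kmer_cache[[key]] <- index_to_kmer(seq_len(4^k) - 1L, k)
  .kmer_cache[[key]]
}

# Rolling k-mer indices for every window start 1..L-k+1; NA where the window
# overlaps a non-ACGT position. Vectorized, O(kL).
.kmer_indices <- function(codes, k) {
  L <- length(codes)
  n <- L - k + 1L
  if (n < 1L) return(integer(0))
  idx <- codes[seq_len(n)]
  if (k > 1L) for (j in seq_len(k - 1L)) {
    idx <- idx * 4L + codes[(1L + j):(n + j)]
  }
  idx
}
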