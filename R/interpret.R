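# Occlusion-based contribution scores: zero the graph features of a set of
# gapped patterns, measure the mean absolute shift of the predicted class
# probabilities, and compare against a matched random-removal baseline.

.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

# All concrete DNA strings matching an IUPAC window.
.expand_iupac <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  opts <- lapply(chars, function(ch) {
    o <- .iupac[[ch]]
    if (is.null(o)) stop("invalid IUPAC character: ", ch, call. = FALSE)
    o
  })
  n <- prod(lengths(opts))
  if (n > 1e6) stop("motif expands to more than 1e6 sequences", call. = FALSE)
  do.call(paste0, rev(expand.grid(rev(opts), stringsAsFactors = FALSE)))
}

#' Construct a set of gapped patterns
#'
#' A gapped pattern is a left k-mer `s`, a gap length `gap`, and a right
#' k-mer `t`, describing the spaced word `s x t` with `|x| = gap`.
#'
#' @param s,t Character vectors of k-mers (equal length k).
#' @param gap Integer vector of gap lengths (recycled).
#' @return data.frame of class `gapped_pattern` with columns `s`, `gap`, `t`.
#' @examples
#' gapped_pattern("ACG", 2, "TAC")
#' @export
gapped_pattern <- function(s, gap, t) {
  n <- max(length(s), length(gap), length(t))
  df <- data.frame(s = toupper(rep_len(s, n)), gap = as.integer(rep_len(gap, n)),
                   t = toupper(rep_len(t, n)), stringsAsFactors = FALSE)
  if (n > 0) {
    if (length(unique(nchar(c(df$s, df$t)))) != 1)
      stop("`s` and `t` must all be k-mers of one length", call. = FALSE)
    if (any(df$gap < 0)) stop("gap lengths must be >= 0", call. = FALSE)
    if (anyNA(kmer_to_index(c(df$s, df$t))))
      stop("`s` and `t` must be concrete ACGT k-mers", call. = FALSE)
  }
  class(df) <- c("gapped_pattern", "data.frame")
  df
}

# Pair-matrix row and bin column addressed by each pattern.
.pattern_address <- function(patterns, k, binning) {
  if (nchar(patterns$s[1]) != k)
    stop("pattern k-mer length does not match the graph's k", call. = FALSE)
  if (any(patterns$gap > binning$d))
    stop("pattern gap exceeds the graph's maximum gap d", call. = FALSE)
  nk <- as.integer(4^k)
  row <- kmer_to_index(patterns$s) * nk + kmer_to_index(patterns$t) + 1L
  bin <- .gap_to_bin(binning)[patterns$gap + 1L]
  cbind(row, bin)
}

#' Zero the graph features of a set of gapped patterns
#'
#' Sets the pair-feature entries addressed by each pattern `(s, t, bin(gap))`
#' to zero; vertex features and all other entries are untouched, and no
#' renormalization is applied, so the occlusion stays local.
#'
#' @param graph A `gpg`.
#' @param patterns A [gapped_pattern()] set (empty set allowed).
#' @return The modified graph.
#' @export
remove_patterns <- function(graph, patterns) {
  stopifnot(inherits(graph, "gpg"))
  if (NROW(patterns) == 0) return(graph)
  addr <- .pattern_address(patterns, graph$k, graph$binning)
  graph$pair[addr] <- 0
  graph
}

#' Contribution score of a pattern set
#'
#' Predicts class probabilities for every graph before and after
#' [remove_patterns()], and returns the mean (over graphs) of the mean
#' absolute difference of the probability vectors. Zero if and only if the
#' removal changes no prediction; always non-negative.
#'
#' @param model A fitted [gpgcn()].
#' @param graphs List of `gpg` graphs (the evaluation set).
#' @param patterns A [gapped_pattern()] set.
#' @param aux Optional auxiliary feature matrix aligned with `graphs`.
#' @return Scalar score.
#' @export
contribution_score <- function(model, graphs, patterns, aux = NULL) {
  stopifnot(inherits(model, "gpgcn"), length(graphs) > 0)
  before <- predict(model, graphs, aux = aux, type = "prob")
  removed <- lapply(graphs, remove_patterns, patterns = patterns)
  after <- predict(model, removed, aux = aux, type = "prob")
  mean(abs(before - after))
}

# Uniform draw of `n` distinct patterns from the (s, gap, t) universe.
.random_patterns <- function(n, k, d) {
  nk <- as.integer(4^k)
  total <- nk * nk * (d + 1)
  pick <- sample.int(total, n) - 1L
  g <- pick %/% (nk * nk)
  rest <- pick %% (nk * nk)
  gapped_pattern(index_to_kmer(rest %/% nk, k), g, index_to_kmer(rest %% nk, k))
}

#' Random-removal baseline score
#'
#' Mean over `R` repeats of the contribution score of `n_patterns` gapped
#' patterns drawn uniformly without replacement from the full
#' `4^k * 4^k * (d+1)` pattern universe. Deterministic given the seed.
#'
#' @param model A fitted [gpgcn()].
#' @param graphs Evaluation graphs.
#' @param n_patterns Number of patterns removed per repeat.
#' @param R Number of repeats (default 10).
#' @param seed RNG seed.
#' @param aux Optional auxiliary features.
#' @return Scalar baseline score.
#' @export
baseline_score <- function(model, graphs, n_patterns, R = 10, seed = 1,
                           aux = NULL) {
  k <- model$config$k
  d <- model$config$d
  total <- as.integer(4^k)^2 * (d + 1)
  if (n_patterns > total)
    stop("`n_patterns` exceeds the pattern universe (", total, ")",
         call. = FALSE)
  if (n_patterns == 0) return(0)
  set.seed(seed)
  mean(vapply(seq_len(R), function(r) {
    contribution_score(model, graphs, .random_patterns(n_patterns, k, d),
                       aux = aux)
  }, numeric(1)))
}

#' Enumerate the gapped patterns contained in an IUPAC motif
#'
#' Expands the consensus into every concrete matching sequence and collects
#' every decomposition `s x t` with `|s| = |t| = k` and `|x| <= d` that fits
#' inside it; duplicates are merged. A motif of length `< 2k` contains no
#' gapped pattern and yields an empty set (motifs shorter than `k` are an
#' error).
#'
#' @param motif IUPAC consensus string (e.g. `"ATGNNRTA"`).
#' @param k k-mer length.
#' @param d Maximum gap length.
#' @return A [gapped_pattern()] data.frame (possibly 0-row).
#' @export
motif_to_patterns <- function(motif, k, d) {
  k <- .check_k(k)
  d <- .check_d(d)
  L <- nchar(motif)
  if (L < k) stop("motif shorter than k", call. = FALSE)
  out <- list()
  for (g in 0:d) {
    span <- 2L * k + g
    if (span > L) next
    for (start in seq_len(L - span + 1L)) {
      sp <- .expand_iupac(substr(motif, start, start + k - 1L))
      tp <- .expand_iupac(substr(motif, start + k + g, start + span - 1L))
      out[[length(out) + 1L]] <-
        data.frame(s = rep(sp, times = length(tp)), gap = g,
                   t = rep(tp, each = length(sp)),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(gapped_pattern(character(0), integer(0), character(0)))
  df <- unique(do.call(rbind, out))
  rownames(df) <- NULL
  gapped_pattern(df$s, df$gap, df$t)
}

#' Score motifs by occlusion and flag the informative ones
#'
#' For each motif: enumerate its gapped patterns, compute the contribution
#' score of removing them all, compute a matched baseline (same number of
#' randomly chosen patterns, `R` repeats), and flag the motif informative
#' when its contribution strictly exceeds the baseline.
#'
#' @param model A fitted [gpgcn()].
#' @param graphs Evaluation graphs.
#' @param motifs Character vector of IUPAC consensus strings; names become
#'   motif ids.
#' @param R Baseline repeats.
#' @param seed RNG seed (each motif gets a distinct derived seed).
#' @param aux Optional auxiliary features.
#' @return data.frame of class `contribution_report` with columns `id`,
#'   `motif`, `n_patterns`, `contribution`, `baseline`, `informative`.
#' @export
score_motifs <- function(model, graphs, motifs, R = 10, seed = 1,
                         aux = NULL) {
  ids <- names(motifs) %||% paste0("motif_", seq_along(motifs))
  rows <- lapply(seq_along(motifs), function(i) {
    pats <- motif_to_patterns(motifs[[i]], model$config$k, model$config$d)
    contrib <- if (nrow(pats) == 0) 0
               else contribution_score(model, graphs, pats, aux = aux)
    base <- if (nrow(pats) == 0) 0
            else baseline_score(model, graphs, nrow(pats), R = R,
                                seed = seed + i - 1L, aux = aux)
    data.frame(id = ids[i], motif = unname(motifs[[i]]),
               n_patterns = nrow(pats), contribution = contrib,
               baseline = base, informative = contrib > base,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contribution_report", "data.frame")
  out
}

#' Read motifs from a plain-text file
#'
#' One motif per line; an optional first column gives the motif id
#' (whitespace-separated). Empty lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Named character vector of IUPAC consensus strings.
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  ids <- vapply(parts, function(p) if (length(p) > 1) p[1] else NA_character_,
                character(1))
  motifs <- vapply(parts, function(p) toupper(p[length(p)]), character(1))
  ids[is.na(ids)] <- paste0("motif_", which(is.na(ids)))
  names(motifs) <- ids
  motifs
}

#' Write a contribution report to TSV
#'
#' @param report A `contribution_report` from [score_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
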