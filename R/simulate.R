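# Deterministic synthetic sequence sets: i.i.d. background, planted
# gapped-pattern / motif signatures, SNP and indel noise, and class-
# conditional Bernoulli auxiliary features.

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' @param classes Number of classes K.
#' @param n_per_class Sequences per class.
#' @param length_range Two integers (min, max); lengths drawn uniformly.
#' @param composition Background base probabilities (A, C, G, T), summing
#'   to 1.
#' @param signatures List of length `classes`; element `c` is a list of
#'   planting instructions for class `c`, each a list with `pattern` (a
#'   one-row [gapped_pattern()] or an IUPAC motif string) and `copies`
#'   (insertions per sequence).
#' @param snp_rate Per-position substitution probability in `[0, 1)`.
#' @param indel_rate Per-position insertion/deletion probability in `[0, 1)`.
#' @param aux_dim Auxiliary feature dimension (0 for none).
#' @param aux_prob `classes x aux_dim` matrix of Bernoulli presence
#'   probabilities (emulating protein presence/absence encodings).
#' @param seed Master seed; the whole dataset regenerates byte-identically.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(classes = 2, n_per_class = 100,
                       length_range = c(1000, 1000),
                       composition = c(0.25, 0.25, 0.25, 0.25),
                       signatures = NULL,
                       snp_rate = 0, indel_rate = 0,
                       aux_dim = 0, aux_prob = NULL, seed = 1) {
  classes <- as.integer(classes)
  n_per_class <- as.integer(n_per_class)
  if (classes < 2 || n_per_class < 1)
    stop("need K >= 2 classes and n >= 1 sequences per class", call. = FALSE)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 1)
    stop("`length_range` must be (min, max) with 1 <= min <= max",
         call. = FALSE)
  .check_composition(composition)
  if (is.null(signatures)) signatures <- rep(list(list()), classes)
  if (length(signatures) != classes)
    stop("`signatures` must have one element per class", call. = FALSE)
  if (snp_rate < 0 || snp_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("noise rates must lie in [0, 1)", call. = FALSE)
  aux_dim <- as.integer(aux_dim)
  if (aux_dim > 0) {
    aux_prob <- as.matrix(aux_prob)
    if (!all(dim(aux_prob) == c(classes, aux_dim)) ||
        any(aux_prob < 0 | aux_prob > 1))
      stop("`aux_prob` must be a classes x aux_dim matrix of probabilities",
           call. = FALSE)
  }
  structure(list(classes = classes, n_per_class = n_per_class,
                 length_range = length_range, composition = composition,
                 signatures = signatures, snp_rate = snp_rate,
                 indel_rate = indel_rate, aux_dim = aux_dim,
                 aux_prob = aux_prob, seed = as.integer(seed)),
            class = "sim_config")
}

.check_composition <- function(composition) {
  if (length(composition) != 4 || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-8)
    stop("`composition` must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
}

#' Generate i.i.d. background sequences
#'
#' @param n Number of sequences.
#' @param length_range (min, max); lengths uniform on the range.
#' @param composition Base probabilities (A, C, G, T).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Character vector of sequences.
#' @export
generate_background <- function(n, length_range = c(1000, 1000),
                                composition = c(0.25, 0.25, 0.25, 0.25),
                                seed = NULL) {
  .check_composition(composition)
  if (!is.null(seed)) set.seed(seed)
  lens <- length_range[1] - 1L +
    sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(.BASES, L, replace = TRUE, prob = composition),
          collapse = ""), character(1))
}

# Concrete realization of a planting instruction: gapped pattern s.x.t with
# a fresh random spacer, or a sampled IUPAC expansion.
.realize_pattern <- function(pattern) {
  if (inherits(pattern, "gapped_pattern")) {
    gap <- pattern$gap[1]
    x <- if (gap > 0) paste(sample(.BASES, gap, replace = TRUE), collapse = "")
         else ""
    paste0(pattern$s[1], x, pattern$t[1])
  } else {
    chars <- strsplit(toupper(pattern), "")[[1]]
    paste(vapply(chars, function(ch) {
      o <- .iupac[[ch]]
      if (is.null(o)) stop("invalid IUPAC character: ", ch, call. = FALSE)
      if (length(o) == 1) o else sample(o, 1)
    }, character(1)), collapse = "")
  }
}

#' Plant a signature into sequences
#'
#' Overwrites `copies` random non-overlapping stretches of every sequence
#' with concrete realizations of the pattern (the spacer of a gapped pattern
#' is drawn fresh for each insertion). Substitution rather than splicing
#' keeps sequence lengths unchanged, so the length distribution carries no
#' class signal.
#'
#' @param sequences Character vector.
#' @param pattern One-row [gapped_pattern()] or IUPAC motif string.
#' @param copies Insertions per sequence (0 = no-op).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Character vector with signatures planted.
#' @export
plant_signature <- function(sequences, pattern, copies, seed = NULL) {
  if (copies == 0) return(sequences)
  if (!is.null(seed)) set.seed(seed)
  span <- nchar(.realize_pattern(pattern))   # span is fixed for a pattern
  vapply(sequences, function(s) {
    L <- nchar(s)
    if (L < span * copies)
      stop("sequence too short to plant ", copies,
           " non-overlapping copies of a span-", span, " pattern",
           call. = FALSE)
    occupied <- rep(FALSE, L)
    placed <- 0L
    tries <- 0L
    while (placed < copies) {
      tries <- tries + 1L
      if (tries > 1000L * copies)
        stop("could not place non-overlapping signature copies", call. = FALSE)
      start <- sample.int(L - span + 1L, 1)
      if (any(occupied[start:(start + span - 1L)])) next
      substr(s, start, start + span - 1L) <- .realize_pattern(pattern)
      occupied[start:(start + span - 1L)] <- TRUE
      placed <- placed + 1L
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Apply SNP and indel noise
#'
#' Each position is substituted with probability `snp_rate` (by a uniformly
#' chosen different base); independently each position triggers an indel
#' with probability `indel_rate` — a deletion of the position or an
#' insertion of a random base before it, with equal chance.
#'
#' @param sequences Character vector.
#' @param snp_rate,indel_rate Per-position rates in `[0, 1)`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Noisy sequences (lengths may change when `indel_rate > 0`).
#' @export
apply_noise <- function(sequences, snp_rate = 0, indel_rate = 0,
                        seed = NULL) {
  if (snp_rate < 0 || snp_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("noise rates must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (snp_rate == 0 && indel_rate == 0) return(sequences)
  vapply(sequences, function(s) {
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    if (snp_rate > 0) {
      hit <- which(stats::runif(L) < snp_rate)
      for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1)
    }
    if (indel_rate > 0) {
      hit <- which(stats::runif(L) < indel_rate)
      ins <- stats::runif(length(hit)) < 0.5
      pieces <- chars
      pieces[hit[!ins]] <- ""                                   # deletions
      pieces[hit[ins]] <- paste0(sample(.BASES, sum(ins), replace = TRUE),
                                 chars[hit[ins]])               # insertions
      chars <- pieces
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a labeled synthetic dataset
#'
#' Composes background generation, per-class signature planting, noise and
#' auxiliary-feature simulation under a single master seed. Optionally
#' writes the FASTA, the auxiliary feature TSV and a JSON manifest that
#' records the full configuration for exact regeneration.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @param basename File stem used inside `dir` (default `"simulated"`).
#' @return A [gpg_dataset()] with classes `"class_0" ... "class_{K-1}"`.
#' @export
generate_dataset <- function(config, dir = NULL, basename = "simulated") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- character(0)
  labels <- integer(0)
  aux <- NULL
  for (cl in seq_len(config$classes) - 1L) {
    s <- generate_background(config$n_per_class, config$length_range,
                             config$composition)
    for (sig in config$signatures[[cl + 1L]])
      s <- plant_signature(s, sig$pattern, sig$copies)
    s <- apply_noise(s, config$snp_rate, config$indel_rate)
    seqs <- c(seqs, s)
    labels <- c(labels, rep(cl, config$n_per_class))
    if (config$aux_dim > 0) {
      p <- config$aux_prob[cl + 1L, ]
      a <- matrix(stats::rbinom(config$n_per_class * config$aux_dim, 1,
                                rep(p, each = config$n_per_class)),
                  nrow = config$n_per_class)
      aux <- rbind(aux, a)
    }
  }
  ids <- sprintf("class%d_seq%03d", labels,
                 stats::ave(labels, labels, FUN = seq_along))
  ds <- gpg_dataset(seqs, paste0("class_", labels), aux = aux, ids = ids)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, paste0(basename, ".fasta"))
    write_fasta(stats::setNames(seqs, ids), fa)
    files <- list(fasta = fa)
    if (!is.null(aux)) {
      tsv <- file.path(dir, paste0(basename, "_aux.tsv"))
      df <- data.frame(id = ids, aux)
      names(df) <- c("id", paste0("f", seq_len(ncol(aux))))
      utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files$aux <- tsv
    }
    manifest <- file.path(dir, paste0(basename, "_manifest.json"))
    .write_manifest(manifest, command = "simulate",
                    config = .manifest_config(config), seed = config$seed,
                    files = files)
    files$manifest <- manifest
    attr(ds, "files") <- files
  }
  ds
}

# sim_config with gapped_pattern objects flattened for JSON.
.manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$signatures <- lapply(cfg$signatures, function(sigs)
    lapply(sigs, function(sig) {
      p <- sig$pattern
      list(pattern = if (inherits(p, "gapped_pattern"))
                       paste0(p$s[1], "(", p$gap[1], ")", p$t[1])
                     else as.character(p),
           copies = sig$copies)
    }))
  cfg
}
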