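# FASTA and table I/O plus run manifests. Sequence parsing is delegated to
# Biostrings; records come back as plain named character vectors.

#' Read a FASTA file
#'
#' Multi-record FASTA (plain or gzip-compressed). Record ids are preserved
#' in order, sequences are case-folded to upper case, and line wrapping is
#' ignored.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path,
                              width = width)
  invisible(path)
}

#' Read an auxiliary feature table
#'
#' Tab-separated, first column `id`, remaining columns numeric features.
#' Features are joined to sequences by record id; any sequence id missing
#' from the table is a hard error (no silent imputation).
#'
#' @param path TSV path.
#' @param ids Sequence record ids to align the rows to.
#' @return Numeric matrix with `length(ids)` rows.
#' @export
read_aux_tsv <- function(path, ids) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df))
    stop("aux table must have an `id` column", call. = FALSE)
  missing <- setdiff(ids, df$id)
  if (length(missing) > 0)
    stop("aux features missing for ids: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  m <- as.matrix(df[match(ids, df$id), setdiff(names(df), "id"),
                    drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# One manifest per artifact-producing run: command, config, seed, input
# digests, package version, timestamp.
.write_manifest <- function(path, command, config, seed, files = list(),
                            inputs = character(0)) {
  digests <- lapply(inputs, function(f)
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_)
  names(digests) <- inputs
  manifest <- list(command = command, config = config, seed = seed,
                   outputs = files, input_md5 = digests,
                   package = "gpgcn",
                   version = as.character(utils::packageVersion("gpgcn")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
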