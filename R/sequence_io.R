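#' Read sequences from a FASTA or FASTQ file
#'
#' Loads DNA reads or contigs into a tibble with one row per record. Sequences
#' are uppercased; IUPAC ambiguity codes and any other non-`A/C/G/T` letters
#' are replaced by `N` (with a warning), so downstream k-mer counting can
#' simply skip windows containing `N`. FASTQ quality strings are parsed for
#' validation and discarded: the binning method uses composition only.
#'
#' @param path Path to an (uncompressed) FASTA or FASTQ file.
#' @param format `"auto"` (default; decided from the first non-empty byte),
#'   `"fasta"` or `"fastq"` (standard 4-line records).
#' @return A tibble with columns `id` (character, unique), `sequence`
#'   (character over `A/C/G/T/N`) and `length` (integer, bp).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgtACGT", ">r2", "TTTT"), tf)
#' read_sequences(tf)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  if (file.size(path) == 0) abort(paste0("empty input file: ", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  out <- if (format == "fastq") read_fastq_records(path) else read_fasta_records(path)
  if (nrow(out) == 0) abort(paste0("no sequence records in ", path))
  if (anyDuplicated(out$id)) {
    abort(paste0("duplicate read id(s): ",
                 paste(unique(out$id[duplicated(out$id)]), collapse = ", ")))
  }
  out$sequence <- normalize_dna(out$sequence)
  out$length <- nchar(out$sequence)
  out[, c("id", "sequence", "length")]
}

read_fasta_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty input file: ", path))
  if (!startsWith(lines[[1]], ">")) {
    abort("malformed FASTA: record 1 does not start with '>'")
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set)),
    length = unname(Biostrings::width(set))
  )
}

# Line-based 4-line FASTQ parsing: the record-indexed error contract needs to
# know which record broke, which stringset readers do not report.
read_fastq_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(sprintf(
      "malformed FASTQ: record %d is truncated (file has %d lines, not a multiple of 4)",
      length(lines) %/% 4 + 1, length(lines)
    ))
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ: record %d lacks a valid '@' header or '+' separator",
                  bad[[1]]))
  }
  bad_q <- which(nchar(qual) != nchar(seqs))
  if (length(bad_q) > 0) {
    abort(sprintf("malformed FASTQ: record %d quality length differs from sequence length",
                  bad_q[[1]]))
  }
  tibble(
    id = sub("\\s.*$", "", sub("^@", "", hdr)),
    sequence = seqs,
    length = nchar(seqs)
  )
}

normalize_dna <- function(x) {
  x <- toupper(x)
  n_other <- sum(vapply(gregexpr("[^ACGTN]", x), function(m) sum(m > 0), 1L))
  if (n_other > 0) {
    warn(sprintf("%d non-ACGTN character(s) replaced by N", n_other))
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

#' Write reads to a FASTA file
#'
#' @param reads A tibble with `id` and `sequence` columns, as returned by
#'   [read_sequences()] or [simulate_community()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  check_reads(reads)
  set <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read truth labels from a two-column TSV
#'
#' The file maps read id to species label, one pair per line, no header.
#'
#' @param path Path to a tab-separated file with columns read id, species label.
#' @return A tibble with columns `id` and `label`. An empty file yields an
#'   empty tibble (evaluation refuses it later).
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) abort(paste0("truth file not found: ", path))
  if (file.size(path) == 0 || length(readLines(path, warn = FALSE)) == 0) {
    return(tibble(id = character(), label = character()))
  }
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          strip.white = FALSE)
  if (ncol(df) < 2) abort("truth file must have two tab-separated columns: id, label")
  out <- tibble(id = df[[1]], label = df[[2]])
  if (anyDuplicated(out$id)) {
    abort(paste0("duplicate id(s) in truth file: ",
                 paste(unique(out$id[duplicated(out$id)]), collapse = ", ")))
  }
  if (any(is.na(out$label))) abort("truth file has missing labels")
  out
}

#' Write truth labels as a two-column TSV
#'
#' @param truth A tibble with `id` and `label` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_reads <- function(reads) {
  if (!is.data.frame(reads) || !all(c("id", "sequence") %in% names(reads))) {
    abort("`reads` must be a data frame with `id` and `sequence` columns")
  }
  if (anyDuplicated(reads$id)) abort("read ids must be unique")
  invisible(reads)
}

# Truth labels must cover the collection they annotate.
check_truth_covers <- function(truth, ids) {
  missing <- setdiff(ids, truth$id)
  if (length(missing) > 0) {
    abort(sprintf("%d read(s) have no truth label (e.g. %s)",
                  length(missing), missing[[1]]))
  }
  invisible(truth)
}
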