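#' Enumerate the k-mer vocabulary
#'
#' All `4^k` DNA words of length `k` over `{A,C,G,T}` in lexicographic order.
#' With the default `k = 4` the feature space has 256 dimensions.
#'
#' @param k Word length, between 1 and 8. Defaults to 4 (tetranucleotides),
#'   the value reported to describe DNA composition best among k = 2..7.
#' @return A tibble with columns `kmer` (character) and `index` (1-based
#'   position in lexicographic order).
#' @examples
#' kmer_vocabulary(2)
#' nrow(kmer_vocabulary(4)) # 256
#' @export
kmer_vocabulary <- function(k = 4) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > 8) {
    abort("`k` must be a single integer between 1 and 8")
  }
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  grids <- rev(do.call(expand.grid, c(rep(list(bases), k),
                                      stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, grids)
  tibble(kmer = kmers, index = seq_along(kmers))
}

# Map each 0-based k-mer code to the 0-based code of its reverse complement.
# Digits base 4 (A=0,C=1,G=2,T=3): complement each digit (3 - d), reverse order.
revcomp_map <- function(k) {
  n <- 4L^k
  codes <- 0:(n - 1)
  rc <- integer(n)
  rem <- codes
  for (pos in 0:(k - 1)) {
    digit <- rem %% 4L
    rem <- rem %/% 4L
    # digit at power `pos` (last char for pos = 0) moves to power k-1-pos
    rc <- rc + (3L - digit) * 4L^(k - 1L - pos)
  }
  rc + 1L # 1-based
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (`A/C/G/T/N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode a sequence as 0-based base-4 digits; anything not A/C/G/T becomes NA.
encode_dna <- function(sequence) {
  v <- utf8ToInt(sequence)
  code <- rep(NA_real_, length(v))
  code[v == 65L] <- 0 # A
  code[v == 67L] <- 1 # C
  code[v == 71L] <- 2 # G
  code[v == 84L] <- 3 # T
  code
}

# 1-based vocabulary indices of the valid (N-free) windows of one sequence, in
# window order. stats::filter gives the rolling base-4 code; NA from any N in
# the window propagates and marks the window invalid.
window_tokens <- function(sequence, k) {
  code <- encode_dna(sequence)
  if (length(code) < k) return(integer(0))
  idx <- stats::filter(code, 4^(0:(k - 1)), sides = 1)
  idx <- idx[k:length(code)]
  as.integer(idx[!is.na(idx)]) + 1L
}

#' Count k-mers per read
#'
#' Slides a window of length `k` over each read and counts occurrences of
#' every k-mer. Under the default `strand = "both"` each valid window
#' increments both the observed k-mer and its reverse complement, so the
#' 256-dimensional (for k = 4) count vector is strand-symmetric and the token
#' total is twice the number of valid windows. Windows containing `N` are
#' skipped.
#'
#' @param reads Tibble with `id` and `sequence` columns.
#' @param k Word length (default 4).
#' @param strand `"both"` (observed + reverse complement, default) or
#'   `"forward"` (observed strand only).
#' @return A wide tibble: `id`, `n_tokens` (the document length fed to the
#'   topic model), then one integer column per vocabulary k-mer. Reads with no
#'   valid window have `n_tokens = 0`.
#' @examples
#' reads <- tibble::tibble(id = "r1", sequence = "AAAA")
#' counts <- kmer_counts(reads)
#' counts$AAAA; counts$TTTT; counts$n_tokens
#' @export
kmer_counts <- function(reads, k = 4, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  corpus <- kmer_tokenize(reads, k = k, strand = strand)
  vocab <- kmer_vocabulary(k)
  mat <- t(vapply(corpus$tokens, function(tok) tabulate(tok, nbins = nrow(vocab)),
                  integer(nrow(vocab))))
  colnames(mat) <- vocab$kmer
  dplyr::bind_cols(
    tibble(id = corpus$id, n_tokens = corpus$n_tokens),
    as_tibble(mat)
  )
}

# Shared tokenizer: per-read 1-based token index sequences, window order,
# observed k-mer before its reverse complement under strand = "both".
kmer_tokenize <- function(reads, k, strand) {
  check_reads(reads)
  rc <- if (strand == "both") revcomp_map(k) else NULL
  tokens <- lapply(reads$sequence, function(s) {
    w <- window_tokens(s, k)
    if (strand == "both" && length(w) > 0) as.integer(rbind(w, rc[w])) else w
  })
  list(id = reads$id, tokens = tokens,
       n_tokens = vapply(tokens, length, integer(1)))
}

#' Build a k-mer corpus for topic modelling
#'
#' Converts reads into the document/word form consumed by [fit_lda()]: each
#' counted k-mer occurrence is one token, ordered by window position (and
#' observed-before-complement under `strand = "both"`), so a seeded sampler is
#' bit-reproducible. Reads with no valid window (shorter than `k`, or all
#' windows containing `N`) are excluded from the corpus and reported.
#'
#' @inheritParams kmer_counts
#' @return An object of class `kmer_corpus`: a list with `id` (reads kept),
#'   `tokens` (per-read integer vocabulary indices), `n_tokens`, `counts`
#'   (reads-by-vocabulary integer matrix), `vocab`, `k`, `strand` and
#'   `excluded` (ids of degenerate reads).
#' @examples
#' reads <- tibble::tibble(id = c("r1", "r2"), sequence = c("ACGTAC", "NNNN"))
#' corpus <- kmer_corpus(reads)
#' corpus$excluded
#' @export
kmer_corpus <- function(reads, k = 4, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  tk <- kmer_tokenize(reads, k = k, strand = strand)
  vocab <- kmer_vocabulary(k)
  keep <- tk$n_tokens > 0
  if (!any(keep)) abort("all reads are degenerate (no valid k-mer window)")
  excluded <- tk$id[!keep]
  if (length(excluded) > 0) {
    warn(sprintf("%d read(s) with no valid %d-mer window excluded from corpus",
                 length(excluded), k))
  }
  tokens <- tk$tokens[keep]
  counts <- t(vapply(tokens, function(tok) tabulate(tok, nbins = nrow(vocab)),
                     integer(nrow(vocab))))
  rownames(counts) <- tk$id[keep]
  colnames(counts) <- vocab$kmer
  structure(
    list(id = tk$id[keep], tokens = tokens, n_tokens = tk$n_tokens[keep],
         counts = counts, vocab = vocab, k = k, strand = strand,
         excluded = excluded),
    class = "kmer_corpus"
  )
}

#' @export
print.kmer_corpus <- function(x, ...) {
  cat(sprintf("<kmer_corpus> %d reads, k = %d (%d-dim), strand = %s, %s tokens",
              length(x$id), x$k, nrow(x$vocab), x$strand,
              format(sum(x$n_tokens), big.mark = ",")))
  if (length(x$excluded) > 0) cat(sprintf(", %d excluded", length(x$excluded)))
  cat("\n")
  invisible(x)
}

#' Export a k-mer count matrix as TSV
#'
#' @param corpus A `kmer_corpus`.
#' @param path Output path; columns are read id then one column per k-mer.
#' @return `path`, invisibly.
#' @export
write_kmer_counts <- function(corpus, path) {
  df <- data.frame(id = corpus$id, corpus$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
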