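#' Describe a synthetic metagenomic community
#'
#' Collects the parameters of the simulator: species genomes are generated
#' from species-specific order-1 Markov chains over \{A,C,G,T\} (so species
#' differ in oligonucleotide composition, the only genome property the
#' binning method exploits), and reads are drawn at the given abundance
#' ratios with uniform start positions, random strand and i.i.d. substitution
#' errors. The defaults describe a 3-species, equal-abundance community of
#' 1,500 reads of ~1 kbp, the scale used throughout the package's own
#' validation.
#'
#' @param n_species Number of species.
#' @param genome_length Genome length per species (bp).
#' @param abundance Positive relative abundances, one per species (e.g.
#'   `c(1, 3, 9)` for a 1:3:9 community); normalized internally.
#' @param read_length_mean Mean read length (bp).
#' @param read_length_sd SD of read length (bp); 0 gives fixed-length reads.
#' @param n_reads Number of reads to draw.
#' @param error_rate Per-base substitution probability, in \[0, 0.2\].
#' @param divergence Between-species composition divergence in \[0, 1\]: each
#'   species' transition matrix is `divergence * P_species +
#'   (1 - divergence) * uniform`. 0 makes all species i.i.d. uniform
#'   (an unbinnable null community); values near 1 give strongly distinct
#'   composition signatures.
#' @param seed Integer seed; identical spec + seed reproduce the community
#'   byte for byte.
#' @return An object of class `community_spec` (a validated list).
#' @export
community_spec <- function(n_species = 3, genome_length = 50000,
                           abundance = rep(1, n_species),
                           read_length_mean = 1000, read_length_sd = 50,
                           n_reads = 1500, error_rate = 0.01,
                           divergence = 0.8, seed = NULL) {
  if (n_species < 1) abort("`n_species` must be >= 1")
  if (length(abundance) != n_species) {
    abort("`abundance` must have one entry per species")
  }
  if (any(abundance <= 0)) abort("`abundance` entries must be positive")
  if (error_rate < 0 || error_rate > 0.2) abort("`error_rate` must be in [0, 0.2]")
  if (divergence < 0 || divergence > 1) abort("`divergence` must be in [0, 1]")
  if (read_length_mean < 1) abort("`read_length_mean` must be >= 1")
  if (read_length_mean > genome_length) {
    abort("`read_length_mean` must not exceed `genome_length`")
  }
  structure(
    list(n_species = as.integer(n_species),
         genome_length = as.integer(genome_length),
         abundance = abundance / sum(abundance),
         read_length_mean = read_length_mean,
         read_length_sd = read_length_sd,
         n_reads = as.integer(n_reads),
         error_rate = error_rate,
         divergence = divergence,
         seed = seed),
    class = "community_spec"
  )
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("<community_spec> %d species (%s), %d reads of ~%g bp, error %g, divergence %g\n",
              x$n_species,
              paste(format(x$abundance, digits = 3), collapse = ":"),
              x$n_reads, x$read_length_mean, x$error_rate, x$divergence))
  invisible(x)
}

# Species-specific transition matrix: sharp Dirichlet rows mixed toward the
# uniform chain by (1 - divergence).
species_transition <- function(divergence) {
  P <- matrix(rgamma(16, shape = 0.5), 4, 4)
  P <- P / rowSums(P)
  divergence * P + (1 - divergence) * 0.25
}

markov_sequence <- function(length, P, init = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  cum <- t(apply(P, 1, cumsum))
  u <- runif(length)
  states <- integer(length)
  states[1] <- findInterval(u[1], cumsum(init)) + 1L
  if (length >= 2) for (i in 2:length) {
    states[i] <- findInterval(u[i], cum[states[i - 1], ]) + 1L
  }
  paste(bases[states], collapse = "")
}

#' Simulate species genomes
#'
#' One genome per species, each from its own order-1 Markov chain so the
#' species' 4-mer profiles differ (controlled by `divergence`).
#'
#' @param spec A [community_spec()].
#' @return A tibble with columns `species` (label) and `sequence`.
#' @export
simulate_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(derive_seed(spec$seed, "genomes"), {
    tibble(
      species = sprintf("species_%02d", seq_len(spec$n_species)),
      sequence = vapply(seq_len(spec$n_species), function(i) {
        markov_sequence(spec$genome_length, species_transition(spec$divergence))
      }, character(1))
    )
  })
}

#' Simulate reads from genomes
#'
#' Each read's species is drawn with probability proportional to abundance,
#' its start position uniformly, its length around `read_length_mean`
#' (truncated to the genome), its strand uniformly (minus-strand reads are
#' reverse-complemented), and substitution errors are applied i.i.d. at
#' `error_rate`.
#'
#' @param genomes A tibble from [simulate_genomes()].
#' @param spec The same [community_spec()].
#' @return A list with `reads` (tibble `id`, `sequence`, `length`) and
#'   `truth` (tibble `id`, `label`).
#' @export
simulate_reads <- function(genomes, spec) {
  stopifnot(inherits(spec, "community_spec"))
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(spec$seed, "reads"), {
    n <- spec$n_reads
    sp <- sample.int(spec$n_species, n, replace = TRUE, prob = spec$abundance)
    glen <- nchar(genomes$sequence)
    len <- pmax(1L, pmin(
      as.integer(round(rnorm(n, spec$read_length_mean, spec$read_length_sd))),
      glen[sp]
    ))
    start <- as.integer(floor(runif(n) * (glen[sp] - len + 1))) + 1L
    minus <- runif(n) < 0.5
    seqs <- substring(genomes$sequence[sp], start, start + len - 1L)
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    if (spec$error_rate > 0) {
      n_err <- stats::rbinom(n, len, spec$error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(len[i], n_err[i])
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        # substitute with one of the three other bases
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(bases, b), 1)
        }, character(1), USE.NAMES = FALSE)
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    list(
      reads = tibble(id = sprintf("read_%06d", seq_len(n)),
                     sequence = seqs, length = nchar(seqs)),
      truth = tibble(id = sprintf("read_%06d", seq_len(n)),
                     label = genomes$species[sp])
    )
  })
}

#' Simulate a labeled synthetic community
#'
#' Convenience wrapper: genomes then reads, from one spec.
#'
#' @param spec A [community_spec()], or arguments passed to [community_spec()]
#'   via `...` when `spec` is missing.
#' @param ... Arguments forwarded to [community_spec()] when `spec` is not
#'   supplied.
#' @return A list with `reads`, `truth`, `genomes`, `spec`.
#' @examples
#' com <- simulate_community(n_species = 2, genome_length = 2000,
#'                           n_reads = 50, read_length_mean = 200, seed = 1)
#' dplyr::count(com$truth, label)
#' @export
simulate_community <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- community_spec(...)
  genomes <- simulate_genomes(spec)
  rd <- simulate_reads(genomes, spec)
  list(reads = rd$reads, truth = rd$truth, genomes = genomes, spec = spec)
}
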