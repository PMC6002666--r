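#' Assembly statistics from contigs
#'
#' Computes the standard draft-assembly summary: total bases, contig
#' count, min/max contig length, N50, N90, and GC content. N50 is the
#' length of the contig at which the cumulative sum of
#' descending-sorted lengths first reaches 50% of the total (N90 at
#' 90%). GC is `100 * (G + C) / (A + C + G + T)` with ambiguous bases
#' excluded from both numerator and denominator, reported to 2 decimals.
#'
#' @param contigs Tibble with columns `contig_id`, `sequence` (see
#'   [read_fasta_contigs()]).
#' @return A one-row tibble: `total_bases`, `n_contigs`, `min_len`,
#'   `max_len`, `n50`, `n90`, `gc_percent`.
#' @export
assembly_stats <- function(contigs) {
  if (nrow(contigs) == 0L) abort("Need at least one contig.")
  seqs <- toupper(contigs$sequence)
  lens <- nchar(seqs)
  if (any(lens == 0L)) abort("Zero-length contig.")
  bs <- Biostrings::BStringSet(seqs)
  freq <- Biostrings::letterFrequency(bs, letters = c("A", "C", "G", "T"))
  acgt <- colSums(freq)
  gc <- 100 * (acgt[["G"]] + acgt[["C"]]) / sum(acgt)

  sorted <- sort(lens, decreasing = TRUE)
  cum <- cumsum(sorted)
  total <- sum(lens)
  n50 <- sorted[which(cum >= 0.5 * total)[1L]]
  n90 <- sorted[which(cum >= 0.9 * total)[1L]]

  tibble(
    total_bases = total, n_contigs = length(lens),
    min_len = min(lens), max_len = max(lens),
    n50 = n50, n90 = n90, gc_percent = round(gc, 2)
  )
}

#' Tetranucleotide z-score signature of a genome
#'
#' Counts every tetranucleotide over all contigs and their reverse
#' complements (windows containing non-ACGT letters are skipped) and
#' standardises the observed counts against a maximal-order Markov
#' expectation built from the tri- and dinucleotide counts of the same
#' sequence set: for word `w1 w2 w3 w4`,
#' `E = N(w1w2w3) * N(w2w3w4) / N(w2w3)` and
#' `var = E * (N(w2w3) - N(w1w2w3)) * (N(w2w3) - N(w2w3w4)) / N(w2w3)^2`,
#' giving `z = (observed - E) / sqrt(var)` (0 wherever the variance is 0
#' or the expectation undefined). Correlating two such 256-entry z
#' vectors ([tetra_correlation()]) yields the TETRA similarity used to
#' support same-species assignment.
#'
#' @param contigs Contig tibble.
#' @param genome_id Label stored in the signature.
#' @return A `tetra_signature` object: list with `genome_id`, `z` (named
#'   256-vector in lexicographic A<C<G<T order), `observed`, `expected`,
#'   `variance`, `usable_windows`.
#' @export
tetra_signature <- function(contigs, genome_id = "genome") {
  seqs <- toupper(contigs$sequence)
  dna <- Biostrings::DNAStringSet(seqs)
  both <- c(dna, Biostrings::reverseComplement(dna))
  n4 <- colSums(Biostrings::oligonucleotideFrequency(both, width = 4L))
  n3 <- colSums(Biostrings::oligonucleotideFrequency(both, width = 3L))
  n2 <- colSums(Biostrings::oligonucleotideFrequency(both, width = 2L))
  if (sum(n4) == 0) abort("No usable tetranucleotide windows.")
  if (sum(nchar(seqs)) < 5000L) {
    warn("Less than 5 kb of sequence; the tetranucleotide signature will be noisy.")
  }

  words <- names(n4)
  left3 <- substr(words, 1L, 3L)
  right3 <- substr(words, 2L, 4L)
  mid2 <- substr(words, 2L, 3L)
  Nl <- n3[left3]; Nr <- n3[right3]; Nm <- n2[mid2]

  expected <- ifelse(Nm > 0, Nl * Nr / Nm, NA_real_)
  variance <- ifelse(Nm > 0, expected * (Nm - Nl) * (Nm - Nr) / Nm^2, NA_real_)
  z <- ifelse(!is.na(variance) & variance > 0,
              (n4 - expected) / sqrt(variance), 0)
  structure(
    list(genome_id = genome_id,
         z = setNames(as.numeric(z), words),
         observed = setNames(as.numeric(n4), words),
         expected = setNames(as.numeric(expected), words),
         variance = setNames(as.numeric(variance), words),
         usable_windows = sum(n4)),
    class = "tetra_signature"
  )
}

#' @export
print.tetra_signature <- function(x, ...) {
  cat("<tetra_signature>", x$genome_id, "|", x$usable_windows,
      "usable windows (both strands)\n")
  invisible(x)
}

#' TETRA correlation between two genome signatures
#'
#' Pearson correlation of the two 256-entry tetranucleotide z-score
#' vectors; values near 1 support assigning the genomes to the same
#' species.
#'
#' @param sig_a,sig_b `tetra_signature` objects.
#' @return A single correlation in \[-1, 1\], or `NA` (with a warning)
#'   when either vector has zero variance.
#' @export
tetra_correlation <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "tetra_signature"), inherits(sig_b, "tetra_signature"))
  if (stats::sd(sig_a$z) == 0 || stats::sd(sig_b$z) == 0) {
    warn("Zero-variance z vector; TETRA correlation undefined.")
    return(NA_real_)
  }
  stats::cor(sig_a$z, sig_b$z)
}

#' Write a tetranucleotide signature as TSV (tetramer, z)
#' @param sig A `tetra_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tetra_signature <- function(sig, path) {
  readr::write_tsv(tibble(tetramer = names(sig$z), z = sig$z), path)
  invisible(path)
}
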