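# Fixtures and independent brute-force oracles used across the suite.
# Oracles are deliberately naive (loops, full scans) and never share code
# with the implementation they check.

# Random presence/absence tibble with every family present somewhere.
random_pa <- function(n_strains, n_families, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_families * n_strains, 1L, p),
                nrow = n_families, ncol = n_strains)
    if (all(rowSums(m) > 0L)) break
  }
  colnames(m) <- sprintf("s%02d", seq_len(n_strains))
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(family_id = sprintf("f%04d", dplyr::row_number()),
                  .before = 1L)
}

# Brute-force subset counters over the raw 0/1 tibble.
oracle_core <- function(pa, strains) {
  m <- as.matrix(pa[strains]); ok <- 0L
  for (f in seq_len(nrow(m))) if (all(m[f, ] == 1L)) ok <- ok + 1L
  ok
}
oracle_pan <- function(pa, strains) {
  m <- as.matrix(pa[strains]); ok <- 0L
  for (f in seq_len(nrow(m))) if (any(m[f, ] == 1L)) ok <- ok + 1L
  ok
}
oracle_new <- function(pa, strains, g) {
  others <- setdiff(strains, g)
  m <- as.matrix(pa[c(g, others)]); ok <- 0L
  for (f in seq_len(nrow(m))) {
    if (m[f, 1L] == 1L && all(m[f, -1L] == 0L)) ok <- ok + 1L
  }
  ok
}

# Exhaustive (subset, last-added) enumeration by explicit loops.
oracle_observations <- function(pa, n, kind) {
  strains <- setdiff(names(pa), "family_id")
  subsets <- utils::combn(strains, n, simplify = FALSE)
  vals <- integer(0)
  for (T in subsets) {
    for (g in T) {
      vals <- c(vals, switch(kind,
        core = oracle_core(pa, T),
        pan = oracle_pan(pa, T),
        new = oracle_new(pa, T, g)
      ))
    }
  }
  vals
}

# Assembly-statistics oracle: full sort + cumulative scan + direct counts.
oracle_assembly_stats <- function(contigs) {
  lens <- nchar(contigs$sequence)
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  nX <- function(frac) {
    acc <- 0
    for (L in sorted) {
      acc <- acc + L
      if (acc >= frac * total) return(L)
    }
  }
  chars <- strsplit(toupper(paste(contigs$sequence, collapse = "")), "")[[1]]
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T"))
  list(total_bases = total, n_contigs = nrow(contigs),
       min_len = min(lens), max_len = max(lens),
       n50 = nX(0.5), n90 = nX(0.9),
       gc_percent = round(100 * gc / (gc + at), 2))
}

# Sliding-window tetranucleotide oracle: counts k-mers over the forward
# and reverse-complement strand by explicit substring extraction, then
# applies the Markov expectation/variance formulas term by term.
oracle_kmer_counts <- function(seqs, k) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ch <- comp[strsplit(s, "")[[1]]]
    ch[is.na(ch)] <- "N"  # ambiguity codes stay ambiguous
    paste(rev(unname(ch)), collapse = "")
  }
  b <- c("A", "C", "G", "T")
  words <- apply(expand.grid(rev(rep(list(b), k)))[, k:1, drop = FALSE],
                 1L, paste, collapse = "")
  words <- sort(words)
  counts <- setNames(integer(length(words)), words)
  all_seqs <- c(seqs, vapply(seqs, rc, character(1)))
  for (s in all_seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (w %in% words) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

oracle_tetra_z <- function(seqs) {
  n4 <- oracle_kmer_counts(seqs, 4L)
  n3 <- oracle_kmer_counts(seqs, 3L)
  n2 <- oracle_kmer_counts(seqs, 2L)
  z <- setNames(numeric(length(n4)), names(n4))
  for (w in names(n4)) {
    l3 <- substr(w, 1, 3); r3 <- substr(w, 2, 4); m2 <- substr(w, 2, 3)
    if (n2[m2] == 0) next
    E <- n3[l3] * n3[r3] / n2[m2]
    V <- E * (n2[m2] - n3[l3]) * (n2[m2] - n3[r3]) / n2[m2]^2
    if (is.na(V) || V <= 0) next
    z[w] <- (n4[w] - E) / sqrt(V)
  }
  z
}

# A small hand-checkable gene table.
tiny_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    strain = c("A", "A", "B"),
    contig = c("c1", "c1", "c1"),
    start = c(1L, 1001L, 1L),
    end = c(900L, 1900L, 900L),
    strand = c("+", "-", "+"),
    product = c("sulfide quinone oxidoreductase",
                "IS4 family transposase", "hypothetical protein")
  )
}
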