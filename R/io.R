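#' Read a gene table
#'
#' The gene table is a TSV with header and the seven canonical columns
#' `gene_id, strain, contig, start, end, strand, product`. Coordinates are
#' 1-based inclusive; strand is `+` or `-`.
#'
#' @param path File path or connection.
#' @return A validated tibble of gene records.
#' @export
read_gene_table <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), strain = readr::col_character(),
    contig = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), strand = readr::col_character(),
    product = readr::col_character()
  ))
  validate_gene_table(g)
}

validate_gene_table <- function(g) {
  need <- c("gene_id", "strain", "contig", "start", "end", "strand", "product")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols) > 0L) {
    abort(paste0("Gene table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  g <- as_tibble(g)[need]
  bad <- which(is.na(g$gene_id) | is.na(g$start) | is.na(g$end) |
                 !(g$strand %in% c("+", "-")))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed gene record at line %d (data row %d).",
                  bad[1L] + 1L, bad[1L]))
  }
  bad <- which(g$start > g$end)
  if (length(bad) > 0L) {
    abort(sprintf("start > end at line %d (gene %s).", bad[1L] + 1L,
                  g$gene_id[bad[1L]]))
  }
  if (anyDuplicated(g$gene_id)) {
    abort(paste0("Duplicate gene_id: ",
                 g$gene_id[anyDuplicated(g$gene_id)][1L]))
  }
  g
}

#' Write a gene table
#' @param genes Gene tibble as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(validate_gene_table(genes), path)
  invisible(path)
}

hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "evalue", "bit_score")

#' Read an all-vs-all hit table (12-column tabular / m8 format)
#'
#' Parses the standard 12-column tabular output of protein similarity
#' searches: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query/subject start/end, E-value, bit score.
#' No header is expected. Scientific-notation E-values in either case
#' (`1e-5`, `1.0E-05`) are accepted.
#'
#' @param path File path or connection.
#' @return A tibble with one row per hit.
#' @export
read_hit_table <- function(path) {
  raw <- suppressWarnings(readr::read_tsv(path, col_names = hit_cols, col_types = readr::cols(
    query_id = readr::col_character(), subject_id = readr::col_character(),
    pct_identity = readr::col_double(), aln_length = readr::col_integer(),
    mismatches = readr::col_integer(), gap_opens = readr::col_integer(),
    q_start = readr::col_integer(), q_end = readr::col_integer(),
    s_start = readr::col_integer(), s_end = readr::col_integer(),
    evalue = readr::col_double(), bit_score = readr::col_double()
  )))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    abort(sprintf("Malformed hit table row at line %d: expected %s, got '%s'.",
                  prob$row[1L], prob$expected[1L], prob$actual[1L]))
  }
  if (anyNA(raw$evalue) || anyNA(raw$pct_identity)) {
    abort("Hit table contains non-numeric identity or E-value fields.")
  }
  if (any(raw$pct_identity < 0 | raw$pct_identity > 100)) {
    abort("pct_identity outside [0, 100].")
  }
  if (any(raw$evalue < 0)) abort("Negative E-value.")
  if (any(raw$aln_length < 1L)) abort("Alignment length below 1.")
  raw
}

#' Write a hit table in 12-column tabular format (no header)
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(as_tibble(hits)[hit_cols], path, col_names = FALSE)
  invisible(path)
}

#' Read / write a presence/absence matrix as TSV
#'
#' First column `family_id`, then one 0/1 column per strain with strain
#' names in the header row.
#'
#' @param path File path.
#' @return [read_pa_matrix()]: a presence/absence tibble.
#' @export
read_pa_matrix <- function(path) {
  pa <- readr::read_tsv(path, col_types = readr::cols(
    family_id = readr::col_character(), .default = readr::col_integer()
  ))
  pa_incidence(pa)  # validation only
  pa
}

#' @rdname read_pa_matrix
#' @param pa Presence/absence tibble.
#' @export
write_pa_matrix <- function(pa, path) {
  pa_incidence(pa)
  readr::write_tsv(pa, path)
  invisible(path)
}

#' Read genome contigs from FASTA
#'
#' Sequences are uppercased; non-ACGT letters are kept as-is and treated
#' as ambiguous by downstream statistics.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `contig_id`, `sequence`.
#' @export
read_fasta_contigs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA ids: ", ids[anyDuplicated(ids)][1L]))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) abort("Zero-length FASTA record.")
  tibble(contig_id = ids, sequence = unname(seqs))
}

#' Write contigs to FASTA with 80-column wrapping
#' @param contigs Tibble with `contig_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_contigs <- function(contigs, path) {
  ss <- Biostrings::BStringSet(setNames(contigs$sequence, contigs$contig_id))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a gene table from GFF3
#'
#' Only the columns mappable to gene records are used: feature rows of
#' type `gene` or `CDS` become records with `gene_id` taken from the ID
#' attribute, `product` from the product (or Name) attribute, and `strain`
#' from the `strain` argument.
#'
#' @param path GFF3 file path.
#' @param strain Strain name to assign to every record.
#' @param feature_types GFF types to keep.
#' @return A gene-table tibble.
#' @export
read_gene_table_gff3 <- function(path, strain, feature_types = c("gene", "CDS")) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad) > 0L) abort(sprintf("Malformed GFF3 row at line %d.", bad[1L]))
  f <- as_tibble(do.call(rbind, parts), .name_repair = "minimal")
  names(f) <- c("seqid", "source", "type", "start", "end", "score",
                "strand", "phase", "attributes")
  f <- dplyr::filter(f, .data$type %in% feature_types)
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  g <- tibble(
    gene_id = attr_val(f$attributes, "ID"),
    strain = strain,
    contig = f$seqid,
    start = as.integer(f$start),
    end = as.integer(f$end),
    strand = ifelse(f$strand %in% c("+", "-"), f$strand, "+"),
    product = dplyr::coalesce(attr_val(f$attributes, "product"),
                              attr_val(f$attributes, "Name"), "")
  )
  validate_gene_table(g)
}
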