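#' Filter similarity hits by the standard cutoffs
#'
#' A hit is kept iff its E-value is at most `max_evalue`, its percent
#' identity at least `min_identity`, and its alignment length at least
#' `min_aln_length` columns. Self-hits (query equal to subject) are always
#' removed. Defaults are the cutoffs used throughout the pipeline:
#' E-value 1e-5, identity 50%, length 65.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param max_evalue,min_identity,min_aln_length Positive thresholds.
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_identity = 50,
                        min_aln_length = 65) {
  stopifnot(max_evalue > 0, min_identity > 0, min_aln_length > 0)
  hits |>
    filter(.data$query_id != .data$subject_id,
           .data$evalue <= max_evalue,
           .data$pct_identity >= min_identity,
           .data$aln_length >= min_aln_length)
}

#' Default mobile-genetic-element annotation keywords
#' @export
mge_keywords_default <- c("transposase", "integrase", "insertion sequence",
                          "IS element", "phage", "recombinase", "resolvase")

#' Remove mobile genetic elements by product annotation
#'
#' Mobile genetic elements (transposases, integrases, IS-associated genes,
#' phage genes, ...) are excluded before ortholog clustering so that
#' promiscuous repeated elements do not glue unrelated families together.
#' A gene is removed iff its product annotation contains any keyword as a
#' case-insensitive substring.
#'
#' @param genes Gene tibble.
#' @param keywords Non-empty character vector of keywords.
#' @return A list with `genes` (retained) and `removed` (removal report
#'   with the matching keyword per gene).
#' @export
remove_mobile_genes <- function(genes, keywords = mge_keywords_default) {
  if (length(keywords) == 0L) abort("`keywords` must be non-empty.")
  prod_lc <- tolower(genes$product %||% "")
  hit_kw <- rep(NA_character_, nrow(genes))
  for (kw in keywords) {
    m <- is.na(hit_kw) & grepl(tolower(kw), prod_lc, fixed = TRUE)
    hit_kw[m] <- kw
  }
  removed <- genes |> mutate(matched_keyword = hit_kw) |> filter(!is.na(hit_kw))
  list(genes = genes[is.na(hit_kw), , drop = FALSE], removed = removed)
}

#' Cluster genes into ortholog families by reciprocal best hits
#'
#' Builds the reciprocal-best-hit (RBH) graph over filtered hits: an edge
#' joins genes `a` and `b` iff `b` is `a`'s highest-bit-score hit among
#' hits into `b`'s strain and vice versa (ties broken by lower E-value,
#' then lexicographic gene id). Connected components of this graph become
#' candidate families; components holding several genes from one strain
#' are resolved by keeping, per strain, the gene with the highest summed
#' bit score to the rest of the component and re-clustering the remainder
#' by the same rule. Genes with no RBH edge become singleton clusters.
#'
#' @param hits Filtered hit tibble ([filter_hits()]).
#' @param genes Gene tibble covering every gene id referenced in `hits`.
#' @return A tibble with columns `cluster_id`, `gene_id`, `strain`;
#'   cluster ids are assigned in lexicographic order of each cluster's
#'   smallest member gene id, so results are invariant to hit-row order.
#' @export
cluster_orthologs <- function(hits, genes) {
  genes <- validate_gene_table(genes)
  strain_of <- setNames(genes$strain, genes$gene_id)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), genes$gene_id)
  if (length(unknown) > 0L) {
    abort(paste0("Hit references unknown gene id: ", unknown[1L]))
  }

  h <- hits |>
    mutate(q_strain = unname(strain_of[.data$query_id]),
           s_strain = unname(strain_of[.data$subject_id])) |>
    filter(.data$q_strain != .data$s_strain)

  edges <- if (nrow(h) > 0L) {
    best <- h |>
      arrange(desc(.data$bit_score), .data$evalue, .data$subject_id) |>
      dplyr::distinct(.data$query_id, .data$s_strain, .keep_all = TRUE) |>
      select("query_id", "subject_id")
    # an RBH edge requires both directed best-hit relations
    dplyr::inner_join(
      best,
      best |> dplyr::rename(query_id = "subject_id", subject_id = "query_id"),
      by = c("query_id", "subject_id")
    ) |>
      filter(.data$query_id < .data$subject_id)
  } else {
    tibble(query_id = character(), subject_id = character())
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes$gene_id)
  comp <- igraph::components(g)$membership
  members_by_comp <- split(names(comp), comp)

  # directed summed bit score lookup for strain-conflict arbitration
  pair_score <- h |>
    group_by(.data$query_id, .data$subject_id) |>
    summarise(score = max(.data$bit_score), .groups = "drop")
  score_env <- new.env(parent = emptyenv(), size = nrow(pair_score) * 2L)
  if (nrow(pair_score) > 0L) {
    keys <- paste0(pair_score$query_id, "\r", pair_score$subject_id)
    for (i in seq_along(keys)) assign(keys[i], pair_score$score[i], envir = score_env)
  }
  get_score <- function(a, b) {
    v <- mget(paste0(a, "\r", b), envir = score_env, ifnotfound = 0)
    unlist(v, use.names = FALSE)
  }
  adj <- split(c(edges$subject_id, edges$query_id),
               c(edges$query_id, edges$subject_id))

  resolve <- function(members) {
    st <- unname(strain_of[members])
    if (!anyDuplicated(st)) return(list(members))
    # per gene: summed bit score towards the other members
    summed <- vapply(members, function(gid) {
      others <- setdiff(members, gid)
      sum(get_score(gid, others))
    }, numeric(1))
    ord <- order(st, -summed, members)
    keep <- members[ord][!duplicated(st[ord])]
    rest <- setdiff(members, keep)
    out <- list(sort(keep))
    if (length(rest) > 0L) {
      sub_edges <- lapply(rest, function(gid) {
        nb <- intersect(adj[[gid]] %||% character(), rest)
        if (length(nb) > 0L) cbind(gid, nb)
      })
      sub_edges <- do.call(rbind, Filter(Negate(is.null), sub_edges))
      gs <- igraph::graph_from_data_frame(
        if (is.null(sub_edges)) data.frame(from = character(), to = character())
        else as.data.frame(sub_edges),
        directed = FALSE, vertices = rest
      )
      sub_comp <- igraph::components(gs)$membership
      for (mem in split(names(sub_comp), sub_comp)) {
        out <- c(out, resolve(mem))
      }
    }
    out
  }

  clusters <- unlist(lapply(members_by_comp, resolve), recursive = FALSE)
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1L))]
  tibble(
    cluster_id = rep(sprintf("fam_%05d", seq_along(clusters)),
                     lengths(clusters)),
    gene_id = unlist(clusters, use.names = FALSE)
  ) |>
    mutate(strain = unname(strain_of[.data$gene_id]))
}

#' Build a presence/absence matrix from ortholog clusters
#'
#' @param clusters Cluster tibble from [cluster_orthologs()].
#' @param strains Optional character vector fixing strain order; defaults
#'   to the sorted strains present in `clusters`.
#' @return A presence/absence tibble (`family_id` + one 0/1 column per
#'   strain).
#' @export
build_presence_absence <- function(clusters, strains = NULL) {
  if (is.null(strains)) strains <- sort(unique(clusters$strain))
  missing_strains <- setdiff(clusters$strain, strains)
  if (length(missing_strains) > 0L) {
    abort(paste0("`strains` does not cover: ",
                 paste(missing_strains, collapse = ", ")))
  }
  fam <- sort(unique(clusters$cluster_id))
  inc <- matrix(0L, nrow = length(fam), ncol = length(strains),
                dimnames = list(fam, strains))
  inc[cbind(clusters$cluster_id, clusters$strain)] <- 1L
  tibble::as_tibble(as.data.frame(inc), rownames = "family_id")
}

#' Write ortholog clusters as TSV
#' @param clusters Cluster tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(clusters[c("cluster_id", "strain", "gene_id")], path)
  invisible(path)
}
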