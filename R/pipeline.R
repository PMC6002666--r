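#' Run the full pan-genome analysis pipeline
#'
#' Orchestrates the end-to-end analysis: mobile-element removal, hit
#' filtering, ortholog clustering, presence/absence matrix construction,
#' combinatorial rarefaction, median curves with normality diagnostics,
#' core/dispensable/strain-specific partition, exponential-decay and
#' Heaps power-law fits, and the open/closed verdict. Supply either a
#' hit table plus gene table, or a precomputed presence/absence matrix.
#' Inputs may be tibbles or file paths (read with [read_hit_table()],
#' [read_gene_table()], [read_pa_matrix()]).
#'
#' @param hits Hit tibble or path to a 12-column tabular hit file.
#' @param genes Gene tibble or path to a gene-table TSV.
#' @param pa Presence/absence tibble or path to its TSV; overrides
#'   `hits`/`genes` when supplied.
#' @param max_evalue,min_identity,min_aln_length Hit-filtering cutoffs
#'   (defaults 1e-5, 50, 65).
#' @param mge_keywords Product keywords for mobile-element removal.
#' @param max_observations Exhaustive-enumeration cap per rarefaction
#'   point (see [enumerate_observations()]).
#' @param seed Integer seed for any sampled enumeration.
#' @param core_start_n,new_start_n First `n` fitted by the core decay
#'   (default 1) and the new-gene decay / power law (default 2).
#' @param output_dir Optional directory; when given, the report bundle
#'   is written there via [write_pangenome_report()].
#' @return A `pangenome_run` list with elements `pa`, `clusters`,
#'   `mge_removed`, `partition`, `totals`, `observations`, `curve`,
#'   `fit_core`, `fit_new`, `fit_heaps`, `verdict`, `config`.
#' @export
run_pangenome_pipeline <- function(hits = NULL, genes = NULL, pa = NULL,
                                   max_evalue = 1e-5, min_identity = 50,
                                   min_aln_length = 65,
                                   mge_keywords = mge_keywords_default,
                                   max_observations = 200000L, seed = 1L,
                                   core_start_n = 1L, new_start_n = 2L,
                                   output_dir = NULL) {
  config <- list(
    max_evalue = max_evalue, min_identity = min_identity,
    min_aln_length = min_aln_length, mge_keywords = mge_keywords,
    max_observations = max_observations, seed = as.integer(seed),
    core_start_n = core_start_n, new_start_n = new_start_n
  )
  clusters <- NULL
  mge_removed <- NULL
  if (is.null(pa)) {
    if (is.null(hits) || is.null(genes)) {
      abort("Supply either `pa` or both `hits` and `genes`.")
    }
    if (is.character(hits)) hits <- read_hit_table(hits)
    if (is.character(genes)) genes <- read_gene_table(genes)
    genes <- validate_gene_table(genes)
    mge <- remove_mobile_genes(genes, mge_keywords)
    mge_removed <- mge$removed
    kept_genes <- mge$genes
    kept_hits <- filter_hits(hits, max_evalue, min_identity, min_aln_length) |>
      filter(.data$query_id %in% kept_genes$gene_id,
             .data$subject_id %in% kept_genes$gene_id)
    clusters <- cluster_orthologs(kept_hits, kept_genes)
    pa <- build_presence_absence(clusters)
  } else if (is.character(pa)) {
    pa <- read_pa_matrix(pa)
  }
  strains <- pa_strains(pa)
  if (length(strains) < 2L) abort("Need at least 2 strains for rarefaction.")

  observations <- pangenome_observations(pa, max_observations = max_observations,
                                         seed = seed)
  curve <- summarize_curve(observations)
  partition <- classify_families(pa)
  totals <- partition_totals(partition)

  fit_core <- fit_core_decay(curve, start_n = core_start_n)
  fit_new <- fit_new_decay(curve, start_n = new_start_n)
  fit_hp <- fit_heaps(curve, start_n = new_start_n)

  run <- structure(
    list(pa = pa, clusters = clusters, mge_removed = mge_removed,
         partition = partition, totals = totals,
         observations = observations, curve = curve,
         fit_core = fit_core, fit_new = fit_new, fit_heaps = fit_hp,
         verdict = fit_hp$verdict, config = config),
    class = "pangenome_run"
  )
  if (!is.null(output_dir)) write_pangenome_report(run, output_dir)
  run
}

#' @export
print.pangenome_run <- function(x, ...) {
  S <- length(pa_strains(x$pa))
  cat("<pangenome_run>", S, "strains,", nrow(x$pa), "gene families\n")
  cat(sprintf("  pan = %d | core = %d | dispensable (incl. specific) = %d\n",
              x$totals$total, x$totals$core, x$totals$dispensable_incl_specific))
  cat(sprintf("  core-genome asymptote Omega = %.0f +/- %.0f\n",
              x$fit_core$asymptote, x$fit_core$se_asymptote))
  cat(sprintf("  new-gene asymptote tg(theta) = %.1f +/- %.1f\n",
              x$fit_new$asymptote, x$fit_new$se_asymptote))
  cat(sprintf("  Heaps alpha = %.2f +/- %.2f -> %s pan-genome\n",
              x$fit_heaps$alpha, x$fit_heaps$se_alpha,
              x$verdict %||% "undetermined"))
  invisible(x)
}

fit_report <- function(fit) {
  if (inherits(fit, "decay_fit")) {
    list(model = fit$model, start_n = fit$start_n,
         epsilon = fit$epsilon, se_epsilon = fit$se_epsilon,
         tau = fit$tau, se_tau = fit$se_tau,
         asymptote_name = fit$asymptote_name,
         asymptote = fit$asymptote, se_asymptote = fit$se_asymptote,
         r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
         converged = fit$converged)
  } else {
    list(model = "heaps", start_n = fit$start_n,
         kappa = fit$kappa, se_kappa = fit$se_kappa,
         alpha = fit$alpha, se_alpha = fit$se_alpha,
         r_squared = fit$r_squared, verdict = fit$verdict,
         low_confidence = fit$low_confidence, converged = fit$converged)
  }
}

#' Write the consolidated report bundle of a pipeline run
#'
#' Writes, under `dir`: the presence/absence matrix
#' (`presence_absence.tsv`), the family partition (`partition.tsv`),
#' median curves (`curves.tsv`), clusters when available
#' (`clusters.tsv`), fit parameters and verdict (`fits.json`), a summary
#' (`summary.json`, including the resolved configuration), and the
#' rarefaction plots (`core_fit.pdf`, `new_fit.pdf`, `heaps_fit.pdf`).
#' Content is deterministic under a fixed seed.
#'
#' @param run A `pangenome_run`.
#' @param dir Output directory (created if missing).
#' @param plots Write the PDF plots (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_pangenome_report <- function(run, dir, plots = TRUE) {
  stopifnot(inherits(run, "pangenome_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pa_matrix(run$pa, file.path(dir, "presence_absence.tsv"))
  write_partition(run$partition, file.path(dir, "partition.tsv"))
  write_curves(run$curve, file.path(dir, "curves.tsv"))
  if (!is.null(run$clusters)) {
    write_clusters(run$clusters, file.path(dir, "clusters.tsv"))
  }
  jsonlite::write_json(
    list(core_decay = fit_report(run$fit_core),
         new_decay = fit_report(run$fit_new),
         heaps = fit_report(run$fit_heaps)),
    file.path(dir, "fits.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    list(
      n_strains = length(pa_strains(run$pa)),
      strains = pa_strains(run$pa),
      totals = as.list(run$totals),
      pan_size = run$totals$total,
      verdict = run$verdict %||% "undetermined",
      n_mge_removed = if (is.null(run$mge_removed)) 0L else nrow(run$mge_removed),
      config = run$config
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (plots) {
    ggplot2::ggsave(file.path(dir, "core_fit.pdf"), autoplot(run$fit_core),
                    width = 6, height = 4)
    ggplot2::ggsave(file.path(dir, "new_fit.pdf"), autoplot(run$fit_new),
                    width = 6, height = 4)
    if (!is.na(run$fit_heaps$alpha)) {
      ggplot2::ggsave(file.path(dir, "heaps_fit.pdf"), autoplot(run$fit_heaps),
                      width = 6, height = 4)
    }
  }
  invisible(dir)
}
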