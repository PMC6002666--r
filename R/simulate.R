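#' Ground-truth description of a simulated pan-genome
#'
#' A pan-genome is simulated from three compartments: a fixed core of
#' `core_size` families present in every strain, a "shell" of `shell_size`
#' accessory families each present in any given strain independently with
#' probability `shell_p`, and a "cloud" of brand-new private families
#' entering each strain as a Poisson draw with mean `cloud_rate`.
#'
#' Under this model the expected number of families shared by all `n`
#' sampled strains is `core_size + shell_size * shell_p^n`, an exponential
#' decay in `n` with rate `-1/log(shell_p)` towards the asymptote
#' `core_size`; the expected number of new families contributed by an
#' `n`-th strain tends to `cloud_rate` as `n` grows. Both expectations lie
#' inside the model families fitted by [fit_core_decay()] and
#' [fit_new_decay()], so simulated matrices carry analytically known truth
#' for every downstream stage.
#'
#' @param n_strains Number of strains (>= 2).
#' @param core_size Number of universally shared families (>= 0).
#' @param shell_size Number of accessory shell families (>= 0).
#' @param shell_p Per-strain presence probability of a shell family,
#'   strictly inside (0, 1).
#' @param cloud_rate Expected number of private singleton families per
#'   strain (>= 0).
#' @param seed Integer seed; identical truth objects (seed included)
#'   regenerate bit-identical matrices.
#' @return An object of class `sim_truth`.
#' @export
#' @examples
#' truth <- sim_truth(n_strains = 5, core_size = 100, shell_size = 50,
#'                    shell_p = 0.6, cloud_rate = 4, seed = 1)
#' pa <- simulate_pangenome_matrix(truth)
sim_truth <- function(n_strains, core_size, shell_size = 0L, shell_p = 0.5,
                      cloud_rate = 0, seed = 1L) {
  n_strains <- check_count(n_strains, "n_strains", min = 2L)
  core_size <- check_count(core_size, "core_size")
  shell_size <- check_count(shell_size, "shell_size")
  if (shell_size > 0L) shell_p <- check_prob_open(shell_p, "shell_p")
  if (!is.numeric(cloud_rate) || length(cloud_rate) != 1L || cloud_rate < 0) {
    abort("`cloud_rate` must be a single number >= 0.")
  }
  structure(
    list(n_strains = n_strains, core_size = core_size,
         shell_size = shell_size, shell_p = as.numeric(shell_p),
         cloud_rate = as.numeric(cloud_rate), seed = as.integer(seed)),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> S =", x$n_strains,
      "| core =", x$core_size,
      "| shell =", x$shell_size, "(p =", x$shell_p, ")",
      "| cloud rate =", x$cloud_rate,
      "| seed =", x$seed, "\n")
  invisible(x)
}

#' Expected shared-family count under a simulation truth
#'
#' Analytic expectation of the number of families present in all of `n`
#' strains: `core_size + shell_size * shell_p^n`.
#'
#' @param truth A [sim_truth()] object.
#' @param n Vector of strain counts.
#' @return Numeric vector of expectations.
#' @export
expected_core_count <- function(truth, n) {
  stopifnot(inherits(truth, "sim_truth"))
  truth$core_size + truth$shell_size * truth$shell_p^n
}

#' Simulate a presence/absence matrix with known truth
#'
#' Draws a strains-by-families boolean incidence table from the
#' core/shell/cloud model described in [sim_truth()]. Shell families that
#' end up present in zero strains are unobservable and dropped. The truth
#' object is attached as the `sim_truth` attribute.
#'
#' @param truth A [sim_truth()] object.
#' @return A tibble with a `family_id` column and one 0/1 integer column
#'   per strain (`strain_01`, `strain_02`, ...), carrying `truth` in the
#'   `sim_truth` attribute.
#' @export
simulate_pangenome_matrix <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  S <- truth$n_strains
  strains <- sprintf("strain_%02d", seq_len(S))

  core <- if (truth$core_size > 0L) {
    matrix(1L, nrow = truth$core_size, ncol = S,
           dimnames = list(sprintf("core_%05d", seq_len(truth$core_size)), strains))
  }

  shell <- if (truth$shell_size > 0L) {
    m <- with_seed(derive_seed(truth$seed, 1L), {
      matrix(rbinom(truth$shell_size * S, 1L, truth$shell_p),
             nrow = truth$shell_size, ncol = S)
    })
    dimnames(m) <- list(sprintf("shell_%05d", seq_len(truth$shell_size)), strains)
    m[rowSums(m) > 0L, , drop = FALSE]  # unobservable families dropped
  }

  cloud <- {
    k <- with_seed(derive_seed(truth$seed, 2L), rpois(S, truth$cloud_rate))
    if (sum(k) > 0L) {
      m <- matrix(0L, nrow = sum(k), ncol = S)
      ids <- character(sum(k))
      at <- 0L
      for (s in seq_len(S)) {
        if (k[s] > 0L) {
          rows <- at + seq_len(k[s])
          m[rows, s] <- 1L
          ids[rows] <- sprintf("cloud_%s_%04d", strains[s], seq_len(k[s]))
          at <- at + k[s]
        }
      }
      dimnames(m) <- list(ids, strains)
      m
    }
  }

  inc <- do.call(rbind, Filter(Negate(is.null), list(core, shell, cloud)))
  if (is.null(inc)) inc <- matrix(0L, 0L, S, dimnames = list(character(), strains))
  out <- tibble::as_tibble(as.data.frame(inc), rownames = "family_id")
  attr(out, "sim_truth") <- truth
  out
}

#' Simulate an all-vs-all hit table with planted ortholog clusters
#'
#' Emits reciprocal similarity hits for every within-cluster gene pair,
#' all passing the default filtering cutoffs (E-value <= 1e-5, identity
#' >= 50%, alignment length >= 65), together with a gene table covering
#' every planted gene. Optionally adds decoy cross-cluster hits that each
#' fail at least one cutoff, to exercise hit filtering.
#'
#' @param planted_clusters Data frame with columns `cluster_id`, `strain`,
#'   `gene_id`; at most one gene per strain within a cluster, gene ids
#'   globally unique.
#' @param decoy_rate Number of decoy hits emitted per true hit (a rate;
#'   the decoy count is `round(decoy_rate * n_true_hits)`).
#' @param seed Integer seed.
#' @return A list with elements `hits` (12-column hit tibble) and `genes`
#'   (gene-table tibble).
#' @export
simulate_hit_table <- function(planted_clusters, decoy_rate = 0, seed = 1L) {
  pc <- as_tibble(planted_clusters)
  need <- c("cluster_id", "strain", "gene_id")
  if (!all(need %in% names(pc))) {
    abort("`planted_clusters` needs columns cluster_id, strain, gene_id.")
  }
  if (anyDuplicated(pc$gene_id)) abort("Duplicate gene ids in planted clusters.")
  dup <- pc |> dplyr::count(.data$cluster_id, .data$strain) |> dplyr::filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort("A planted cluster holds more than one gene from the same strain.")
  }

  genes <- pc |>
    arrange(.data$strain, .data$cluster_id) |>
    group_by(.data$strain) |>
    mutate(ord = row_number()) |>
    ungroup() |>
    mutate(
      contig = paste0(.data$strain, "_ctg1"),
      start = (.data$ord - 1L) * 1500L + 1L,
      end = (.data$ord - 1L) * 1500L + 1200L,
      strand = "+",
      product = paste0("planted family ", .data$cluster_id, " protein")
    ) |>
    select("gene_id", "strain", "contig", "start", "end", "strand", "product")

  hits <- with_seed(seed, {
    true_hits <- pc |>
      group_by(.data$cluster_id) |>
      summarise(pair = list({
        g <- .data$gene_id
        if (length(g) >= 2L) {
          idx <- utils::combn(length(g), 2L)
          tibble(a = g[idx[1L, ]], b = g[idx[2L, ]])
        } else {
          tibble(a = character(), b = character())
        }
      }), .groups = "drop") |>
      tidyr::unnest("pair")

    mk_hit <- function(q, s, identity, len, evalue, bits) {
      tibble(
        query_id = q, subject_id = s,
        pct_identity = round(identity, 2), aln_length = as.integer(len),
        mismatches = as.integer(round(len * (100 - identity) / 100)),
        gap_opens = 0L,
        q_start = 1L, q_end = as.integer(len),
        s_start = 1L, s_end = as.integer(len),
        evalue = evalue, bit_score = round(bits, 1)
      )
    }

    n_true <- nrow(true_hits)
    out <- list()
    if (n_true > 0L) {
      identity <- runif(n_true, 70, 99)
      len <- sample(100:400, n_true, replace = TRUE)
      evalue <- 10^-runif(n_true, 20, 150)
      bits <- len * identity / 50
      out$fwd <- mk_hit(true_hits$a, true_hits$b, identity, len, evalue, bits)
      out$rev <- mk_hit(true_hits$b, true_hits$a, identity, len, evalue, bits)
    }

    n_decoy <- round(decoy_rate * max(1L, 2L * n_true))
    if (n_decoy > 0L && nrow(pc) >= 2L) {
      qa <- sample(pc$gene_id, n_decoy, replace = TRUE)
      sb <- sample(pc$gene_id, n_decoy, replace = TRUE)
      keep <- qa != sb
      qa <- qa[keep]; sb <- sb[keep]
      mode <- sample(1:3, length(qa), replace = TRUE)
      identity <- ifelse(mode == 2L, runif(length(qa), 10, 49.5), runif(length(qa), 55, 95))
      len <- ifelse(mode == 3L, sample(20:64, length(qa), replace = TRUE),
                    sample(80:300, length(qa), replace = TRUE))
      evalue <- ifelse(mode == 1L, 10^-runif(length(qa), 1, 4.9),
                       10^-runif(length(qa), 6, 40))
      out$decoy <- mk_hit(qa, sb, identity, len, evalue, len * identity / 100)
    }
    bind_rows(out)
  })

  if (nrow(hits) == 0L) {
    hits <- tibble(
      query_id = character(), subject_id = character(),
      pct_identity = numeric(), aln_length = integer(),
      mismatches = integer(), gap_opens = integer(),
      q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(),
      evalue = numeric(), bit_score = numeric()
    )
  }
  list(hits = hits, genes = genes)
}

#' Convenience builder of complete planted clusters
#'
#' @param n_clusters Number of clusters to plant.
#' @param strains Character vector of strain names; every cluster gets one
#'   gene in every strain.
#' @return A tibble suitable for [simulate_hit_table()].
#' @export
plant_clusters <- function(n_clusters, strains) {
  n_clusters <- check_count(n_clusters, "n_clusters")
  if (n_clusters == 0L) {
    return(tibble(cluster_id = character(), strain = character(),
                  gene_id = character()))
  }
  tidyr::expand_grid(
    cluster_id = sprintf("pc_%04d", seq_len(n_clusters)),
    strain = strains
  ) |>
    mutate(gene_id = paste0(.data$strain, "|", .data$cluster_id))
}

#' Simulate FASTA contigs with controlled length and GC
#'
#' Contig lengths are drawn log-uniformly between `min_length` and
#' `max_length`; each base is G or C independently with probability
#' `gc_target / 100` (then split uniformly between the two bases of the
#' pair). With `alternating = TRUE` the deterministic repeating pattern
#' "ACGT" is used instead, which realises exactly 50% GC.
#'
#' @param n_contigs Number of contigs (>= 1).
#' @param min_length,max_length Length bounds in bp (>= 1).
#' @param gc_target Target GC percentage in \[0, 100\].
#' @param seed Integer seed.
#' @param alternating If TRUE, emit the fixed "ACGT" repeat at exactly the
#'   requested lengths (gc_target is ignored and must be 50).
#' @return A tibble with columns `contig_id`, `sequence`.
#' @export
simulate_contigs <- function(n_contigs, min_length = 225L, max_length = 155963L,
                             gc_target = 50, seed = 1L, alternating = FALSE) {
  n_contigs <- check_count(n_contigs, "n_contigs", min = 1L)
  min_length <- check_count(min_length, "min_length", min = 1L)
  max_length <- check_count(max_length, "max_length", min = min_length)
  if (!is.numeric(gc_target) || gc_target < 0 || gc_target > 100) {
    abort("`gc_target` must lie in [0, 100].")
  }
  with_seed(seed, {
    lens <- as.integer(round(exp(runif(n_contigs, log(min_length), log(max_length)))))
    lens <- pmin(pmax(lens, min_length), max_length)
    seqs <- vapply(lens, function(L) {
      if (alternating) {
        paste(rep_len(c("A", "C", "G", "T"), L), collapse = "")
      } else {
        gc <- runif(L) < gc_target / 100
        half <- runif(L) < 0.5
        base <- ifelse(gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
        paste(base, collapse = "")
      }
    }, character(1))
    tibble(contig_id = sprintf("contig_%04d", seq_len(n_contigs)),
           sequence = seqs)
  })
}
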