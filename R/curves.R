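#' Core, new-gene, and pan-genome counts for a strain subset
#'
#' `count_core()` counts families present in every strain of the subset;
#' `count_pan()` counts families present in at least one subset strain;
#' `count_new()` counts families present in `added_strain` but absent
#' from every other subset member, i.e. the growth of the gene pool when
#' `added_strain` joins the remaining `n - 1` strains.
#'
#' @param pa Presence/absence tibble.
#' @param strains Non-empty character vector of strain names.
#' @param added_strain One element of `strains`.
#' @return A single non-negative integer.
#' @export
count_core <- function(pa, strains) {
  m <- subset_incidence(pa, strains)
  sum(rowSums(m) == length(strains))
}

#' @rdname count_core
#' @export
count_pan <- function(pa, strains) {
  if (length(strains) == 0L) return(0L)  # empty pool: pan of no strains
  m <- subset_incidence(pa, strains)
  sum(rowSums(m) > 0L)
}

#' @rdname count_core
#' @export
count_new <- function(pa, strains, added_strain) {
  if (!added_strain %in% strains) {
    abort("`added_strain` must be part of `strains`.")
  }
  m <- subset_incidence(pa, strains)
  sum(m[, added_strain] & rowSums(m) == 1L)
}

subset_incidence <- function(pa, strains) {
  if (length(strains) == 0L) abort("Strain subset must be non-empty.")
  m <- pa_incidence(pa)
  unknown <- setdiff(strains, colnames(m))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown strain: ", unknown[1L]))
  }
  m[, strains, drop = FALSE]
}

#' Enumerate rarefaction observations at a given subset size
#'
#' For `n` of the `S` strains there are `n * choose(S, n)` ordered pairs
#' (subset `T` of size `n`, designated last-added strain `g` in `T`) —
#' equal to `S! / ((n-1)! (S-n)!)`, the number of observations behind
#' each plotted point of the rarefaction curves. Each pair contributes
#' one observation: the core count of `T` (`kind = "core"`; independent
#' of `g`, so each subset contributes `n` identical values), the number
#' of genes `g` adds to the pool of `T` without `g` (`kind = "new"`), or
#' the pan size of `T` (`kind = "pan"`).
#'
#' When the pair count exceeds `max_observations`, a uniform seeded
#' sample of pairs is drawn instead and the result is flagged
#' `exhaustive = FALSE`.
#'
#' @param pa Presence/absence tibble with `S >= 2` strains.
#' @param n Subset size, `1 <= n <= S`.
#' @param kind One of `"core"`, `"new"`, `"pan"`.
#' @param max_observations Exhaustive-enumeration cap (default 200000,
#'   which covers `S <= 12` fully).
#' @param seed Seed for the sampled mode (ignored when exhaustive).
#' @return A tibble with columns `kind`, `n`, `value`, `exhaustive`; the
#'   number of rows is the observation count.
#' @export
enumerate_observations <- function(pa, n, kind = c("core", "new", "pan"),
                                   max_observations = 200000L, seed = 1L) {
  kind <- match.arg(kind)
  m <- pa_incidence(pa)
  storage.mode(m) <- "integer"
  S <- ncol(m)
  n <- check_count(n, "n", min = 1L)
  if (n > S) abort(sprintf("`n` = %d exceeds the number of strains (%d).", n, S))

  n_pairs <- n * choose(S, n)
  if (n_pairs <= max_observations) {
    subsets <- utils::combn(S, n, simplify = FALSE)
    vals <- unlist(lapply(subsets, function(idx) {
      sub <- m[, idx, drop = FALSE]
      rs <- rowSums(sub)
      switch(kind,
        core = rep.int(sum(rs == n), n),
        pan = rep.int(sum(rs > 0L), n),
        new = colSums(sub[rs == 1L, , drop = FALSE])
      )
    }), use.names = FALSE)
    tibble(kind = kind, n = n, value = as.integer(vals), exhaustive = TRUE)
  } else {
    vals <- with_seed(seed, {
      vapply(seq_len(max_observations), function(i) {
        idx <- sample.int(S, n)
        sub <- m[, idx, drop = FALSE]
        rs <- rowSums(sub)
        switch(kind,
          core = sum(rs == n),
          pan = sum(rs > 0L),
          new = {
            gi <- sample.int(n, 1L)
            sum(sub[, gi] == 1L & rs == 1L)
          }
        )
      }, numeric(1))
    })
    out <- tibble(kind = kind, n = n, value = as.integer(vals),
                  exhaustive = FALSE)
    attr(out, "seed") <- as.integer(seed)
    out
  }
}

#' Enumerate rarefaction observations for every subset size
#'
#' @inheritParams enumerate_observations
#' @param kinds Which observation kinds to enumerate.
#' @return A tibble binding [enumerate_observations()] output over all
#'   `n = 1..S` and requested kinds.
#' @export
pangenome_observations <- function(pa, kinds = c("core", "new", "pan"),
                                   max_observations = 200000L, seed = 1L) {
  S <- length(pa_strains(pa))
  purrr::map(kinds, function(k) {
    purrr::map(seq_len(S), function(n) {
      enumerate_observations(pa, n, k, max_observations, seed)
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Shapiro-Wilk normality diagnostic
#'
#' Thin wrapper around the Royston AS R94 implementation in
#' [stats::shapiro.test()] that never throws mid-pipeline: degenerate
#' input (fewer than 3 values, or all values identical) yields `NA`
#' results flagged by `ok = FALSE`. Samples larger than 5000 are reduced
#' to a deterministic subsample of 5000 before testing.
#'
#' @param values Numeric vector.
#' @return A list with elements `W`, `p`, `ok`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) > 5000L) {
    values <- with_seed(derive_seed(length(values), 7L),
                        sample(values, 5000L))
  }
  if (length(values) < 3L || length(unique(values)) == 1L) {
    return(list(W = NA_real_, p = NA_real_, ok = FALSE))
  }
  res <- tryCatch(stats::shapiro.test(values), error = function(e) NULL)
  if (is.null(res)) return(list(W = NA_real_, p = NA_real_, ok = FALSE))
  list(W = unname(res$statistic), p = unname(res$p.value), ok = TRUE)
}

#' Summarise observation multisets into per-n curve points
#'
#' The per-`n` median summarises each observation multiset (the midpoint
#' average of the two central order statistics for even counts), together
#' with the Shapiro-Wilk normality diagnostic. Medians are used
#' unconditionally: rarefaction observation multisets are typically
#' non-normal, and the normality test is reported for inspection only,
#' never to switch the summary statistic.
#'
#' @param observations Observation tibble from
#'   [pangenome_observations()] / [enumerate_observations()].
#' @return A tibble with columns `kind`, `n`, `n_observations`,
#'   `exhaustive`, `median`, `shapiro_W`, `shapiro_p`.
#' @export
summarize_curve <- function(observations) {
  observations |>
    group_by(.data$kind, .data$n) |>
    summarise(
      n_observations = dplyr::n(),
      exhaustive = all(.data$exhaustive),
      median = stats::median(.data$value),
      shapiro_W = shapiro_wilk(.data$value)$W,
      shapiro_p = shapiro_wilk(.data$value)$p,
      .groups = "drop"
    ) |>
    arrange(.data$kind, .data$n)
}

#' Partition gene families into core, dispensable, and strain-specific
#'
#' Core families are present in all `S` strains; strain-specific families
#' in exactly one; dispensable families in between. Because the
#' dispensable genome is often reported inclusive of strain-specific
#' genes, [partition_totals()] reports both groupings.
#'
#' @param pa Presence/absence tibble with `S >= 2` strains.
#' @return A tibble with columns `family_id`, `n_strains_present`,
#'   `class` (one of `"core"`, `"dispensable"`, `"specific"`).
#' @export
classify_families <- function(pa) {
  m <- pa_incidence(pa)
  S <- ncol(m)
  if (S < 2L) abort("Need at least 2 strains to classify families.")
  k <- rowSums(m)
  tibble(
    family_id = rownames(m),
    n_strains_present = as.integer(k),
    class = dplyr::case_when(k == S ~ "core",
                             k == 1L ~ "specific",
                             TRUE ~ "dispensable")
  )
}

#' @rdname classify_families
#' @param partition Output of [classify_families()].
#' @return [partition_totals()]: a one-row tibble of class totals,
#'   including the dispensable count with strain-specific families folded
#'   in (`dispensable_incl_specific`).
#' @export
partition_totals <- function(partition) {
  tibble(
    total = nrow(partition),
    core = sum(partition$class == "core"),
    dispensable = sum(partition$class == "dispensable"),
    specific = sum(partition$class == "specific"),
    dispensable_incl_specific = sum(partition$class != "core")
  )
}

#' Per-strain strain-specific family counts
#'
#' @param pa Presence/absence tibble.
#' @return A tibble with columns `strain`, `n_specific`.
#' @export
strain_specific_counts <- function(pa) {
  m <- pa_incidence(pa)
  single <- rowSums(m) == 1L
  tibble(strain = colnames(m),
         n_specific = as.integer(colSums(m[single, , drop = FALSE])))
}

#' Functional-category profile of core vs dispensable families
#'
#' Joins a user-supplied family-to-category table onto the partition and
#' tallies, per class, the percentage of families in each category.
#' Strain-specific families count towards the dispensable genome.
#' Families without a mapping are reported as `"unassigned"`; percentages
#' sum to 100 within each class (unassigned included).
#'
#' @param partition Output of [classify_families()].
#' @param categories Data frame with columns `family_id`, `category`.
#' @return A tibble with columns `class`, `category`, `n`, `percent`.
#' @export
category_profile <- function(partition, categories) {
  categories <- as_tibble(categories)
  if (!all(c("family_id", "category") %in% names(categories))) {
    abort("`categories` needs columns family_id, category.")
  }
  partition |>
    mutate(class = ifelse(.data$class == "core", "core", "dispensable")) |>
    left_join(categories, by = "family_id") |>
    mutate(category = dplyr::coalesce(.data$category, "unassigned")) |>
    dplyr::count(.data$class, .data$category, name = "n") |>
    group_by(.data$class) |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' Write curve points / family partition as TSV
#' @param curve Curve tibble from [summarize_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curve, path) {
  readr::write_tsv(dplyr::rename(curve, curve_kind = "kind"), path)
  invisible(path)
}

#' @rdname write_curves
#' @param partition Partition tibble from [classify_families()].
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(partition[c("family_id", "class", "n_strains_present")], path)
  invisible(path)
}
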