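make_hit <- function(q, s, identity = 90, len = 200, evalue = 1e-30,
                     bits = 300) {
  tibble::tibble(
    query_id = q, subject_id = s, pct_identity = identity,
    aln_length = as.integer(len), mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = as.integer(len), s_start = 1L,
    s_end = as.integer(len), evalue = evalue, bit_score = bits
  )
}

test_that("filtering applies the three cutoffs jointly and drops self-hits", {
  hits <- dplyr::bind_rows(
    make_hit("a", "b"),                                  # passes
    make_hit("a", "c", evalue = 1e-4),                   # E too weak
    make_hit("a", "d", identity = 49.9),                 # identity too low
    make_hit("a", "e", len = 64),                        # too short
    make_hit("a", "a")                                   # self-hit
  )
  kept <- filter_hits(hits)
  expect_equal(kept$subject_id, "b")
  expect_equal(nrow(filter_hits(hits[0, ])), 0L)
})

test_that("filtering equals a brute-force triple-threshold scan on random hits", {
  set.seed(31)
  n <- 1000L
  hits <- make_hit(
    q = sprintf("g%03d", sample(200, n, TRUE)),
    s = sprintf("g%03d", sample(200, n, TRUE)),
    identity = runif(n, 0, 100),
    len = sample(1:300, n, TRUE),
    evalue = 10^-runif(n, 0, 10),
    bits = runif(n, 20, 500)
  )
  kept <- filter_hits(hits)
  manual <- logical(n)
  for (i in seq_len(n)) {
    manual[i] <- hits$query_id[i] != hits$subject_id[i] &&
      hits$evalue[i] <= 1e-5 && hits$pct_identity[i] >= 50 &&
      hits$aln_length[i] >= 65
  }
  expect_equal(as.data.frame(kept), as.data.frame(hits[manual, ]))
})

test_that("filtering is monotone: raising any threshold never adds hits", {
  set.seed(32)
  n <- 400L
  hits <- make_hit(
    q = sprintf("g%03d", sample(100, n, TRUE)),
    s = sprintf("g%03d", sample(100, n, TRUE)),
    identity = runif(n, 0, 100), len = sample(1:300, n, TRUE),
    evalue = 10^-runif(n, 0, 10)
  )
  base <- filter_hits(hits)
  for (args in list(list(max_evalue = 1e-7), list(min_identity = 70),
                    list(min_aln_length = 150))) {
    stricter <- do.call(filter_hits, c(list(hits), args))
    expect_true(all(paste(stricter$query_id, stricter$subject_id,
                          stricter$evalue) %in%
                    paste(base$query_id, base$subject_id, base$evalue)))
  }
})

test_that("mobile-element removal matches a brute-force substring scan", {
  products <- c("IS4 family transposase", "sulfide quinone oxidoreductase",
                "phage tail protein", "site-specific Integrase",
                "ATP synthase", "IS element orfB", "tyrosine recombinase XerC",
                "resolvase domain protein", "Insertion Sequence protein")
  set.seed(33)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:50), strain = "A", contig = "c",
    start = 1L, end = 10L, strand = "+",
    product = sample(products, 50, TRUE)
  )
  res <- remove_mobile_genes(genes)
  manual <- vapply(genes$product, function(p) {
    any(vapply(mge_keywords_default, function(kw) {
      grepl(tolower(kw), tolower(p), fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  expect_equal(res$removed$gene_id, genes$gene_id[manual])
  expect_equal(res$genes$gene_id, genes$gene_id[!manual])
  expect_equal(nrow(res$removed) + nrow(res$genes), 50L)
})

test_that("one mutual-RBH gene per strain forms a single cluster", {
  strains <- c("A", "B", "C", "D")
  genes <- tibble::tibble(
    gene_id = paste0("g", strains), strain = strains, contig = "c",
    start = 1L, end = 10L, strand = "+", product = "x"
  )
  pairs <- t(utils::combn(genes$gene_id, 2))
  hits <- dplyr::bind_rows(
    make_hit(pairs[, 1], pairs[, 2]),
    make_hit(pairs[, 2], pairs[, 1])
  )
  cl <- cluster_orthologs(hits, genes)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(sort(cl$gene_id), sort(genes$gene_id))
})

test_that("planted clusters are recovered exactly on decoy-free fixtures", {
  for (seed in c(1, 2, 3)) {
    pcs <- plant_clusters(20, sprintf("s%02d", 1:4))
    sim <- simulate_hit_table(pcs, decoy_rate = 0, seed = seed)
    cl <- cluster_orthologs(filter_hits(sim$hits), sim$genes)
    got <- split(cl$gene_id, cl$cluster_id)
    want <- split(pcs$gene_id, pcs$cluster_id)
    expect_equal(length(got), 20L)
    expect_setequal(
      unname(vapply(got, function(g) paste(sort(g), collapse = "|"), character(1))),
      unname(vapply(want, function(g) paste(sort(g), collapse = "|"), character(1)))
    )
  }
})

test_that("decoy hits are removed and do not disturb planted recovery", {
  pcs <- plant_clusters(12, sprintf("s%02d", 1:5))
  sim <- simulate_hit_table(pcs, decoy_rate = 1, seed = 9)
  cl <- cluster_orthologs(filter_hits(sim$hits), sim$genes)
  expect_equal(length(unique(cl$cluster_id)), 12L)
  expect_true(all(table(cl$cluster_id) == 5L))
})

test_that("clustering is invariant to hit-table row order", {
  pcs <- plant_clusters(15, sprintf("s%02d", 1:4))
  sim <- simulate_hit_table(pcs, decoy_rate = 0.5, seed = 13)
  hits <- filter_hits(sim$hits)
  cl1 <- cluster_orthologs(hits, sim$genes)
  set.seed(99)
  cl2 <- cluster_orthologs(hits[sample(nrow(hits)), ], sim$genes)
  expect_identical(cl1, cl2)
})

test_that("a within-strain paralog pair is resolved by max summed bit score", {
  # component: A has a1 (strong) and a2 (weak paralog), B has b1, C has c1.
  genes <- tibble::tibble(
    gene_id = c("a1", "a2", "b1", "c1"),
    strain = c("A", "A", "B", "C"), contig = "c",
    start = 1L, end = 10L, strand = "+", product = "x"
  )
  hits <- dplyr::bind_rows(
    make_hit("a1", "b1", bits = 400), make_hit("b1", "a1", bits = 400),
    make_hit("a1", "c1", bits = 350), make_hit("c1", "a1", bits = 350),
    # a2 is b1's best hit into A? no - keep a1 best; a2 reaches c1 reciprocally
    make_hit("a2", "c1", bits = 300), make_hit("c1", "a2", bits = 300)
  )
  # RBH edges: a1-b1 (mutual best), a1-c1? c1's best into A is a1 (350 > 300),
  # a1's best into C is c1 -> edge. a2-c1 not reciprocal. So component {a1,b1,c1}
  # plus singleton a2.
  cl <- cluster_orthologs(hits, genes)
  got <- split(cl$gene_id, cl$cluster_id)
  sizes <- sort(vapply(got, length, integer(1)))
  expect_equal(unname(sizes), c(1L, 3L))
  big <- got[[which.max(lengths(got))]]
  expect_setequal(big, c("a1", "b1", "c1"))
  # brute-force check of the arbitration rule on a forced conflict:
  # make a2 also reciprocal with b1 so the component holds both paralogs
  hits2 <- dplyr::bind_rows(hits,
    make_hit("a2", "b1", bits = 500), make_hit("b1", "a2", bits = 500))
  # now b1's best into A is a2 (500); a1-b1 edge dissolves, a1-c1 remains,
  # c1's best is still a1, so component is {a1, c1} + {a2, b1}
  cl2 <- cluster_orthologs(hits2, genes)
  got2 <- split(cl2$gene_id, cl2$cluster_id)
  expect_setequal(
    unname(vapply(got2, function(g) paste(sort(g), collapse = "|"), character(1))),
    c("a1|c1", "a2|b1")
  )
})

test_that("strain conflicts inside one component are split, conserving genes", {
  # component {a1, a2, b1, c1} carries strain A twice: a1-b1, a2-c1 and
  # b1-c1 are all reciprocal best hits
  genes <- tibble::tibble(
    gene_id = c("a1", "a2", "b1", "c1"),
    strain = c("A", "A", "B", "C"), contig = "c",
    start = 1L, end = 10L, strand = "+", product = "x"
  )
  hits <- dplyr::bind_rows(
    make_hit("a1", "b1", bits = 400), make_hit("b1", "a1", bits = 400),
    make_hit("a2", "c1", bits = 450), make_hit("c1", "a2", bits = 450),
    make_hit("b1", "c1", bits = 350), make_hit("c1", "b1", bits = 350)
  )
  cl <- cluster_orthologs(hits, genes)
  # all genes appear exactly once
  expect_setequal(cl$gene_id, genes$gene_id)
  expect_equal(anyDuplicated(cl$gene_id), 0L)
  # no cluster carries two genes of one strain
  per <- dplyr::count(cl, cluster_id, strain)
  expect_true(all(per$n == 1L))
  # exhaustive arbitration oracle: keep the A paralog with the larger
  # summed bit score to the rest of the component (a2: 450 > a1: 400)
  got <- split(cl$gene_id, cl$cluster_id)
  expect_setequal(
    unname(vapply(got, function(g) paste(sort(g), collapse = "|"), character(1))),
    c("a2|b1|c1", "a1")
  )
})

test_that("hits referencing unknown genes are an error", {
  genes <- tiny_genes()
  expect_error(cluster_orthologs(make_hit("g1", "nope"), genes),
               "unknown gene id")
})

test_that("presence/absence construction conserves cluster sizes", {
  pcs <- plant_clusters(20, sprintf("s%02d", 1:4))
  sim <- simulate_hit_table(pcs, decoy_rate = 0, seed = 21)
  cl <- cluster_orthologs(filter_hits(sim$hits), sim$genes)
  pa <- build_presence_absence(cl)
  m <- as.matrix(pa[-1])
  expect_equal(dim(m), c(20L, 4L))
  expect_true(all(m == 1L))
  # singleton-only input gives an identity pattern
  singles <- tibble::tibble(cluster_id = sprintf("c%d", 1:3),
                            gene_id = sprintf("g%d", 1:3),
                            strain = c("A", "B", "C"))
  pa2 <- build_presence_absence(singles)
  expect_equal(unname(rowSums(as.matrix(pa2[-1]))), rep(1, 3))
  # row sums equal cluster sizes on a random fixture
  set.seed(22)
  rand <- pcs[sample(nrow(pcs), 50), ]
  pa3 <- build_presence_absence(rand)
  sizes <- table(rand$cluster_id)
  expect_equal(unname(rowSums(as.matrix(pa3[-1]))[order(pa3$family_id)]),
               unname(as.numeric(sizes[sort(names(sizes))])))
})
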