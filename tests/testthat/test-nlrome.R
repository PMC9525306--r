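mk_genes <- function(is_nlr, strand = NULL, orthogroup = NULL,
                     accession = "A", chrom = "chr1") {
  n <- length(is_nlr)
  start <- seq(1000, by = 5000, length.out = n)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)), accession_id = accession,
    chrom = chrom, start = start, end = start + 2000,
    strand = strand %||% rep("+", n), is_nlr = is_nlr,
    orthogroup_id = orthogroup %||% sprintf("OG%02d", seq_len(n)))
}

test_that("approaching rule yields pairs, singletons and clusters", {
  # one intervening non-NLR -> pair
  pair <- classify_nlr_arrangement(mk_genes(c(TRUE, FALSE, TRUE)))
  expect_equal(sort(pair$category), c("pair", "pair"))
  expect_equal(dplyr::n_distinct(pair$group_id), 1L)

  # two intervening non-NLRs -> two singletons
  single <- classify_nlr_arrangement(mk_genes(c(TRUE, FALSE, FALSE, TRUE)))
  expect_equal(sort(single$category), c("singleton", "singleton"))

  # chained approaching -> cluster of three
  clus <- classify_nlr_arrangement(mk_genes(c(TRUE, TRUE, FALSE, TRUE)))
  expect_equal(unique(clus$category), "cluster")
  expect_equal(unique(clus$group_size), 3L)
})

test_that("classifier equals the brute-force oracle on random chromosomes", {
  set.seed(77)
  for (i in 1:200) {
    g <- random_chromosome_genes(n_genes = 60, p_nlr = runif(1, 0.05, 0.4))
    got <- classify_nlr_arrangement(g)
    want <- oracle_nlr_arrangement(g)
    got <- got[match(want$gene_id, got$gene_id), ]
    expect_identical(got$category, want$category)
    # identical partition, not just identical sizes
    expect_equal(dplyr::n_distinct(paste(got$group_id, want$component)),
                 dplyr::n_distinct(want$component))
    expect_equal(dplyr::n_distinct(got$group_id),
                 dplyr::n_distinct(want$component))
  }
})

test_that("pair orientation follows strand geometry and ignores input order", {
  a_plus <- list(start = 100, strand = "+")
  b_plus <- list(start = 900, strand = "+")
  a_minus <- list(start = 100, strand = "-")
  b_minus <- list(start = 900, strand = "-")
  expect_equal(pair_orientation(a_plus, b_plus), "T-H")
  expect_equal(pair_orientation(a_minus, b_minus), "T-H")
  expect_equal(pair_orientation(a_minus, b_plus), "H-H")
  expect_equal(pair_orientation(a_plus, b_minus), "T-T")
  # swap-invariance
  expect_equal(pair_orientation(b_plus, a_minus), "H-H")
  expect_error(pair_orientation(list(start = 1, strand = NA),
                                list(start = 2, strand = "+")),
               "strand")
})

test_that("orientation and homogeneity are attached to classified pairs", {
  g <- mk_genes(c(TRUE, TRUE), strand = c("-", "+"),
                orthogroup = c("OG1", "OG1"))
  out <- classify_nlr_arrangement(g)
  expect_equal(unique(out$orientation), "H-H")
  expect_equal(unique(out$homogeneity), "homogeneous")

  het <- classify_nlr_arrangement(mk_genes(c(TRUE, TRUE, TRUE),
                                           orthogroup = c("OG1", "OG1", "OG2")))
  expect_equal(unique(het$homogeneity), "heterogeneous")
  expect_equal(unique(het$strand_pattern), "+++")
})

test_that("group homogeneity requires orthogroup ids and flags any mismatch", {
  g <- tibble::tibble(gene_id = c("a", "b"), orthogroup_id = c("OG1", NA),
                      group_id = "grp")
  expect_error(group_homogeneity(g), "without an orthogroup id")
  ok <- tibble::tibble(orthogroup_id = c("OG1", "OG1", "OG2"),
                       group_id = "grp")
  expect_equal(group_homogeneity(ok)$homogeneity, "heterogeneous")
})

test_that("identical start coordinates are tie-broken with a warning", {
  g <- mk_genes(c(TRUE, TRUE))
  g$start[2] <- g$start[1]
  g$end[2] <- g$end[1] + 10
  expect_warning(out <- classify_nlr_arrangement(g), "share a start")
  expect_equal(sort(out$category), c("pair", "pair"))
})

test_that("core NLR summary classifies within the named subpopulation", {
  presence <- matrix(FALSE, 2, 10,
                     dimnames = list(c("nlrA", "nlrB"), sprintf("a%02d", 1:10)))
  presence["nlrA", ] <- TRUE                 # in all
  presence["nlrB", 1:5] <- TRUE              # only in subpop P
  subpop <- setNames(rep(c("P", "Q"), each = 5), sprintf("a%02d", 1:10))
  pav <- pav_matrix(presence, subpop)
  s <- core_nlr_summary(pav, c("nlrA", "nlrB"), subpop = "P")
  expect_equal(s$n_core, 2L)
  expect_equal(s$frac_core + s$frac_dispensable, 1)
  sq <- core_nlr_summary(pav, c("nlrA", "nlrB"), subpop = "Q")
  expect_equal(sq$n_nlr, 1L)                 # nlrB absent from Q entirely
  # 94% presence is dispensable
  p94 <- matrix(FALSE, 1, 50, dimnames = list("n1", sprintf("b%02d", 1:50)))
  p94[1, 1:47] <- TRUE
  s94 <- core_nlr_summary(pav_matrix(p94), "n1")
  expect_equal(s94$n_dispensable, 1L)
  expect_error(core_nlr_summary(pav, "nlrA", subpop = "nope"), "unknown")
  empty <- core_nlr_summary(pav, character(0))
  expect_equal(empty$n_nlr, 0L)
})

test_that("domain enrichment calibrates on null and separated counts", {
  acc <- sprintf("a%02d", 1:40)
  subpop <- setNames(rep(c("P", "Q"), each = 20), acc)
  # identical distributions -> adjusted p near 1
  null_counts <- tibble::tibble(accession_id = rep(acc, 2),
                                domain = rep(c("d1", "d2"), each = 40),
                                count = rep(5L, 80))
  res <- domain_enrichment(null_counts, subpop)
  expect_true(all(res$adj_p > 0.5))

  # complete separation -> small adjusted p
  sep <- tibble::tibble(accession_id = acc, domain = "d1",
                        count = rep(c(10L, 0L), each = 20))
  res2 <- domain_enrichment(sep, subpop)
  expect_true(all(res2$adj_p < 0.01))

  # single domain, single eligible subpop: adjusted equals raw
  one <- domain_enrichment(sep, setNames(rep("P", 40), acc))
  expect_true(all(is.na(one$p_value)) || all(one$adj_p == one$p_value))

  small <- setNames(c("P", rep("Q", 39)), acc)
  expect_warning(domain_enrichment(sep, small), "skipped")
})
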