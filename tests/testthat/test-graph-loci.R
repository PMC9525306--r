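# bubbles for three accessions sharing a pan backbone; contig coordinates are
# shifted per accession so the pan projection does the aligning
planted_bubbles <- function() {
  pan <- tibble::tibble(
    bubble_id = c("b1", "b2", "b3"),
    pan_chrom = "chr1",
    pan_start = c(1000, 50000, 90000),
    pan_end = c(2000, 52000, 91000))
  purrr::map_dfr(1:3, function(i) {
    dplyr::mutate(pan, accession_id = paste0("acc", i),
                  contig = paste0("ctg", i),
                  contig_start = pan_start + i * 1e6,
                  contig_end = pan_end + i * 1e6,
                  strand = "+")
  })
}

feature_at <- function(acc, id, bubble_start, category = "singleton",
                       width = 500) {
  i <- as.integer(sub("acc", "", acc))
  tibble::tibble(accession_id = acc, feature_id = id, category = category,
                 contig = paste0("ctg", i),
                 start = bubble_start + i * 1e6 + 100,
                 end = bubble_start + i * 1e6 + 100 + width)
}

test_that("feature-bubble overlap reports intersections and unplaced features", {
  bub <- planted_bubbles()
  feats <- dplyr::bind_rows(
    feature_at("acc1", "f1", 1000),
    feature_at("acc2", "f2", 1000),
    # spans two bubbles: b2 and b3 on acc1 coordinates
    tibble::tibble(accession_id = "acc1", feature_id = "wide",
                   category = "cluster", contig = "ctg1",
                   start = 1e6 + 51000, end = 1e6 + 90500),
    tibble::tibble(accession_id = "acc1", feature_id = "lost",
                   category = "singleton", contig = "ctgX",
                   start = 10, end = 20))
  ov <- overlap_features_with_bubbles(feats, bub)
  expect_equal(nrow(ov$table[ov$table$feature_id == "wide", ]), 2L)
  expect_equal(ov$unplaced$feature_id, "lost")
  expect_match(ov$unplaced$reason, "contig")
  expect_equal(
    ov$table$bubble_id[ov$table$feature_id == "f1"], "b1")
})

test_that("uncalled bubbles are interpolated between collinear flanks", {
  bub <- planted_bubbles()
  # make acc2's middle bubble uncalled
  bub$pan_start[bub$accession_id == "acc2" & bub$bubble_id == "b2"] <- NA
  bub$pan_end[bub$accession_id == "acc2" & bub$bubble_id == "b2"] <- NA
  # inconsistent coordinates across accessions must be rejected
  expect_error(overlap_features_with_bubbles(
    feature_at("acc2", "f", 50000),
    dplyr::mutate(bub, pan_start = ifelse(
      accession_id == "acc3" & bubble_id == "b1", 999, pan_start))),
    "inconsistent pan coordinates")
  ov <- overlap_features_with_bubbles(feature_at("acc2", "f", 50000), bub)
  expect_equal(nrow(ov$table), 1L)
  # interpolated position lies strictly between the flanking bubbles
  expect_gt(ov$table$pan_start, 2000)
  expect_lt(ov$table$pan_end, 90000)
})

test_that("locus inference recovers planted groups with tie-break and exclusion", {
  bub <- planted_bubbles()
  feats <- dplyr::bind_rows(
    # planted locus 1: all three accessions in bubble b1
    feature_at("acc1", "x1", 1000), feature_at("acc2", "x2", 1000),
    feature_at("acc3", "x3", 1000),
    # planted locus 2: two accessions in bubble b2, PLUS a second singleton of
    # acc1 in the same bubble that must be displaced 1 bp away
    feature_at("acc1", "y1", 50000), feature_at("acc2", "y2", 50000),
    feature_at("acc1", "y9", 50000),
    # single-member locus in b3: excluded
    feature_at("acc3", "z1", 90000))
  ov <- overlap_features_with_bubbles(feats, bub)
  loci <- infer_loci(ov$table)

  by_locus <- split(loci$members$feature_id, loci$members$locus_id)
  expect_true(any(vapply(by_locus, function(m)
    setequal(m, c("x1", "x2", "x3")), logical(1))))
  expect_true(any(vapply(by_locus, function(m)
    setequal(m, c("y1", "y2")), logical(1))))
  # displaced singleton: kept = lexicographically smaller id; y9 moved 1 bp
  disp <- loci$excluded[loci$excluded$feature_id == "y9", ]
  expect_equal(nrow(disp), 1L)
  expect_equal(disp$pan_start, 52001)
  expect_equal(disp$pan_start, disp$pan_end)
  # z1's single-member locus is excluded
  expect_true("z1" %in% loci$excluded$feature_id)
  expect_false("z1" %in% loci$members$feature_id)
  # every feature lands in exactly one of members / excluded / unplaced
  all_ids <- c(loci$members$feature_id, loci$excluded$feature_id,
               ov$unplaced$feature_id)
  expect_setequal(all_ids, feats$feature_id)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("displaced singletons from different accessions co-locate", {
  bub <- planted_bubbles()
  feats <- dplyr::bind_rows(
    feature_at("acc1", "a1", 50000), feature_at("acc1", "a2", 50000),
    feature_at("acc2", "b1", 50000), feature_at("acc2", "b2", 50000))
  loci <- infer_loci(overlap_features_with_bubbles(feats, bub)$table)
  by_locus <- split(loci$members$feature_id, loci$members$locus_id)
  expect_true(any(vapply(by_locus, function(m)
    setequal(m, c("a1", "b1")), logical(1))))
  expect_true(any(vapply(by_locus, function(m)
    setequal(m, c("a2", "b2")), logical(1))))
})

test_that("locus inference is row-order invariant", {
  bub <- planted_bubbles()
  feats <- dplyr::bind_rows(
    feature_at("acc1", "x1", 1000), feature_at("acc2", "x2", 1000),
    feature_at("acc1", "y1", 50000), feature_at("acc2", "y2", 50000))
  t1 <- overlap_features_with_bubbles(feats, bub)$table
  set.seed(1)
  t2 <- t1[sample.int(nrow(t1)), ]
  l1 <- infer_loci(t1)
  l2 <- infer_loci(t2)
  norm <- function(l) dplyr::arrange(l$members, feature_id)[
    c("feature_id", "locus_id")]
  expect_identical(norm(l1), norm(l2))
})

test_that("per-subpopulation copy number counts absent accessions as zero", {
  bub <- planted_bubbles()
  feats <- dplyr::bind_rows(
    # acc1 carries two cluster features at the locus (the singleton 1 bp
    # tie-break does not apply to clusters)
    feature_at("acc1", "m1", 1000, category = "cluster"),
    feature_at("acc1", "m2", 1000, category = "cluster"),
    feature_at("acc2", "m3", 1000), feature_at("acc3", "m4", 1000))
  loci <- infer_loci(overlap_features_with_bubbles(feats, bub)$table)
  subpop <- c(acc1 = "P", acc2 = "P", acc3 = "Q", acc4 = "Q")
  cn <- locus_copy_number(loci, subpop)
  expect_equal(cn$mean_members[cn$subpop == "P"], (2 + 1) / 2)
  expect_equal(cn$mean_members[cn$subpop == "Q"], (1 + 0) / 2)
})
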