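test_that("the five SV filter rules match manual enumeration at boundaries", {
  v <- boundary_variants()
  svs <- make_sv_set(v, boundary_genotypes(v))
  gaps <- tibble::tibble(chrom = "chr1", start = 94000, end = 96000)  # half-open
  fl <- suppressWarnings(filter_svs(svs, reference_gaps = gaps))
  # manual enumeration: sv01 len 49; sv04 len 1 Mb + 1; sv05 depth 29;
  # sv07 imprecise; sv08 null genotype; sv09 in gap; sv11 len 49 AND depth 29;
  # sv12 missing depth
  expect_setequal(fl$kept$variants$sv_id,
                  c("sv02", "sv03", "sv06", "sv10"))
  counts <- setNames(fl$rule_counts$n_rejected, fl$rule_counts$rule)
  expect_equal(unname(counts["size"]), 3L)          # sv01, sv04, sv11
  expect_equal(unname(counts["gap"]), 1L)           # sv09
  expect_equal(unname(counts["null_genotype"]), 1L) # sv08
  expect_equal(unname(counts["imprecise"]), 1L)     # sv07
  expect_equal(unname(counts["low_depth"]), 3L)     # sv05, sv11, sv12
  # a record failing several rules increments each
  expect_true(all(c("rule_size", "rule_low_depth") %in% names(fl$rejected)))
  r11 <- fl$rejected[fl$rejected$sv_id == "sv11", ]
  expect_true(r11$rule_size && r11$rule_low_depth)
  # kept + rejected = input; filtering is idempotent
  expect_equal(nrow(fl$kept$variants) + nrow(fl$rejected), nrow(v))
  again <- filter_svs(fl$kept, reference_gaps = gaps)
  expect_identical(again$kept$variants, fl$kept$variants)
})

test_that("SV filter round-trips through a Sniffles-dialect VCF", {
  v <- boundary_variants()
  svs <- make_sv_set(v, boundary_genotypes(v))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(svs, path, tibble::tibble(chrom = "chr1", length = 2e6))
  back <- read_sv_vcf(path)
  gaps <- tibble::tibble(chrom = "chr1", start = 94000, end = 96000)
  fl <- suppressWarnings(filter_svs(back, reference_gaps = gaps))
  expect_setequal(fl$kept$variants$sv_id, c("sv02", "sv03", "sv06", "sv10"))
})

test_that("SV spectrum fractions follow direct arithmetic", {
  v <- tibble::tibble(sv_id = paste0("s", 1:3), chrom = "chr1",
                      pos = c(100L, 200L, 300L), end = c(100L, 200L, 300L),
                      svtype = "INS", svlen = c(200L, 200L, 5000L),
                      support_depth = 60L, precise = TRUE)
  gt <- matrix(0L, 3, 100, dimnames = list(v$sv_id, sprintf("A%03d", 1:100)))
  gt["s1", 1] <- 1L           # MAF 0.01
  gt["s2", ] <- 1L            # carried by all: MAF 0
  gt["s3", 1:50] <- 1L        # MAF 0.5
  sp <- sv_spectrum(make_sv_set(v, gt))
  expect_equal(sp$frac_lt_1kb, 2 / 3)
  expect_equal(sp$frac_maf_lt_0.05, 2 / 3)
  expect_equal(sp$frac_shared, 2 / 3)
  g <- glance(sp)
  expect_equal(g$n_all_missing, 0L)
})

test_that("window tiling and breakpoint attribution follow the 200/100 kb geometry", {
  cl <- tibble::tibble(chrom = "chr1", length = 5e5)
  # a DEL contributes pos and end; both fall in two overlapping windows
  v <- tibble::tibble(sv_id = "d1", chrom = "chr1", pos = 150000L,
                      end = 150999L, svtype = "DEL", svlen = 1000L,
                      support_depth = 60L, precise = TRUE)
  w <- window_breakpoint_counts(v, cl)
  expect_equal(nrow(w), 4L)
  expect_equal(w$start, c(0, 1e5, 2e5, 3e5))
  expect_equal(w$end, c(2e5, 3e5, 4e5, 5e5))
  expect_equal(w$n_breakpoints, c(2L, 2L, 0L, 0L))

  # empty SV list -> all zeros
  w0 <- window_breakpoint_counts(v[0, ], cl)
  expect_true(all(w0$n_breakpoints == 0))

  # INS contributes a single breakpoint
  ins <- dplyr::mutate(v, svtype = "INS", end = pos)
  expect_equal(window_breakpoint_counts(ins, cl)$n_breakpoints[1:2], c(1L, 1L))

  # breakpoint mass conservation over non-overlapping half-steps
  set.seed(2)
  cl2 <- tibble::tibble(chrom = "chr1", length = 2e6)
  svs <- simulate_svs(sv_sim_config(500, n_accessions = 2, seed = 12), cl2)
  w2 <- window_breakpoint_counts(svs, cl2, window = 1e5, step = 1e5)
  n_bp <- sum(svs$variants$svtype %in% c("DEL", "INV", "DUP")) +
    nrow(svs$variants)
  expect_equal(sum(w2$n_breakpoints), n_bp)

  expect_error(window_breakpoint_counts(
    dplyr::mutate(v, pos = 6e5, end = 6e5, svtype = "INS"), cl),
    "beyond chromosome end")
})

test_that("hotspot flagging takes floor(top_frac x W) and merges adjacent windows", {
  w <- tibble::tibble(chrom = "chr1",
                      start = seq(0, by = 1e5, length.out = 100),
                      end = seq(2e5, by = 1e5, length.out = 100),
                      n_breakpoints = sample(1000:9999, 100))
  hs <- detect_hotspots(w, top_frac = 0.10)
  expect_equal(nrow(hs$flagged), 10L)
  expect_equal(sort(hs$flagged$n_breakpoints, decreasing = TRUE),
               sort(w$n_breakpoints, decreasing = TRUE)[1:10])

  # two adjacent flagged windows merge into one region
  w2 <- w
  w2$n_breakpoints <- rep(1L, 100)
  w2$n_breakpoints[1:2] <- c(100L, 90L)
  hs2 <- detect_hotspots(w2, top_frac = 0.02)
  expect_equal(nrow(hs2$regions), 1L)
  expect_equal(hs2$regions$start, 0)
  expect_equal(hs2$regions$end, 3e5)
  expect_equal(hs2$regions$n_windows_merged, 2L)

  expect_error(detect_hotspots(w[1:5, ]), "at least 10")
  w3 <- dplyr::mutate(w, n_breakpoints = 0L)
  expect_warning(out <- detect_hotspots(w3), "zero")
  expect_equal(nrow(out$regions), 0L)
})

test_that("matched null preserves the length multiset and is deterministic", {
  cl <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(2e6, 1e6))
  svs <- simulate_svs(sv_sim_config(300, n_accessions = 2, seed = 3), cl)
  n1 <- simulate_matched_null(svs, cl, n_sim = 1, seed = 5)
  n2 <- simulate_matched_null(svs, cl, n_sim = 1, seed = 5)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  # per-replicate breakpoint mass equals the observed SV count structure
  w_obs <- window_breakpoint_counts(svs, cl, window = 1e5, step = 1e5)
  w_null <- simulate_matched_null(svs, cl, n_sim = 2, seed = 5,
                                  window = 1e5, step = 1e5)
  per_rep <- tapply(w_null$n_breakpoints, w_null$replicate, sum)
  expect_true(all(per_rep == sum(w_obs$n_breakpoints)))
})

test_that("hotspot significance behaves at identity and complete separation", {
  w <- tibble::tibble(chrom = "chr1",
                      start = seq(0, by = 1e5, length.out = 100),
                      end = seq(2e5, by = 1e5, length.out = 100),
                      n_breakpoints = rpois(100, 20))
  null1 <- dplyr::mutate(w, replicate = 1L)
  p_same <- hotspot_significance(w, null1)$p_value
  expect_gt(p_same, 0.9)
  shifted <- dplyr::mutate(w, n_breakpoints = n_breakpoints + 10L)
  p_shift <- hotspot_significance(shifted, null1)$p_value
  expect_lt(p_shift, 1e-6)
  expect_error(hotspot_significance(w[1, ], null1[1, ]), "single window")
  expect_error(hotspot_significance(w, dplyr::mutate(null1, start = start + 1)),
               "do not match")
})

test_that("SV-gene annotation distinguishes containment, overlap and flanks", {
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1",
                          start = 200L, end = 4000L)
  mk_sv <- function(pos, end) tibble::tibble(
    sv_id = "s", chrom = "chr1", pos = pos, end = end, svtype = "DEL",
    svlen = end - pos + 1L, support_depth = 60L, precise = TRUE)
  expect_equal(annotate_sv_gene(mk_sv(100L, 5000L), genes)$sv_annotation$category,
               "contains-gene")
  expect_equal(annotate_sv_gene(mk_sv(3900L, 4200L), genes)$sv_annotation$category,
               "overlaps-gene")
  expect_equal(annotate_sv_gene(mk_sv(4500L, 4600L), genes)$sv_annotation$category,
               "within-flank")
  expect_equal(annotate_sv_gene(mk_sv(8000L, 8100L), genes)$sv_annotation$category,
               "intergenic")
  ann <- annotate_sv_gene(mk_sv(4500L, 4600L), genes)
  expect_true(ann$gene_flags$flanked)
  expect_error(annotate_sv_gene(mk_sv(1L, 2L), genes, flank = -1), "non-negative")
})
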