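test_that("build_pav_matrix transcribes cells and drops empty rows", {
  tbl <- tibble::tibble(
    orthogroup_id = c("OG1", "OG2", "OG3"),
    A = c("a1", "a2", ""),
    B = c("b1", "", "b3"))
  pav <- build_pav_matrix(tbl)
  expect_equal(sum(!pav$presence), 2L)
  expect_equal(unname(pav$presence["OG2", ]), c(TRUE, FALSE))

  tbl$A[3] <- ""
  tbl$B[3] <- ""
  expect_warning(pav2 <- build_pav_matrix(tbl), "present in no accession")
  expect_equal(nrow(pav2$presence), 2L)
  expect_error(build_pav_matrix(tbl, accessions = c("A", "Z")), "absent")
})

test_that("PAV matrix round-trips the generator's truth matrix exactly", {
  sim <- simulate_pangenome(pangenome_sim_config(c(X = 6, Y = 4), 50, 80,
                                                 seed = 31))
  pav <- suppressWarnings(build_pav_matrix(sim$orthogroups,
                                           subpop = sim$truth$accessions))
  truth <- sim$truth$presence[rownames(pav$presence), colnames(pav$presence)]
  expect_identical(pav$presence, truth)
})

test_that("core threshold is an exact fraction test at the 239/251 boundary", {
  presence <- matrix(FALSE, 3, 251,
                     dimnames = list(c("at239", "at238", "all"),
                                     sprintf("a%03d", 1:251)))
  presence["at239", 1:239] <- TRUE
  presence["at238", 1:238] <- TRUE
  presence["all", ] <- TRUE
  cls <- classify_core_dispensable(pav_matrix(presence))
  expect_equal(cls$class[cls$orthogroup_id == "at239"], "core")
  expect_equal(cls$class[cls$orthogroup_id == "at238"], "dispensable")
  expect_equal(cls$class[cls$orthogroup_id == "all"], "core")
  # partition at every threshold
  for (thr in c(0.5, 0.9, 0.95, 1)) {
    cl <- classify_core_dispensable(pav_matrix(presence), thr)
    expect_equal(sum(cl$class == "core") + sum(cl$class == "dispensable"), 3L)
  }
})

test_that("rarefaction endpoints and monotonicity hold within each ordering", {
  set.seed(4)
  presence <- matrix(runif(60) < 0.6, 12, 5,
                     dimnames = list(paste0("og", 1:12), paste0("a", 1:5)))
  presence[rowSums(presence) == 0, 1] <- TRUE
  pav <- pav_matrix(presence)
  rc <- rarefaction_curves(pav, n_orders = 40, seed = 8)
  per <- attr(rc, "per_order")
  # step N pan = total orthogroups, every ordering
  expect_true(all(per$pan[, 5] == nrow(presence)))
  # monotone within orderings
  expect_true(all(apply(per$pan, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(per$core, 1, function(x) all(diff(x) <= 0))))
  # step-1 pan = core = that accession's gene count
  expect_true(all(per$pan[, 1] == per$core[, 1]))
})

test_that("sampled rarefaction matches the exhaustive-ordering oracle", {
  presence <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE,
                       TRUE, FALSE, TRUE, FALSE, FALSE,
                       TRUE, TRUE, TRUE, FALSE, TRUE), 5, 3,
                     dimnames = list(paste0("og", 1:5), c("a", "b", "c")))
  oracle <- oracle_rarefaction(presence)
  rc <- rarefaction_curves(pav_matrix(presence), n_orders = 600, seed = 17)
  got <- tidy(rc)
  for (k in 1:3) {
    se_pan <- stats::sd(oracle$pan[, k]) / sqrt(600)
    expect_lt(abs(got$mean_count[got$count_kind == "pan" &
                                   got$n_accessions == k] -
                    oracle$pan_mean[k]), max(4 * se_pan, 1e-9))
    se_core <- stats::sd(oracle$core[, k]) / sqrt(600)
    expect_lt(abs(got$mean_count[got$count_kind == "core" &
                                   got$n_accessions == k] -
                    oracle$core_mean[k]), max(4 * se_core, 1e-9))
  }
})

test_that("nonprivate mode restricts once on the full matrix", {
  presence <- matrix(c(TRUE, FALSE, FALSE,   # private to a
                       TRUE, TRUE, FALSE,
                       TRUE, TRUE, TRUE), 3, 3, byrow = TRUE,
                     dimnames = list(paste0("og", 1:3), c("a", "b", "c")))
  rc <- rarefaction_curves(pav_matrix(presence), n_orders = 5, seed = 1,
                           gene_set_mode = "nonprivate")
  final <- tidy(rc)
  expect_equal(final$mean_count[final$count_kind == "pan" &
                                  final$n_accessions == 3], 2)
})

test_that("pairwise PAV divergence matches hand enumeration and brute force", {
  presence <- matrix(FALSE, 4, 2, dimnames = list(paste0("g", 1:4), c("A", "B")))
  presence[c("g1", "g2", "g3"), "A"] <- TRUE
  presence[c("g2", "g3", "g4"), "B"] <- TRUE
  d <- pairwise_pav_divergence(pav_matrix(presence), "A", "B")
  expect_equal(d$pairs$n_differing, 2)
  expect_equal(d$pairs$n_union, 4)
  expect_equal(d$mean_ratio, 0.5)

  # identical and disjoint cases
  same <- matrix(TRUE, 3, 2, dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_equal(pairwise_pav_divergence(pav_matrix(same), "A", "B")$mean_ratio, 0)
  disj <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                 dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_equal(pairwise_pav_divergence(pav_matrix(disj), "A", "B")$mean_ratio, 1)

  # brute force over all pairs of a random 5-accession matrix
  set.seed(11)
  M <- matrix(runif(50) < 0.5, 10, 5,
              dimnames = list(paste0("og", 1:10), paste0("a", 1:5)))
  M[rowSums(M) == 0, 1] <- TRUE
  dd <- pairwise_pav_divergence(pav_matrix(M), paste0("a", 1:5))
  manual <- as.numeric(combn(5, 2, function(ij) {
    x <- M[, ij[1]]; y <- M[, ij[2]]
    sum(xor(x, y)) / sum(x | y)
  }))
  expect_equal(sort(dd$pairs$ratio), sort(manual))
  expect_equal(dd$mean_ratio, mean(manual))
})

test_that("taxon levels follow the ordered sharing rules", {
  acc <- c(or1 = "Or", ob1 = "Ob", og1 = "Og", osi1 = "Osi", osj1 = "Osj")
  mk <- function(present_in) {
    p <- matrix(FALSE, 1, 5, dimnames = list("og", names(acc)))
    p[1, present_in] <- TRUE
    assign_taxon_levels(pav_matrix(p, acc))$level
  }
  expect_equal(mk(c("or1", "ob1")), "I")
  expect_equal(mk(c("or1", "osj1")), "II")
  expect_equal(mk(c("og1", "ob1")), "III")
  expect_equal(mk(c("osi1", "osj1")), "IV")
  expect_equal(mk(c("osi1", "og1")), "undetermined")
  # level I wins over later rules when several apply
  expect_equal(mk(c("or1", "ob1", "osi1", "osj1")), "I")

  p <- matrix(TRUE, 1, 2, dimnames = list("og", c("x", "y")))
  expect_error(assign_taxon_levels(pav_matrix(p, c(x = "Or", y = "Ob"))),
               "missing required subpopulation")
})
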