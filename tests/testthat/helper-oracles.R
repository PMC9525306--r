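# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (explicit pairwise relations,
# exhaustive enumeration, textbook algebra) rather than reusing any package
# internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- NLR arrangement oracle --------------------------------------------------
# Explicit approaching matrix over all NLR pairs + connected components via
# breadth-first search. `genes` is one accession/chromosome, any row order.
oracle_nlr_arrangement <- function(genes, max_intervening = 1) {
  g <- genes[order(genes$start, genes$end, genes$gene_id), ]
  nlr_rank <- which(g$is_nlr)
  m <- length(nlr_rank)
  if (m == 0) return(tibble::tibble(gene_id = character(), category = character(),
                                    component = integer()))
  # non-NLR genes strictly between two gene ranks, via a cumulative count
  cnn <- cumsum(!g$is_nlr)
  between <- function(lo, hi) cnn[hi - 1] - cnn[lo]
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      lo <- min(nlr_rank[i], nlr_rank[j]); hi <- max(nlr_rank[i], nlr_rank[j])
      adj[i, j] <- between(lo, hi) <= max_intervening
    }
  }
  comp <- rep(NA_integer_, m)
  cid <- 0
  for (i in seq_len(m)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    queue <- i
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      queue <- c(queue, which(adj[cur, ] & is.na(comp)))
    }
  }
  sizes <- table(comp)
  tibble::tibble(
    gene_id = g$gene_id[nlr_rank],
    category = c("singleton", "pair", "cluster")[pmin(sizes[as.character(comp)], 3)],
    component = comp)
}

# random single-chromosome gene table for oracle comparisons
random_chromosome_genes <- function(n_genes, p_nlr, chrom = "chr1",
                                    accession = "ACC") {
  start <- cumsum(sample(500:3000, n_genes, replace = TRUE))
  tibble::tibble(
    gene_id = sprintf("%s_%s_g%03d", accession, chrom, seq_len(n_genes)),
    accession_id = accession, chrom = chrom,
    start = start, end = start + sample(300:2500, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    is_nlr = stats::runif(n_genes) < p_nlr)
}

# --- rarefaction exhaustive oracle -------------------------------------------
# All orderings of the accessions; per-step pan/core counts by direct set ops.
oracle_rarefaction <- function(presence) {
  N <- ncol(presence)
  perms <- .permutations(seq_len(N))
  pan <- matrix(0, nrow(perms), N)
  core <- matrix(0, nrow(perms), N)
  for (r in seq_len(nrow(perms))) {
    seen <- rep(FALSE, nrow(presence))
    inall <- rep(TRUE, nrow(presence))
    for (k in seq_len(N)) {
      col <- presence[, perms[r, k]]
      seen <- seen | col
      inall <- inall & col
      pan[r, k] <- sum(seen)
      core[r, k] <- sum(inall)
    }
  }
  list(pan_mean = colMeans(pan), core_mean = colMeans(core),
       pan = pan, core = core)
}

.permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# --- Weir-Cockerham haploid oracle -------------------------------------------
# Textbook variance-components algebra written out step by step.
oracle_wc_fst <- function(n1, n2, p1, p2) {
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - 2)
  nc <- N - (n1^2 + n2^2) / N                              # / (r - 1)
  a <- (msp - msg) / nc
  list(a = a, within = msg, fst = a / (a + msg))
}

# --- boundary-value SV fixture -----------------------------------------------
# 12 records exercising every filter rule at its boundary:
# sv01 len 49 (size), sv02 len 50 (kept), sv03 len 1 Mb (kept),
# sv04 len 1 Mb + 1 (size), sv05 depth 29 (depth), sv06 depth 30 (kept),
# sv07 IMPRECISE, sv08 0/0 genotype, sv09 in reference gap, sv10 kept,
# sv11 len 49 AND depth 29 (two rules), sv12 missing depth
boundary_variants <- function() {
  tibble::tibble(
    sv_id = sprintf("sv%02d", 1:12),
    chrom = "chr1",
    pos = as.integer(c(1e4, 2e4, 3e4, 4e4, 5e4, 6e4, 7e4, 8e4, 95e3, 1.1e5,
                       1.2e5, 1.3e5)),
    svlen = c(49L, 50L, 1000000L, 1000001L, 500L, 500L, 500L, 500L, 500L,
              500L, 49L, 500L),
    svtype = c("INS", "INS", "INS", "INS", "DEL", "DEL", "INS", "INS", "DEL",
               "INS", "INS", "INS"),
    support_depth = c(60L, 60L, 60L, 60L, 29L, 30L, 60L, 60L, 60L, 60L, 29L,
                      NA_integer_),
    precise = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                TRUE, TRUE)) |>
    dplyr::mutate(end = as.integer(ifelse(svtype == "DEL", pos + svlen - 1L,
                                          pos)))
}

boundary_genotypes <- function(v) {
  gt <- matrix(1L, nrow(v), 3, dimnames = list(v$sv_id, paste0("S", 1:3)))
  gt["sv08", ] <- 0L         # 0/0 across the panel
  gt
}

# --- small builders ----------------------------------------------------------
toy_pav <- function(presence, subpop = NULL) {
  pav_matrix(presence, subpop)
}

make_sv_set <- function(variants, genotypes = NULL, n_acc = 3) {
  if (is.null(genotypes)) {
    genotypes <- matrix(1L, nrow(variants), n_acc,
                        dimnames = list(variants$sv_id,
                                        sprintf("ACC%03d", seq_len(n_acc))))
  }
  structure(list(variants = variants, genotypes = genotypes), class = "sv_set")
}
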