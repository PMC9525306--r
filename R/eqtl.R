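#' Rank-based inverse normal transform
#'
#' Replaces values by standard-normal quantiles of their ranks with the Blom
#' offset, `qnorm((rank - 3/8) / (n + 1/4))`, ties receiving averaged ranks —
#' the usual quantile-quantile normalization of expression values. Constant
#' input maps to all zeros with a warning.
#'
#' @param values Numeric vector with at least 3 non-missing values.
#' @return Transformed numeric vector (`NA`s preserved in place).
#' @export
#' @examples
#' rank_normalize(c(5, 1, 9))
rank_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("rank normalization needs >= 3 non-missing values")
  out <- rep(NA_real_, length(values))
  x <- values[ok]
  if (length(unique(x)) == 1) {
    warn("constant input; rank-normalized values set to 0")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Filter and rank-normalize an expression matrix
#'
#' Keeps genes with mean FPKM above `min_mean_fpkm` (default 0.1) and
#' rank-normalizes each retained gene across accessions.
#'
#' @param expression Tibble `gene_id` + one numeric column per accession.
#' @param min_mean_fpkm Mean-FPKM retention threshold.
#' @return Tibble of the same shape, transformed; attribute `n_dropped`
#'   records the genes removed by the filter.
#' @export
normalize_expression <- function(expression, min_mean_fpkm = 0.1) {
  .assert_cols(expression, "gene_id", "expression")
  vals <- as.matrix(expression[setdiff(names(expression), "gene_id")])
  keep <- rowMeans(vals, na.rm = TRUE) > min_mean_fpkm
  vals <- vals[keep, , drop = FALSE]
  trans <- t(apply(vals, 1, rank_normalize))
  dimnames(trans) <- dimnames(vals)
  out <- bind_cols(tibble(gene_id = expression$gene_id[keep]),
                   as_tibble(trans, .name_repair = "minimal"))
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "transformed") <- TRUE
  out
}

#' SV-expression association with covariate-adjusted linear models
#'
#' For every (SV, gene) pair, fits ordinary least squares of the transformed
#' expression on genotype dosage plus covariates, reporting the genotype
#' coefficient, its t-test p-value, and Benjamini-Hochberg adjusted p-values
#' across all tests. SVs are pre-filtered to allele frequency >= `maf_min`
#' and missing rate <= `max_missing`; remaining missing dosages are
#' mean-imputed. Computation residualizes expression and dosage on the
#' covariates once and scans all pairs in matrix form, which is exactly
#' equivalent to the per-pair OLS fit.
#'
#' @param sv_genotypes Dosage matrix (SV x accession) or an `sv_set`.
#' @param expression Rank-normalized tibble from [normalize_expression()]
#'   (or any `gene_id` + accession-column tibble).
#' @param covariates Optional numeric matrix or tibble (accession x
#'   covariate, e.g. expression PEER factors and genotype PCs); an intercept
#'   is always included.
#' @param maf_min,max_missing SV inclusion filters (defaults 0.05 and 0.1).
#' @return An `eqtl_result` tibble: `sv_id, gene_id, beta, se, statistic,
#'   p_value, adj_p`, ordered by p-value.
#' @export
eqtl_associate <- function(sv_genotypes, expression, covariates = NULL,
                           maf_min = 0.05, max_missing = 0.1) {
  G <- if (inherits(sv_genotypes, "sv_set")) sv_genotypes$genotypes else
    sv_genotypes
  .assert_cols(expression, "gene_id", "expression")
  acc <- intersect(colnames(G), setdiff(names(expression), "gene_id"))
  if (length(acc) < 3) abort("need >= 3 accessions shared by genotypes and expression")
  G <- G[, acc, drop = FALSE]
  E <- as.matrix(expression[acc])
  rownames(E) <- expression$gene_id

  miss <- rowMeans(is.na(G))
  f <- rowMeans(G, na.rm = TRUE)
  keep <- miss <= max_missing & pmin(f, 1 - f) >= maf_min
  G <- G[keep, , drop = FALSE]
  if (nrow(G) == 0) abort("no SVs pass the MAF / missingness filters")
  # mean-impute residual missingness
  if (anyNA(G)) {
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- rowMeans(G, na.rm = TRUE)[idx[, 1]]
  }

  n <- length(acc)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    if (nrow(C) != n) {
      # allow accession-keyed tibbles
      if (!is.null(rownames(C)) && all(acc %in% rownames(C))) {
        C <- C[acc, , drop = FALSE]
      } else {
        abort("covariates must have one row per accession")
      }
    }
    X <- cbind(X, C)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      abort(sprintf("rank-deficient covariates; collinear column(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  qrX <- qr(X)
  resid_on_X <- function(M) M - t(qr.fitted(qrX, t(M)))
  Er <- resid_on_X(E)
  Gr <- resid_on_X(G)

  ss_g <- rowSums(Gr^2)
  ss_e <- rowSums(Er^2)
  if (any(ss_g == 0)) {
    G <- G[ss_g > 0, , drop = FALSE]
    Gr <- Gr[ss_g > 0, , drop = FALSE]
    ss_g <- ss_g[ss_g > 0]
  }
  num <- Er %*% t(Gr)                                # gene x sv
  beta <- sweep(num, 2, ss_g, "/")
  df <- n - ncol(X) - 1
  if (df < 1) abort("not enough accessions for the covariate model")
  rss <- outer(ss_e, rep(1, ncol(num))) - beta * num
  rss[rss < 0] <- 0
  se <- sqrt(sweep(rss / df, 2, ss_g, "/"))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)

  out <- tibble(
    sv_id = rep(colnames(num) %||% rownames(G), each = nrow(num)),
    gene_id = rep(rownames(E), ncol(num)),
    beta = as.vector(beta), se = as.vector(se),
    statistic = as.vector(tstat), p_value = as.vector(pval)) |>
    mutate(adj_p = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value)
  structure(out, class = c("eqtl_result", class(out)),
            df = df, n_accessions = n)
}

#' Prune linked eQTL hits by background LD
#'
#' Within each gene, walks hits in ascending p-value order (ties broken by
#' `sv_id`) and retains a hit only if its genotype r-squared with every
#' already-retained hit for that gene is at or below `r2_background` — the
#' background linkage-disequilibrium level, so hits closer in LD than
#' background are collapsed onto the most significant one. r-squared is the
#' squared Pearson correlation of dosages over pairwise-complete accessions;
#' pairs with no genotype overlap are treated as unlinked with a warning.
#'
#' @param hits Tibble with `sv_id, gene_id, p_value` (e.g. the significant
#'   subset of an [eqtl_associate()] result).
#' @param sv_genotypes Dosage matrix (SV x accession) or `sv_set`.
#' @param r2_background Background r-squared (default 0.11, the stable
#'   LD-decay plateau for deletions and insertions).
#' @return The input with a logical `retained` column.
#' @export
prune_linked <- function(hits, sv_genotypes, r2_background = 0.11) {
  G <- if (inherits(sv_genotypes, "sv_set")) sv_genotypes$genotypes else
    sv_genotypes
  .assert_cols(hits, c("sv_id", "gene_id", "p_value"), "hits")
  warned <- FALSE
  r2 <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2 || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      if (!warned) {
        warn("SV pair(s) without usable genotype overlap treated as unlinked")
        warned <<- TRUE
      }
      return(0)
    }
    cor(a[ok], b[ok])^2
  }
  hits |>
    group_by(.data$gene_id) |>
    arrange(.data$p_value, .data$sv_id, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      kept <- character(0)
      ret <- logical(nrow(d))
      for (i in seq_len(nrow(d))) {
        ok <- all(vapply(kept, function(k)
          r2(G[d$sv_id[i], ], G[k, ]) <= r2_background, logical(1)))
        ret[i] <- ok
        if (ok) kept <- c(kept, d$sv_id[i])
      }
      mutate(d, retained = ret)
    }) |>
    ungroup()
}

#' Classify eQTL hits as cis or trans
#'
#' A hit is cis iff its SV interval intersects the gene body or lies within
#' `flank` bp (strictly less than) of either gene end — i.e. of the
#' transcription start site or the gene end, whichever strand the gene is on;
#' otherwise trans (including different-chromosome pairs).
#'
#' @param hits Tibble with `sv_id, gene_id`.
#' @param genes Tibble `gene_id, chrom, start, end` (1-based closed).
#' @param svs Tibble or `sv_set` with `sv_id, chrom, pos, end`.
#' @param flank Cis distance in bp (default 2000).
#' @return The input with a `class` column (`"cis"` / `"trans"`).
#' @export
classify_cis <- function(hits, genes, svs, flank = 2000) {
  v <- if (inherits(svs, "sv_set")) svs$variants else svs
  .assert_cols(hits, c("sv_id", "gene_id"), "hits")
  .assert_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  gi <- match(hits$gene_id, genes$gene_id)
  si <- match(hits$sv_id, v$sv_id)
  if (anyNA(gi) || is.null(genes$start) ||
      any(is.na(genes$start[gi]) | is.na(genes$end[gi]))) {
    bad <- hits$gene_id[is.na(gi) | is.na(genes$start[gi])][1]
    abort(sprintf("gene %s has no coordinates", bad))
  }
  if (anyNA(si)) {
    abort(sprintf("SV %s has no coordinates", hits$sv_id[is.na(si)][1]))
  }
  sv_start <- v$pos[si]; sv_end <- pmax(v$pos[si], v$end[si])
  same_chrom <- v$chrom[si] == genes$chrom[gi]
  # gap between closed intervals; 0 when overlapping
  gap <- pmax(0, pmax(genes$start[gi] - sv_end, sv_start - genes$end[gi]))
  mutate(hits, class = ifelse(same_chrom & gap < flank, "cis", "trans"))
}

#' @export
glance.eqtl_result <- function(x, alpha = 0.05, ...) {
  tibble(n_tests = nrow(x), n_significant = sum(x$adj_p <= alpha),
         alpha = alpha, df = attr(x, "df"),
         n_accessions = attr(x, "n_accessions"))
}

#' @export
tidy.eqtl_result <- function(x, ...) as_tibble(unclass(x)[names(x)])
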