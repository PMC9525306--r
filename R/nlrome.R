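#' Classify NLRs into singletons, pairs and clusters
#'
#' Two NLRs on the same chromosome of the same accession are "approaching"
#' when at most one non-NLR gene lies between them in gene-rank order (the
#' rule counts annotated genes, not base pairs). Groups are the connected
#' components of the approaching relation: one member is a singleton, two a
#' pair, three or more a cluster. Pairs additionally get an orientation
#' (T-H / H-H / T-T, see [pair_orientation()]), pairs and clusters a
#' homogeneity call from their orthogroup ids (see [group_homogeneity()]),
#' and clusters a strand string (e.g. `"+-+"`).
#'
#' Genes are ordered by `(start, end, gene_id)` within each chromosome;
#' identical starts are resolved by that deterministic tie-break with a
#' warning.
#'
#' @param genes Tibble of gene records for one or more accessions:
#'   `gene_id, accession_id, chrom, start, end, strand, is_nlr`, optionally
#'   `orthogroup_id` (required for homogeneity).
#' @param max_intervening Maximum non-NLR genes between approaching NLRs
#'   (default 1, the "fewer than two" rule).
#' @return Tibble with one row per NLR: `gene_id, accession_id, chrom,
#'   category` (singleton/pair/cluster), `group_id, group_size, orientation`
#'   (pairs), `strand_pattern`, `homogeneity` (pairs/clusters).
#' @export
#' @examples
#' g <- tibble::tibble(
#'   gene_id = paste0("g", 1:4), accession_id = "A", chrom = "chr1",
#'   start = c(100, 300, 500, 700), end = c(150, 350, 550, 750),
#'   strand = "+", is_nlr = c(TRUE, FALSE, TRUE, TRUE),
#'   orthogroup_id = c("OG1", "OG9", "OG1", "OG2"))
#' classify_nlr_arrangement(g)
classify_nlr_arrangement <- function(genes, max_intervening = 1L) {
  .assert_cols(genes, c("gene_id", "accession_id", "chrom", "start", "end",
                        "strand", "is_nlr"), "genes")
  has_og <- "orthogroup_id" %in% names(genes)
  dup_start <- genes |>
    group_by(.data$accession_id, .data$chrom, .data$start) |>
    filter(n() > 1) |>
    ungroup()
  if (nrow(dup_start) > 0) {
    warn(sprintf(
      "%d gene(s) share a start coordinate; ordered by (end, gene_id)",
      nrow(dup_start)))
  }

  ordered <- genes |>
    group_by(.data$accession_id, .data$chrom) |>
    arrange(.data$start, .data$end, .data$gene_id, .by_group = TRUE) |>
    mutate(.rank = row_number()) |>
    ungroup()

  nlrs <- ordered |>
    filter(.data$is_nlr) |>
    group_by(.data$accession_id, .data$chrom) |>
    arrange(.data$.rank, .by_group = TRUE) |>
    mutate(
      # non-NLR genes between consecutive NLRs; chaining the consecutive
      # relation yields the full connected components (gaps are sub-sums)
      gap_prev = .data$.rank - lag(.data$.rank, default = NA_integer_) - 1L,
      new_group = is.na(.data$gap_prev) | .data$gap_prev > max_intervening,
      local_group = cumsum(.data$new_group)) |>
    ungroup() |>
    mutate(group_id = paste(.data$accession_id, .data$chrom,
                            .data$local_group, sep = ":")) |>
    group_by(.data$group_id) |>
    mutate(group_size = n(),
           strand_pattern = paste(.data$strand, collapse = "")) |>
    ungroup() |>
    mutate(category = dplyr::case_when(
      .data$group_size == 1 ~ "singleton",
      .data$group_size == 2 ~ "pair",
      TRUE ~ "cluster"))

  pairs_df <- filter(nlrs, .data$category == "pair")
  orient <- if (nrow(pairs_df) == 0) {
    tibble(group_id = character(), orientation = character())
  } else {
    pairs_df |>
      group_by(.data$group_id) |>
      arrange(.data$.rank, .by_group = TRUE) |>
      summarise(orientation = .orientation_code(first(.data$strand),
                                                last(.data$strand)),
                .groups = "drop")
  }
  nlrs <- left_join(nlrs, orient, by = "group_id")

  if (has_og) {
    homog <- group_homogeneity(nlrs |> filter(.data$category != "singleton"),
                               group_col = "group_id")
    nlrs <- left_join(nlrs, homog, by = "group_id")
  } else {
    nlrs$homogeneity <- NA_character_
  }
  nlrs |>
    select("gene_id", "accession_id", "chrom", "category", "group_id",
           "group_size", "orientation", "strand_pattern", "homogeneity")
}

.orientation_code <- function(strand_left, strand_right) {
  if (length(strand_left) == 0) return(character(0))
  if (is.na(strand_left) || is.na(strand_right) ||
      !strand_left %in% c("+", "-") || !strand_right %in% c("+", "-")) {
    abort("pair orientation requires defined strands")
  }
  if (strand_left == strand_right) return("T-H")
  if (strand_left == "-") "H-H" else "T-T"
}

#' Orientation of a gene pair
#'
#' With the two genes ordered by start coordinate (the input order does not
#' matter; genes are re-sorted), a pair on the same strand is tail-to-head
#' (T-H); a `-`/`+` pair has its 5' ends (promoters) facing inward and is
#' head-to-head (H-H); a `+`/`-` pair has its 3' ends facing and is
#' tail-to-tail (T-T).
#'
#' @param a,b One-row tibbles (or lists) with `start` and `strand`; same
#'   chromosome assumed.
#' @return `"T-H"`, `"H-H"` or `"T-T"`.
#' @export
#' @examples
#' pair_orientation(list(start = 100, strand = "-"),
#'                  list(start = 900, strand = "+"))
pair_orientation <- function(a, b) {
  if (b$start < a$start) { tmp <- a; a <- b; b <- tmp }
  .orientation_code(a$strand, b$strand)
}

#' Homogeneity of NLR pairs and clusters
#'
#' A pair or cluster is homogeneous iff all member genes belong to the same
#' orthogroup (non-redundant gene); any mismatch makes it heterogeneous.
#'
#' @param genes Tibble with `orthogroup_id` and a grouping column.
#' @param group_col Name of the grouping column (default `"group_id"`).
#' @return Tibble `group_id, homogeneity`.
#' @export
group_homogeneity <- function(genes, group_col = "group_id") {
  .assert_cols(genes, c("orthogroup_id", group_col), "genes")
  bad <- is.na(genes$orthogroup_id) | genes$orthogroup_id == ""
  if (any(bad)) {
    ids <- if ("gene_id" %in% names(genes)) genes$gene_id[bad] else which(bad)
    abort(sprintf("gene(s) without an orthogroup id: %s",
                  paste(ids, collapse = ", ")))
  }
  genes |>
    group_by(group_id = .data[[group_col]]) |>
    summarise(homogeneity = ifelse(n_distinct(.data$orthogroup_id) == 1,
                                   "homogeneous", "heterogeneous"),
              .groups = "drop")
}

#' Core/dispensable summary of NLR orthogroups within a subpopulation
#'
#' Restricts the PAV matrix to the NLR orthogroups and the accessions of the
#' named subpopulation (or the full panel) and applies the core threshold
#' within that panel: core iff present in >= `threshold` of the
#' subpopulation's accessions.
#'
#' @param pav A [pav_matrix()].
#' @param nlr_orthogroups Character vector of NLR orthogroup ids.
#' @param subpop Subpopulation label, or `NULL` for all accessions.
#' @param threshold Core fraction, default 0.95.
#' @return One-row tibble `subpop, n_nlr, n_core, n_dispensable, frac_core,
#'   frac_dispensable`.
#' @export
core_nlr_summary <- function(pav, nlr_orthogroups, subpop = NULL,
                             threshold = 0.95) {
  stopifnot(inherits(pav, "pav_matrix"))
  if (!is.null(subpop) && !subpop %in% pav$subpop) {
    abort(sprintf("unknown subpopulation '%s'", subpop))
  }
  cols <- if (is.null(subpop)) colnames(pav$presence) else
    names(pav$subpop)[pav$subpop == subpop]
  rows <- intersect(nlr_orthogroups, rownames(pav$presence))
  sub <- pav$presence[rows, cols, drop = FALSE]
  # only NLR orthogroups represented in this panel at all
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  n <- nrow(sub)
  n_core <- if (n == 0) 0L else sum(rowSums(sub) / length(cols) >= threshold)
  tibble(subpop = subpop %||% "all", n_nlr = n,
         n_core = n_core, n_dispensable = n - n_core,
         frac_core = if (n > 0) n_core / n else NA_real_,
         frac_dispensable = if (n > 0) (n - n_core) / n else NA_real_)
}

#' Integrated-domain enrichment across subpopulations
#'
#' For every domain x subpopulation, compares that subpopulation's
#' per-accession domain counts against all other accessions with a two-sided
#' Wilcoxon rank-sum test, adjusts across all tests with Benjamini-Hochberg,
#' and reports Z-score-transformed mean counts (scaled within each domain
#' across subpopulations) for display. Subpopulations with fewer than two
#' accessions are skipped with a warning.
#'
#' @param domain_counts Long tibble `accession_id, domain, count`
#'   (non-negative integers); accessions without a row for a domain count 0.
#' @param subpop Tibble `accession_id, subpop` or named vector.
#' @return Tibble `domain, subpop, mean_count, z_mean, p_value, adj_p`.
#' @export
domain_enrichment <- function(domain_counts, subpop) {
  .assert_cols(domain_counts, c("accession_id", "domain", "count"),
               "domain_counts")
  if (any(domain_counts$count < 0)) abort("domain counts must be non-negative")
  if (is.data.frame(subpop)) subpop <- setNames(subpop$subpop, subpop$accession_id)
  acc <- names(subpop)
  full <- tidyr::expand_grid(accession_id = acc,
                             domain = unique(domain_counts$domain)) |>
    left_join(domain_counts, by = c("accession_id", "domain")) |>
    mutate(count = tidyr::replace_na(.data$count, 0),
           subpop = subpop[.data$accession_id])

  sizes <- table(subpop)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(sprintf("subpopulation(s) with < 2 accessions skipped: %s",
                 paste(small, collapse = ", ")))
  }
  pops <- setdiff(names(sizes), small)
  out <- full |>
    group_by(.data$domain) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(pops, function(p) {
        x <- d$count[d$subpop == p]
        y <- d$count[d$subpop != p]
        pv <- if (length(y) == 0) NA_real_ else
          suppressWarnings(wilcox.test(x, y)$p.value)
        if (length(y) > 0 && is.na(pv)) pv <- 1   # no rank variation at all
        tibble(subpop = p, mean_count = mean(x), p_value = pv)
      })
    }) |>
    group_by(.data$domain) |>
    mutate(z_mean = if (n() > 1 && stats::sd(.data$mean_count) > 0)
      as.numeric(scale(.data$mean_count)) else 0) |>
    ungroup() |>
    mutate(adj_p = p.adjust(.data$p_value, method = "BH")) |>
    select("domain", "subpop", "mean_count", "z_mean", "p_value", "adj_p")
  out
}
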