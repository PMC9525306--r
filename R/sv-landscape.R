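#' Filter structural-variant calls
#'
#' Applies the five standard long-read SV filters: a call is removed if it
#' (1) is smaller than `min_len` or larger than `max_len`; (2) falls in an
#' assembly gap of the reference; (3) has a null genotype (no carrier across
#' the panel, or a literal `0/0` single-sample genotype); (4) is flagged
#' imprecise; or (5) has support depth below `min_depth`. A record failing
#' several rules increments each rule's rejection count; records with a
#' missing depth or precision flag are rejected under the corresponding rule
#' with a warning and counted separately.
#'
#' @param svs An `sv_set` (see [simulate_svs()], [read_sv_vcf()]) or a
#'   variants tibble with an optional `genotype` character column.
#' @param reference_gaps Tibble `chrom, start, end` of reference assembly
#'   gaps in BED convention (0-based half-open, sorted), or `NULL`.
#' @param min_len,max_len Length bounds in bp (defaults 50 and 1e6).
#' @param min_depth Minimum supporting-read depth (default 30).
#' @return An `sv_filter` object: `kept` (same shape as the input), `rejected`
#'   (variants plus logical `rule_*` columns), `rule_counts` tibble and
#'   `n_missing_field` counts. `tidy()` gives per-rule counts, `glance()` the
#'   totals.
#' @export
filter_svs <- function(svs, reference_gaps = NULL,
                       min_len = 50, max_len = 1e6, min_depth = 30) {
  is_set <- inherits(svs, "sv_set")
  v <- if (is_set) svs$variants else svs
  .assert_cols(v, c("sv_id", "chrom", "pos", "end", "svtype", "svlen"), "svs")

  r_size <- v$svlen < min_len | v$svlen > max_len

  r_gap <- rep(FALSE, nrow(v))
  if (!is.null(reference_gaps) && nrow(reference_gaps) > 0 && nrow(v) > 0) {
    # gaps are 0-based half-open; SV interval is 1-based closed [pos, end]
    for (ch in unique(reference_gaps$chrom)) {
      g <- reference_gaps[reference_gaps$chrom == ch, ]
      i <- which(v$chrom == ch)
      if (length(i) == 0) next
      hits <- IRanges::overlapsAny(
        .iranges(v$pos[i], pmax(v$pos[i], v$end[i])),
        .iranges(g$start + 1, g$end))
      r_gap[i] <- hits
    }
  }

  if (is_set) {
    carriers <- rowSums(svs$genotypes > 0, na.rm = TRUE)
    r_null_gt <- carriers == 0
  } else if ("genotype" %in% names(v)) {
    r_null_gt <- v$genotype %in% c("0/0", "0", "0|0")
  } else {
    r_null_gt <- rep(FALSE, nrow(v))
  }

  na_precise <- is.na(v$precise)
  r_imprecise <- na_precise | !v$precise
  na_depth <- is.na(v$support_depth)
  r_depth <- na_depth | v$support_depth < min_depth
  if (any(na_precise) || any(na_depth)) {
    warn(sprintf(
      "%d record(s) missing the precision flag and %d missing depth were rejected under the corresponding rules",
      sum(na_precise), sum(na_depth)))
  }

  rules <- cbind(size = r_size, gap = r_gap, null_genotype = r_null_gt,
                 imprecise = r_imprecise, low_depth = r_depth)
  keep <- rowSums(rules) == 0
  kept_v <- v[keep, , drop = FALSE]
  kept <- if (is_set) {
    structure(list(variants = kept_v,
                   genotypes = svs$genotypes[keep, , drop = FALSE]),
              class = "sv_set")
  } else kept_v
  rejected <- bind_cols(v[!keep, , drop = FALSE],
                        as_tibble(rules[!keep, , drop = FALSE],
                                  .name_repair = ~ paste0("rule_", .x)))
  structure(
    list(kept = kept, rejected = rejected,
         rule_counts = tibble(rule = colnames(rules),
                              n_rejected = as.integer(colSums(rules))),
         n_missing_field = c(precise = sum(na_precise), depth = sum(na_depth)),
         n_input = nrow(v), n_kept = sum(keep)),
    class = "sv_filter")
}

#' @export
print.sv_filter <- function(x, ...) {
  cat(sprintf("<sv_filter> kept %d / %d SVs\n", x$n_kept, x$n_input))
  print(x$rule_counts)
  invisible(x)
}

#' @export
tidy.sv_filter <- function(x, ...) x$rule_counts

#' @export
glance.sv_filter <- function(x, ...) {
  tibble(n_input = x$n_input, n_kept = x$n_kept,
         n_rejected = x$n_input - x$n_kept,
         n_missing_precise = unname(x$n_missing_field["precise"]),
         n_missing_depth = unname(x$n_missing_field["depth"]))
}

#' Size and frequency spectrum of an SV set
#'
#' Summarizes an SV panel the way pan-SV studies report it: the fraction of
#' SVs shorter than 1 kb, the minor-allele-frequency (MAF) histogram with the
#' fraction below 0.05, and the fraction shared by at least two accessions.
#' MAF is `min(f, 1 - f)` with `f` the carrier fraction over non-missing
#' accessions (haploid presence convention). SVs with all genotypes missing
#' are excluded from the MAF statistics and counted.
#'
#' @param svs An `sv_set`.
#' @param maf_breaks Histogram breaks on `[0, 0.5]`.
#' @return An `sv_spectrum` object; `glance()` returns the headline fractions,
#'   `tidy()` the MAF histogram.
#' @export
sv_spectrum <- function(svs, maf_breaks = seq(0, 0.5, by = 0.05)) {
  stopifnot(inherits(svs, "sv_set"))
  v <- svs$variants
  gt <- svs$genotypes
  n_typed <- rowSums(!is.na(gt))
  all_missing <- n_typed == 0
  carriers <- rowSums(gt > 0, na.rm = TRUE)
  f <- ifelse(all_missing, NA_real_, carriers / n_typed)
  maf <- pmin(f, 1 - f)
  hist_tbl <- tibble(
    maf_bin = cut(maf[!all_missing], breaks = maf_breaks,
                  include.lowest = TRUE, right = FALSE)) |>
    count(.data$maf_bin, name = "n_svs")
  structure(
    list(n_svs = nrow(v),
         frac_lt_1kb = mean(v$svlen < 1000),
         frac_maf_lt_0.05 = mean(maf[!all_missing] < 0.05),
         frac_shared = mean(carriers[!all_missing] >= 2),
         n_all_missing = sum(all_missing),
         maf = maf, maf_histogram = hist_tbl),
    class = "sv_spectrum")
}

#' @export
print.sv_spectrum <- function(x, ...) {
  cat(sprintf(
    "<sv_spectrum> %d SVs: %.1f%% < 1 kb; %.1f%% MAF < 0.05; %.1f%% shared by >= 2 accessions\n",
    x$n_svs, 100 * x$frac_lt_1kb, 100 * x$frac_maf_lt_0.05,
    100 * x$frac_shared))
  invisible(x)
}

#' @export
tidy.sv_spectrum <- function(x, ...) x$maf_histogram

#' @export
glance.sv_spectrum <- function(x, ...) {
  tibble(n_svs = x$n_svs, frac_lt_1kb = x$frac_lt_1kb,
         frac_maf_lt_0.05 = x$frac_maf_lt_0.05, frac_shared = x$frac_shared,
         n_all_missing = x$n_all_missing)
}

# sliding-window tiling (0-based half-open internally)
.tile_windows <- function(chrom_lengths, window, step) {
  if (!(window >= step && step > 0)) abort("need window >= step > 0")
  purrr::map_dfr(seq_len(nrow(chrom_lengths)), function(i) {
    L <- chrom_lengths$length[i]
    starts <- seq(0, max(L - window, 0), by = step)
    while (tail(starts, 1) + window < L) {
      starts <- c(starts, tail(starts, 1) + step)   # trailing partial windows
    }
    tibble(chrom = chrom_lengths$chrom[i], start = starts,
           end = pmin(starts + window, L))
  })
}

#' Count SV breakpoints in sliding windows
#'
#' Tiles each chromosome with `window`-sized windows every `step` bp
#' (0-based half-open; trailing partial windows included) and counts SV
#' breakpoints per window. Insertions and translocations contribute one
#' breakpoint (`pos`); deletions, inversions and duplications contribute two
#' (`pos` and `end`). A breakpoint in the overlap of two windows increments
#' both.
#'
#' @param svs An `sv_set` or variants tibble.
#' @param chrom_lengths Tibble `chrom, length`.
#' @param window,step Window and step size in bp (defaults 200 kb / 100 kb).
#' @return An `sv_windows` tibble: `chrom, start, end, n_breakpoints`
#'   (coordinates 0-based half-open).
#' @export
window_breakpoint_counts <- function(svs, chrom_lengths,
                                     window = 2e5, step = 1e5) {
  v <- if (inherits(svs, "sv_set")) svs$variants else svs
  .assert_cols(v, c("sv_id", "chrom", "pos", "end", "svtype"), "svs")
  .assert_cols(chrom_lengths, c("chrom", "length"), "chrom_lengths")
  len_of <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  bad <- !(v$chrom %in% names(len_of)) | v$pos > len_of[v$chrom] |
    (v$svtype %in% c("DEL", "INV", "DUP") & v$end > len_of[v$chrom])
  if (any(bad)) {
    abort(sprintf("SV beyond chromosome end: %s (%s:%d-%d)",
                  v$sv_id[bad][1], v$chrom[bad][1], v$pos[bad][1],
                  v$end[bad][1]))
  }
  two_bp <- v$svtype %in% c("DEL", "INV", "DUP")
  bp <- bind_rows(tibble(chrom = v$chrom, pos = v$pos),
                  tibble(chrom = v$chrom[two_bp], pos = v$end[two_bp]))

  win <- .tile_windows(chrom_lengths, window, step)
  win$n_breakpoints <- 0L
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    p <- bp$pos[bp$chrom == ch]
    if (length(p) == 0) next
    hits <- IRanges::countOverlaps(
      .iranges(win$start[wi] + 1, win$end[wi]),   # to 1-based closed
      .iranges(p, p))
    win$n_breakpoints[wi] <- as.integer(hits)
  }
  structure(win, class = c("sv_windows", class(win)),
            window = window, step = step)
}

#' Detect SV hotspot windows and regions
#'
#' Ranks windows by breakpoint count in descending order and flags the top
#' `floor(top_frac x n_windows)` as hotspots, breaking ties at the cutoff by
#' `(chrom, start)` order (strict rank: tied windows beyond the quota are not
#' included). Overlapping or adjacent flagged windows are merged into hotspot
#' regions.
#'
#' @param window_stats An `sv_windows` tibble ([window_breakpoint_counts()]).
#' @param top_frac Fraction of windows to flag (default 0.10).
#' @return An `sv_hotspots` object with `regions` (`chrom, start, end,
#'   n_windows_merged, peak_count`), `flagged` windows and the input
#'   `windows`.
#' @export
detect_hotspots <- function(window_stats, top_frac = 0.10) {
  .assert_cols(window_stats, c("chrom", "start", "end", "n_breakpoints"),
               "window_stats")
  W <- nrow(window_stats)
  if (W < 10) abort("hotspot detection needs at least 10 windows")
  if (all(window_stats$n_breakpoints == 0)) {
    warn("all window counts are zero; no hotspots")
    return(structure(list(regions = tibble(chrom = character(),
                                           start = numeric(), end = numeric(),
                                           n_windows_merged = integer(),
                                           peak_count = integer()),
                          flagged = window_stats[0, ],
                          windows = window_stats, top_frac = top_frac),
                     class = "sv_hotspots"))
  }
  n_top <- floor(top_frac * W)
  ord <- order(-window_stats$n_breakpoints, window_stats$chrom,
               window_stats$start)
  flagged <- window_stats[sort(ord[seq_len(n_top)]), ]

  regions <- flagged |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(new_region = cumsum(
      is.na(lag(.data$end)) | .data$start > lag(.data$end))) |>
    group_by(.data$chrom, .data$new_region) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows_merged = n(),
              peak_count = max(.data$n_breakpoints), .groups = "drop") |>
    select("chrom", "start", "end", "n_windows_merged", "peak_count") |>
    arrange(.data$chrom, .data$start)
  structure(list(regions = regions, flagged = flagged,
                 windows = window_stats, top_frac = top_frac),
            class = "sv_hotspots")
}

#' @export
print.sv_hotspots <- function(x, ...) {
  cat(sprintf("<sv_hotspots> %d hotspot window(s) in %d region(s) (top %.0f%% of %d windows)\n",
              nrow(x$flagged), nrow(x$regions), 100 * x$top_frac,
              nrow(x$windows)))
  print(x$regions)
  invisible(x)
}

#' @export
tidy.sv_hotspots <- function(x, ...) x$regions

#' @export
glance.sv_hotspots <- function(x, ...) {
  tibble(n_windows = nrow(x$windows), n_flagged = nrow(x$flagged),
         n_regions = nrow(x$regions), top_frac = x$top_frac)
}

#' Matched-size null simulation for SV hotspots
#'
#' Each replicate places the same number of SVs with exactly the observed
#' length and type multiset at uniform random positions on the reference
#' (per-chromosome probability proportional to length, optionally avoiding
#' declared gap intervals), then computes per-window breakpoint counts with
#' the same tiling as the observed data.
#'
#' @param svs Observed `sv_set` or variants tibble (post-filtering).
#' @param chrom_lengths Tibble `chrom, length`.
#' @param n_sim Number of replicates (default 100).
#' @param seed Integer seed.
#' @param reference_gaps Optional gaps tibble (BED convention) to avoid.
#' @param window,step Tiling parameters, matching the observed windows.
#' @return An `sv_null_windows` tibble: `replicate, chrom, start, end,
#'   n_breakpoints`.
#' @export
simulate_matched_null <- function(svs, chrom_lengths, n_sim = 100, seed = 1L,
                                  reference_gaps = NULL,
                                  window = 2e5, step = 1e5) {
  v <- if (inherits(svs, "sv_set")) svs$variants else svs
  if (nrow(v) == 0) abort("matched null needs a non-empty SV set")
  set.seed(.check_seed(seed))
  L <- chrom_lengths$length
  spanning <- v$svtype %in% c("DEL", "INV", "DUP")
  too_long <- spanning & v$svlen > max(L)
  if (any(too_long)) {
    abort(sprintf("SV %s is longer than every chromosome",
                  v$sv_id[too_long][1]))
  }
  gap_ir <- NULL
  if (!is.null(reference_gaps) && nrow(reference_gaps) > 0) {
    gap_ir <- split(.iranges(reference_gaps$start + 1, reference_gaps$end),
                    reference_gaps$chrom)
  }
  out <- vector("list", n_sim)
  for (r in seq_len(n_sim)) {
    sim <- .place_uniform(v, chrom_lengths, gap_ir)
    w <- window_breakpoint_counts(sim, chrom_lengths, window, step)
    out[[r]] <- mutate(as_tibble(w), replicate = r)
  }
  res <- bind_rows(out) |>
    select("replicate", "chrom", "start", "end", "n_breakpoints")
  structure(res, class = c("sv_null_windows", class(res)),
            window = window, step = step, n_sim = n_sim)
}

# place each SV uniformly; keep length/type; avoid gaps by resampling
.place_uniform <- function(v, chrom_lengths, gap_ir, max_tries = 20) {
  n <- nrow(v)
  span <- v$svtype %in% c("DEL", "INV", "DUP")
  # chromosomes able to host each SV
  ch_idx <- sample.int(nrow(chrom_lengths), n, replace = TRUE,
                       prob = chrom_lengths$length)
  L <- chrom_lengths$length[ch_idx]
  need <- ifelse(span, v$svlen, 1)
  redo <- need > L
  tries <- 0
  while (any(redo) && tries < max_tries) {
    ch_idx[redo] <- sample.int(nrow(chrom_lengths), sum(redo), replace = TRUE,
                               prob = chrom_lengths$length)
    L <- chrom_lengths$length[ch_idx]
    redo <- need > L
    tries <- tries + 1
  }
  if (any(redo)) {
    abort(sprintf("SV %s cannot be placed on any chromosome",
                  v$sv_id[redo][1]))
  }
  pos <- floor(runif(n, 1, L - need + 2))
  if (!is.null(gap_ir)) {
    for (t in seq_len(max_tries)) {
      in_gap <- rep(FALSE, n)
      for (ch in names(gap_ir)) {
        i <- which(chrom_lengths$chrom[ch_idx] == ch)
        if (length(i) == 0) next
        ends <- ifelse(span[i], pos[i] + v$svlen[i] - 1, pos[i])
        in_gap[i] <- IRanges::overlapsAny(.iranges(pos[i], ends), gap_ir[[ch]])
      }
      if (!any(in_gap)) break
      pos[in_gap] <- floor(runif(sum(in_gap), 1, L[in_gap] - need[in_gap] + 2))
    }
  }
  tibble(sv_id = v$sv_id, chrom = chrom_lengths$chrom[ch_idx],
         pos = as.integer(pos),
         end = as.integer(ifelse(span, pos + v$svlen - 1, pos)),
         svtype = v$svtype, svlen = v$svlen)
}

#' Wilcoxon test of observed window counts against the simulated null
#'
#' Two-sided Wilcoxon rank-sum test comparing the observed per-window
#' breakpoint counts against the pooled per-window counts of all null
#' replicates. The tilings must match; a single window is refused because the
#' test is undefined there.
#'
#' @param observed An `sv_windows` tibble.
#' @param null_sets An `sv_null_windows` tibble from
#'   [simulate_matched_null()].
#' @return One-row tibble `statistic, p_value, n_windows, n_null`.
#' @export
hotspot_significance <- function(observed, null_sets) {
  obs_key <- paste(observed$chrom, observed$start, observed$end)
  null_key <- null_sets |>
    distinct(.data$chrom, .data$start, .data$end)
  if (!setequal(obs_key, paste(null_key$chrom, null_key$start, null_key$end))) {
    abort("observed and null window tilings do not match")
  }
  if (nrow(observed) < 2) {
    abort("hotspot significance is undefined for a single window")
  }
  ht <- suppressWarnings(
    wilcox.test(observed$n_breakpoints, null_sets$n_breakpoints,
                alternative = "two.sided"))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n_windows = nrow(observed), n_null = nrow(null_sets))
}

#' Annotate SV-gene relationships
#'
#' Classifies every SV against the gene annotation: `contains-gene` if the SV
#' interval covers both endpoints of some gene, `overlaps-gene` for any other
#' intersection with a gene body, `within-flank` if it only intersects the
#' `flank`-bp extension around a gene, else `intergenic`. Also reports, per
#' gene, whether it is flanked by any SV (an SV overlapping the gene or its
#' flanks).
#'
#' @param svs An `sv_set` or variants tibble.
#' @param genes Tibble `gene_id, chrom, start, end` (1-based closed).
#' @param flank Flank size in bp (default 2000); must be non-negative.
#' @return An `sv_gene_annotation` object with `sv_annotation`
#'   (`sv_id, category`) and `gene_flags` (`gene_id, flanked`); `glance()`
#'   reports the fraction of genes flanked by SVs.
#' @export
annotate_sv_gene <- function(svs, genes, flank = 2000) {
  v <- if (inherits(svs, "sv_set")) svs$variants else svs
  if (flank < 0) abort("`flank` must be non-negative")
  .assert_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")

  sv_ir_end <- pmax(v$pos, v$end)
  category <- rep("intergenic", nrow(v))
  gene_flanked <- rep(FALSE, nrow(genes))
  for (ch in unique(v$chrom)) {
    si <- which(v$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) next
    sv_ir <- .iranges(v$pos[si], sv_ir_end[si])
    gene_ir <- .iranges(genes$start[gi], genes$end[gi])
    flank_ir <- .iranges(pmax(1, genes$start[gi] - flank),
                         genes$end[gi] + flank)
    # containment: SV covers both gene endpoints
    hit <- IRanges::findOverlaps(sv_ir, gene_ir)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    full <- v$pos[si][qh] <= genes$start[gi][sh] &
      sv_ir_end[si][qh] >= genes$end[gi][sh]
    category[si[unique(qh)]] <- "overlaps-gene"
    category[si[unique(qh[full])]] <- "contains-gene"
    flank_only <- IRanges::overlapsAny(sv_ir, flank_ir) &
      !IRanges::overlapsAny(sv_ir, gene_ir)
    category[si[flank_only]] <- "within-flank"
    gene_flanked[gi] <- gene_flanked[gi] |
      IRanges::overlapsAny(flank_ir, sv_ir)
  }
  structure(
    list(sv_annotation = tibble(sv_id = v$sv_id, category = category),
         gene_flags = tibble(gene_id = genes$gene_id, flanked = gene_flanked),
         flank = flank),
    class = "sv_gene_annotation")
}

#' @export
print.sv_gene_annotation <- function(x, ...) {
  tab <- table(x$sv_annotation$category)
  cat(sprintf("<sv_gene_annotation> %s; %.1f%% of genes flanked by SVs (flank %d bp)\n",
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              100 * mean(x$gene_flags$flanked), x$flank))
  invisible(x)
}

#' @export
tidy.sv_gene_annotation <- function(x, ...) x$sv_annotation

#' @export
glance.sv_gene_annotation <- function(x, ...) {
  tibble(n_svs = nrow(x$sv_annotation),
         n_genes = nrow(x$gene_flags),
         frac_genes_flanked = mean(x$gene_flags$flanked),
         frac_intergenic = mean(x$sv_annotation$category == "intergenic"))
}
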