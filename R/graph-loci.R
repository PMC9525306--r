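#' Overlap features with pan-genome graph bubbles
#'
#' Intersects per-accession feature intervals (NLR singletons, pairs,
#' clusters, or any gene features) with the accession's bubble paths on its
#' own contig coordinates, reporting one row per (feature, bubble)
#' intersection together with the bubble's pan-backbone projection. Bubbles
#' with no pan coordinates (uncalled by the graph aligner) are interpolated
#' linearly between the nearest two collinear flanking bubbles on the same
#' contig; uncalled bubbles without flanks on both sides are dropped as
#' non-collinear. Features on contigs absent from the bubble table (or
#' overlapping no bubble) are returned separately as unplaced.
#'
#' @param features Tibble `accession_id, feature_id, category, contig,
#'   start, end` (1-based closed, accession contig coordinates).
#' @param bubbles Tibble `bubble_id, pan_chrom, pan_start, pan_end,
#'   accession_id, contig, contig_start, contig_end, strand`; `pan_*` may be
#'   `NA` for uncalled bubbles.
#' @return List with `table` (feature columns + `bubble_id, pan_chrom,
#'   pan_start, pan_end`) and `unplaced` (features with a reason).
#' @export
overlap_features_with_bubbles <- function(features, bubbles) {
  .assert_cols(features, c("accession_id", "feature_id", "category",
                           "contig", "start", "end"), "features")
  .assert_cols(bubbles, c("bubble_id", "pan_chrom", "pan_start", "pan_end",
                          "accession_id", "contig", "contig_start",
                          "contig_end"), "bubbles")
  bad <- bubbles |>
    filter(!is.na(.data$pan_start), .data$pan_start >= .data$pan_end)
  if (nrow(bad) > 0) {
    abort(sprintf("bubble %s has pan_start >= pan_end", bad$bubble_id[1]))
  }
  incons <- bubbles |>
    filter(!is.na(.data$pan_start)) |>
    distinct(.data$bubble_id, .data$pan_chrom, .data$pan_start, .data$pan_end) |>
    count(.data$bubble_id) |>
    filter(.data$n > 1)
  if (nrow(incons) > 0) {
    abort(sprintf("inconsistent pan coordinates for bubble %s",
                  incons$bubble_id[1]))
  }

  bubbles <- .interpolate_uncalled(bubbles)

  rows <- list(); unplaced <- list()
  for (a in unique(features$accession_id)) {
    fa <- features[features$accession_id == a, ]
    ba <- bubbles[bubbles$accession_id == a, ]
    off_contig <- !(fa$contig %in% ba$contig)
    if (any(off_contig)) {
      unplaced[[length(unplaced) + 1]] <-
        mutate(fa[off_contig, ], reason = "contig not in bubble table")
    }
    fa <- fa[!off_contig, , drop = FALSE]
    matched <- rep(FALSE, nrow(fa))
    for (ctg in unique(fa$contig)) {
      fi <- which(fa$contig == ctg)
      bi <- which(ba$contig == ctg)
      hit <- IRanges::findOverlaps(
        .iranges(fa$start[fi], fa$end[fi]),
        .iranges(ba$contig_start[bi], ba$contig_end[bi]))
      qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
      if (length(qh) > 0) {
        rows[[length(rows) + 1]] <- bind_cols(
          fa[fi[qh], ],
          ba[bi[sh], c("bubble_id", "pan_chrom", "pan_start", "pan_end")])
        matched[fi[unique(qh)]] <- TRUE
      }
    }
    if (any(!matched)) {
      unplaced[[length(unplaced) + 1]] <-
        mutate(fa[!matched, ], reason = "no overlapping bubble")
    }
  }
  list(table = bind_rows(rows),
       unplaced = if (length(unplaced) > 0) bind_rows(unplaced) else
         mutate(features[0, ], reason = character(0)))
}

# linear interpolation of uncalled bubbles between collinear flanks
.interpolate_uncalled <- function(bubbles) {
  bubbles |>
    group_by(.data$accession_id, .data$contig) |>
    arrange(.data$contig_start, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      nas <- which(is.na(d$pan_start))
      for (i in nas) {
        before <- which(!is.na(d$pan_start) & seq_len(nrow(d)) < i)
        after <- which(!is.na(d$pan_start) & seq_len(nrow(d)) > i)
        if (length(before) == 0 || length(after) == 0) next
        lo <- max(before); hi <- min(after)
        if (d$pan_chrom[lo] != d$pan_chrom[hi]) next
        f <- (d$contig_start[i] - d$contig_start[lo]) /
          (d$contig_start[hi] - d$contig_start[lo])
        width <- d$contig_end[i] - d$contig_start[i]
        d$pan_chrom[i] <- d$pan_chrom[lo]
        d$pan_start[i] <- round(d$pan_end[lo] +
                                  f * (d$pan_start[hi] - d$pan_end[lo]))
        d$pan_end[i] <- d$pan_start[i] + max(width, 1)
      }
      d
    }) |>
    ungroup() |>
    filter(!is.na(.data$pan_start))
}

#' Infer collinear loci from a feature-bubble table
#'
#' Projects each feature onto the pan-genome backbone (the hull of its
#' overlapping bubbles' pan intervals) and single-linkage clusters the
#' projected intervals: features whose intervals strictly overlap share a
#' locus, mirroring interval-cluster behaviour. When two singleton features
#' of the same accession fall in the same bubble, the lexicographically
#' smaller feature id keeps the bubble's locus and each additional singleton
#' is re-assigned to a point locus exactly 1 bp beyond the bubble's pan end,
#' so displaced singletons from different accessions still co-locate.
#' Loci with a single member feature are excluded from the locus table and
#' listed separately.
#'
#' @param feature_bubble_table Output `table` of
#'   [overlap_features_with_bubbles()].
#' @return A `pan_loci` object: `loci` (`locus_id, pan_chrom, pan_start,
#'   pan_end, n_members`), `members` (feature -> locus), `excluded`
#'   (single-member loci).
#' @export
infer_loci <- function(feature_bubble_table) {
  tbl <- feature_bubble_table
  .assert_cols(tbl, c("accession_id", "feature_id", "category", "bubble_id",
                      "pan_chrom", "pan_start", "pan_end"), "feature table")
  if (any(is.na(tbl$pan_start))) {
    abort("pan coordinates must be present for all rows")
  }

  # 1 bp tie-break: extra same-accession singletons sharing a bubble
  displaced <- tbl |>
    filter(.data$category == "singleton") |>
    distinct(.data$accession_id, .data$feature_id, .data$bubble_id,
             .data$pan_chrom, .data$pan_end) |>
    group_by(.data$accession_id, .data$bubble_id) |>
    arrange(.data$feature_id, .by_group = TRUE) |>
    filter(row_number() > 1) |>
    ungroup() |>
    mutate(disp_point = .data$pan_end + 1)

  feat <- tbl |>
    anti_join(displaced,
              by = c("accession_id", "feature_id", "bubble_id")) |>
    group_by(.data$accession_id, .data$feature_id, .data$category,
             .data$pan_chrom) |>
    summarise(pan_start = min(.data$pan_start),
              pan_end = max(.data$pan_end), .groups = "drop")
  feat_disp <- displaced |>
    mutate(pan_start = .data$disp_point, pan_end = .data$disp_point,
           category = "singleton") |>
    select("accession_id", "feature_id", "category", "pan_chrom",
           "pan_start", "pan_end") |>
    # a displaced singleton may also overlap other bubbles; those rows were
    # dropped by the anti_join only for the shared bubble, so de-duplicate
    anti_join(feat, by = c("accession_id", "feature_id"))
  feat <- bind_rows(feat, feat_disp) |>
    arrange(.data$pan_chrom, .data$pan_start, .data$pan_end,
            .data$accession_id, .data$feature_id)

  # single-linkage chaining on strict overlap (closed intervals)
  feat <- feat |>
    group_by(.data$pan_chrom) |>
    mutate(run_max = cummax(dplyr::lag(.data$pan_end, default = -Inf)),
           new_locus = .data$pan_start > .data$run_max,
           locus_no = cumsum(.data$new_locus)) |>
    ungroup() |>
    mutate(locus_id = paste0(.data$pan_chrom, ":L", .data$locus_no))

  loci_all <- feat |>
    group_by(.data$locus_id, .data$pan_chrom) |>
    summarise(pan_start = min(.data$pan_start), pan_end = max(.data$pan_end),
              n_members = n(), .groups = "drop")
  single <- loci_all$locus_id[loci_all$n_members == 1]
  members <- feat |>
    select("locus_id", "accession_id", "feature_id", "category",
           "pan_chrom", "pan_start", "pan_end")
  structure(
    list(loci = loci_all |> filter(!.data$locus_id %in% single) |>
           arrange(.data$pan_chrom, .data$pan_start),
         members = members |> filter(!.data$locus_id %in% single),
         excluded = members |> filter(.data$locus_id %in% single)),
    class = "pan_loci")
}

#' @export
print.pan_loci <- function(x, ...) {
  cat(sprintf("<pan_loci> %d multi-member loci (%d member features; %d single-member features excluded)\n",
              nrow(x$loci), nrow(x$members), nrow(x$excluded)))
  invisible(x)
}

#' @export
tidy.pan_loci <- function(x, ...) x$members

#' @export
glance.pan_loci <- function(x, ...) {
  tibble(n_loci = nrow(x$loci), n_members = nrow(x$members),
         n_excluded_single = nrow(x$excluded))
}

#' Per-locus, per-subpopulation mean copy number
#'
#' For each locus and subpopulation, the mean number of member features per
#' accession of that subpopulation, counting accessions with no member at the
#' locus as zero.
#'
#' @param loci A `pan_loci` object from [infer_loci()].
#' @param subpop Tibble `accession_id, subpop` or named vector covering all
#'   accessions of the panel (including those absent from every locus).
#' @return Tibble `locus_id, subpop, mean_members`.
#' @export
locus_copy_number <- function(loci, subpop) {
  stopifnot(inherits(loci, "pan_loci"))
  if (is.data.frame(subpop)) subpop <- setNames(subpop$subpop, subpop$accession_id)
  pop_sizes <- table(subpop)
  counts <- loci$members |>
    count(.data$locus_id, .data$accession_id) |>
    mutate(subpop = unname(subpop[.data$accession_id]))
  if (any(is.na(counts$subpop))) {
    abort("member accession(s) missing from the subpopulation map")
  }
  tidyr::expand_grid(locus_id = loci$loci$locus_id,
                     subpop = names(pop_sizes)) |>
    left_join(counts |>
                group_by(.data$locus_id, .data$subpop) |>
                summarise(total = sum(.data$n), .groups = "drop"),
              by = c("locus_id", "subpop")) |>
    mutate(total = tidyr::replace_na(.data$total, 0L),
           mean_members = .data$total / as.numeric(pop_sizes[.data$subpop])) |>
    select("locus_id", "subpop", "mean_members")
}
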