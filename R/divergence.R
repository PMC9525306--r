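#' Per-site Weir-Cockerham FST variance components
#'
#' Computes the Weir & Cockerham (1984) estimator for haploid data at every
#' site of a two-population haplotype panel, via the one-way ANOVA form:
#' with population allele frequencies `p_i`, sample sizes `n_i`,
#' `MSP = sum n_i (p_i - p_bar)^2 / (r - 1)` the between-population mean
#' square, `MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)` the within-population
#' mean square, and `n_c` the effective sample size, the between component is
#' `a = (MSP - MSG) / n_c`, the within component is `MSG`, and
#' `FST = a / (a + within)`. Negative per-site values are retained (not
#' clamped). Monomorphic sites get components `(0, 0)` and an undefined
#' ratio; they are flagged `usable = FALSE` and excluded from ratio averages
#' but still contribute (zero) to windowed ratio-of-sums.
#'
#' Inbred rice is treated as haploid; there is no heterozygosity term.
#'
#' @param haplotypes A `hap_set` from [simulate_haplotypes()], or a 0/1
#'   matrix (haplotype x site, `NA` = missing) with `pop` supplied.
#' @param pop Population label per haplotype row (ignored for a `hap_set`).
#' @param positions Site positions (ignored for a `hap_set`).
#' @return Tibble `pos, p1, p2, n1, n2, a, within, fst, usable`.
#' @export
fst_per_site <- function(haplotypes, pop = NULL, positions = NULL) {
  if (inherits(haplotypes, "hap_set")) {
    pop <- haplotypes$pop
    positions <- haplotypes$positions
    haplotypes <- haplotypes$haplotypes
  }
  pops <- unique(pop)
  if (length(pops) != 2) abort("exactly two populations are required")
  H1 <- haplotypes[pop == pops[1], , drop = FALSE]
  H2 <- haplotypes[pop == pops[2], , drop = FALSE]
  n1 <- colSums(!is.na(H1)); n2 <- colSums(!is.na(H2))
  if (any(n1 < 2 | n2 < 2) && ncol(haplotypes) > 0) {
    abort("each population needs >= 2 non-missing calls at every site")
  }
  p1 <- colMeans(H1, na.rm = TRUE); p2 <- colMeans(H2, na.rm = TRUE)
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  r <- 2
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - r)
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  a <- (msp - msg) / nc
  within <- msg
  mono <- pbar == 0 | pbar == 1
  a[mono] <- 0; within[mono] <- 0
  fst <- ifelse(a + within == 0, NA_real_, a / (a + within))
  tibble(pos = positions %||% seq_along(p1),
         p1 = p1, p2 = p2, n1 = as.integer(n1), n2 = as.integer(n2),
         a = a, within = within, fst = fst, usable = !mono & (a + within) != 0)
}

#' Windowed Weir-Cockerham FST
#'
#' Aggregates per-site variance components into windows using the
#' ratio-of-sums form (`sum a / sum (a + within)`), the recommended
#' aggregation for the Weir-Cockerham estimator; a mean-of-ratios mode is
#' available for comparison. Windows default to non-overlapping 20 kb tiles
#' (step = window); windows with no usable site report `NA`.
#'
#' @param sites Per-site tibble from [fst_per_site()] (must be position
#'   sorted; unsorted input is sorted with a warning).
#' @param region_length Length of the scanned region in bp.
#' @param window,step Window and step in bp; `step` defaults to `window`.
#' @param mode `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @param chrom Chromosome label for the output.
#' @return A `divergence_windows` tibble: `chrom, start, end, fst, n_sites`.
#' @export
windowed_fst <- function(sites, region_length, window = 2e4, step = window,
                         mode = c("ratio_of_sums", "mean_of_ratios"),
                         chrom = "chr1") {
  mode <- match.arg(mode)
  if (is.unsorted(sites$pos)) {
    warn("sites were not position-sorted; sorting")
    sites <- arrange(sites, .data$pos)
  }
  win <- .tile_windows(tibble(chrom = chrom, length = region_length),
                       window, step)
  stat <- purrr::map_dfr(seq_len(nrow(win)), function(i) {
    s <- sites[sites$pos > win$start[i] & sites$pos <= win$end[i], ]
    usable <- s[s$usable, ]
    fst <- if (mode == "ratio_of_sums") {
      denom <- sum(s$a + s$within)
      if (nrow(usable) == 0 || denom == 0) NA_real_ else sum(s$a) / denom
    } else {
      if (nrow(usable) == 0) NA_real_ else mean(usable$fst)
    }
    tibble(fst = fst, n_sites = nrow(usable))
  })
  out <- bind_cols(win, stat)
  structure(out, class = c("divergence_windows", class(out)),
            window = window, step = step, statistic = "fst")
}

#' Windowed absolute divergence (Dxy)
#'
#' For each window, `Dxy = sum over sites of [p1 (1 - p2) + p2 (1 - p1)]`
#' divided by the window length in bp — the mean per-bp pairwise difference
#' between cross-population haplotype pairs. Invariant sites contribute zero,
#' so only segregating sites need to be supplied.
#'
#' @param haplotypes A `hap_set`, or a matrix with `pop`/`positions`.
#' @param window,step Window and step in bp (step defaults to window).
#' @inheritParams fst_per_site
#' @return A `divergence_windows` tibble: `chrom, start, end, dxy, n_sites`.
#' @export
windowed_dxy <- function(haplotypes, window = 2e4, step = window,
                         pop = NULL, positions = NULL) {
  if (inherits(haplotypes, "hap_set")) {
    region_length <- haplotypes$region_length
    chrom <- haplotypes$chrom
    pop <- haplotypes$pop
    positions <- haplotypes$positions
    H <- haplotypes$haplotypes
  } else {
    H <- haplotypes
    region_length <- max(positions)
    chrom <- "chr1"
  }
  if (window <= 0) abort("window length must be positive")
  pops <- unique(pop)
  if (length(pops) != 2) abort("exactly two populations are required")
  p1 <- colMeans(H[pop == pops[1], , drop = FALSE], na.rm = TRUE)
  p2 <- colMeans(H[pop == pops[2], , drop = FALSE], na.rm = TRUE)
  d <- p1 * (1 - p2) + p2 * (1 - p1)

  win <- .tile_windows(tibble(chrom = chrom, length = region_length),
                       window, step)
  stat <- purrr::map_dfr(seq_len(nrow(win)), function(i) {
    inw <- positions > win$start[i] & positions <= win$end[i]
    tibble(dxy = sum(d[inw]) / (win$end[i] - win$start[i]),
           n_sites = sum(inw))
  })
  out <- bind_cols(win, stat)
  structure(out, class = c("divergence_windows", class(out)),
            window = window, step = step, statistic = "dxy")
}

#' Select top divergent regions
#'
#' Flags the `floor(frac x n)` windows with the highest value of the chosen
#' statistic (ties at the cutoff broken by genomic order) and merges adjacent
#' selected windows into regions. Windows with missing values are excluded
#' from ranking; if every defined value is identical the quota is filled in
#' genomic order with a warning.
#'
#' @param windows A `divergence_windows` tibble with an `fst` or `dxy`
#'   column.
#' @param frac Fraction of windows to select (default 0.05).
#' @param statistic Column to rank on; defaults to the tibble's statistic.
#' @return Tibble of merged regions `chrom, start, end, n_windows_merged,
#'   peak_value`.
#' @export
top_divergent_regions <- function(windows, frac = 0.05, statistic = NULL) {
  statistic <- statistic %||% attr(windows, "statistic") %||%
    intersect(c("fst", "dxy"), names(windows))[1]
  vals <- windows[[statistic]]
  defined <- which(!is.na(vals))
  if (length(defined) == 0) {
    warn("all window values are missing; no regions selected")
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows_merged = integer(), peak_value = numeric()))
  }
  if (length(defined) < 20) abort("need >= 20 windows with defined values")
  if (length(unique(vals[defined])) == 1) {
    warn("statistic is constant across windows; selecting by genomic order")
  }
  n_top <- floor(frac * length(defined))
  ord <- defined[order(-vals[defined], windows$chrom[defined],
                       windows$start[defined])]
  sel <- windows[sort(ord[seq_len(n_top)]), ]
  sel$.val <- sel[[statistic]]
  sel |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(new_region = cumsum(
      is.na(lag(.data$end)) | .data$start > lag(.data$end))) |>
    group_by(.data$chrom, .data$new_region) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows_merged = n(), peak_value = max(.data$.val),
              .groups = "drop") |>
    select("chrom", "start", "end", "n_windows_merged", "peak_value") |>
    arrange(.data$chrom, .data$start)
}
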