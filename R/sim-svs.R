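#' Simulate a structural-variant call set
#'
#' Places `cfg$n_svs` SVs on the reference chromosomes. Positions are uniform
#' per bp outside any injected hotspot region and multiplied by the region's
#' enrichment factor inside it; lengths come from the configured lognormal
#' mixture truncated to `cfg$length_range`; types are drawn by weight. Each
#' variant gets haploid presence/absence genotypes over the accession panel
#' with a carrier frequency drawn from `cfg$maf_spectrum`, a support depth,
#' and a precision flag, so the output is directly serializable to a
#' Sniffles-dialect VCF via [write_sv_vcf()].
#'
#' @param cfg An [sv_sim_config()].
#' @param chrom_lengths Tibble with columns `chrom, length` (bp).
#'
#' @return An `sv_set`: list with `variants` (tibble `sv_id, chrom, pos, end,
#'   svtype, svlen, support_depth, precise`) and `genotypes` (0/1 integer
#'   matrix, SV x accession, `NA` = missing).
#' @export
#' @examples
#' cl <- tibble::tibble(chrom = "chr1", length = 1e6)
#' svs <- simulate_svs(sv_sim_config(100, seed = 3), cl)
simulate_svs <- function(cfg, chrom_lengths) {
  stopifnot(inherits(cfg, "sv_sim_config"))
  .assert_cols(chrom_lengths, c("chrom", "length"), "chrom_lengths")
  if (any(chrom_lengths$length <= 0)) abort("chromosome lengths must be positive")
  set.seed(.substream(cfg$seed, 2L))

  acc <- sprintf("ACC%03d", seq_len(cfg$n_accessions))
  if (cfg$n_svs == 0) {
    return(structure(
      list(variants = tibble(sv_id = character(), chrom = character(),
                             pos = integer(), end = integer(),
                             svtype = character(), svlen = integer(),
                             support_depth = integer(), precise = logical()),
           genotypes = matrix(integer(), nrow = 0, ncol = cfg$n_accessions,
                              dimnames = list(NULL, acc))),
      class = "sv_set"))
  }

  seg <- .weighted_segments(chrom_lengths, cfg$hotspot_regions)
  seg_p <- seg$weight * (seg$end - seg$start + 1)
  pick <- sample.int(nrow(seg), cfg$n_svs, replace = TRUE, prob = seg_p)
  pos <- floor(runif(cfg$n_svs, seg$start[pick], seg$end[pick] + 1))
  chrom <- seg$chrom[pick]

  svlen <- .draw_lengths(cfg$length_mixture, cfg$n_svs, cfg$length_range)
  svtype <- sample(names(cfg$type_weights), cfg$n_svs, replace = TRUE,
                   prob = cfg$type_weights)
  len_of <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  spanning <- svtype %in% c("DEL", "INV", "DUP")
  # keep spanning SVs inside the chromosome
  too_long <- spanning & svlen > len_of[chrom]
  if (any(too_long)) {
    svlen[too_long] <- pmax(50, floor(len_of[chrom[too_long]] / 2))
  }
  shift <- spanning & (pos + svlen - 1 > len_of[chrom])
  pos[shift] <- len_of[chrom[shift]] - svlen[shift] + 1
  end <- ifelse(spanning, pos + svlen - 1, pos)

  f <- .draw_spectrum(cfg$maf_spectrum, cfg$n_svs)
  gt <- matrix(rbinom(cfg$n_svs * cfg$n_accessions, 1, rep(f, cfg$n_accessions)),
               nrow = cfg$n_svs,
               dimnames = list(sprintf("SV%06d", seq_len(cfg$n_svs)), acc))

  variants <- tibble(
    sv_id = rownames(gt), chrom = chrom,
    pos = as.integer(pos), end = as.integer(end),
    svtype = svtype, svlen = as.integer(svlen),
    support_depth = rpois(cfg$n_svs, 60),
    precise = runif(cfg$n_svs) < 0.97) |>
    arrange(.data$chrom, .data$pos)
  structure(list(variants = variants,
                 genotypes = gt[variants$sv_id, , drop = FALSE]),
            class = "sv_set")
}

#' @export
as_tibble.sv_set <- function(x, ...) x$variants

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf("<sv_set> %d SVs x %d accessions\n",
              nrow(x$variants), ncol(x$genotypes)))
  print(x$variants, ...)
  invisible(x)
}

# split chromosomes into constant-weight segments around hotspot regions
.weighted_segments <- function(chrom_lengths, hotspots) {
  base <- tibble(chrom = chrom_lengths$chrom, start = 1,
                 end = chrom_lengths$length, weight = 1)
  if (is.null(hotspots) || nrow(hotspots) == 0) return(base)
  len_of <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  bad <- !(hotspots$chrom %in% names(len_of)) |
    hotspots$start < 1 | hotspots$end > len_of[hotspots$chrom] |
    hotspots$start > hotspots$end
  if (any(bad)) {
    abort(sprintf("hotspot region outside chromosome bounds: %s:%s-%s",
                  hotspots$chrom[bad][1], hotspots$start[bad][1],
                  hotspots$end[bad][1]))
  }
  out <- list()
  for (ch in chrom_lengths$chrom) {
    L <- len_of[[ch]]
    hs <- hotspots[hotspots$chrom == ch, , drop = FALSE]
    hs <- hs[order(hs$start), , drop = FALSE]
    cur <- 1
    for (i in seq_len(nrow(hs))) {
      if (hs$start[i] > cur) {
        out[[length(out) + 1]] <- tibble(chrom = ch, start = cur,
                                         end = hs$start[i] - 1, weight = 1)
      }
      out[[length(out) + 1]] <- tibble(chrom = ch, start = hs$start[i],
                                       end = hs$end[i],
                                       weight = hs$multiplier[i])
      cur <- hs$end[i] + 1
    }
    if (cur <= L) {
      out[[length(out) + 1]] <- tibble(chrom = ch, start = cur, end = L,
                                       weight = 1)
    }
  }
  bind_rows(out)
}

.draw_lengths <- function(mixture, n, range) {
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  meanlog <- vapply(mixture, function(m) m$meanlog, numeric(1))[comp]
  sdlog <- vapply(mixture, function(m) m$sdlog, numeric(1))[comp]
  len <- rlnorm(n, meanlog, sdlog)
  # resample out-of-range draws once, then clamp the stragglers
  bad <- len < range[1] | len > range[2]
  if (any(bad)) {
    len[bad] <- rlnorm(sum(bad), meanlog[bad], sdlog[bad])
    len <- pmin(pmax(len, range[1]), range[2])
  }
  round(len)
}
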