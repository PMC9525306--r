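#' Simulate a multi-subpopulation pan-genome
#'
#' Generates per-accession gene annotations, an OrthoFinder-style orthogroup
#' membership table and a truth table under the study conditions described by
#' a [pangenome_sim_config()]. Core orthogroups are present in every
#' accession; each dispensable orthogroup draws a presence probability from
#' the configured frequency spectrum and is then present independently per
#' accession at that frequency. Every orthogroup has a fixed home chromosome
#' and a fixed position in gene order shared by all accessions (so gene order
#' is collinear across the panel); NLR orthogroups are inserted next to
#' already-placed NLRs with probability `nlr_cluster_bias`. Gene coordinates
#' are non-overlapping within a chromosome, with gene lengths and intergenic
#' gaps drawn per accession.
#'
#' Each present orthogroup contributes one gene model per accession; tandem
#' paralog expansion is not simulated.
#'
#' @param cfg A [pangenome_sim_config()].
#'
#' @return A `pan_sim` list with elements
#'   \describe{
#'     \item{genes}{tibble of gene records: `gene_id, accession_id, chrom,
#'       start, end, strand, orthogroup_id, is_nlr` (1-based closed
#'       coordinates).}
#'     \item{orthogroups}{wide tibble, one row per orthogroup, one column per
#'       accession, cells comma-separated gene ids or `""`.}
#'     \item{truth}{list: `orthogroup` tibble (`orthogroup_id, class,
#'       presence_prob, is_nlr, chrom`), `accessions` tibble (`accession_id,
#'       subpop`), and the realized logical `presence` matrix.}
#'   }
#' @export
#' @examples
#' sim <- simulate_pangenome(pangenome_sim_config(c(A = 3, B = 2), 20, 30, seed = 7))
#' dplyr::count(sim$genes, accession_id)
simulate_pangenome <- function(cfg) {
  stopifnot(inherits(cfg, "pangenome_sim_config"))
  set.seed(.substream(cfg$seed, 1L))

  subpops <- rep(names(cfg$n_accessions_per_subpop), cfg$n_accessions_per_subpop)
  acc <- paste0(subpops, "_", unlist(lapply(cfg$n_accessions_per_subpop, seq_len)))
  n_acc <- length(acc)
  n_og <- cfg$n_core_orthogroups + cfg$n_dispensable_orthogroups
  og <- sprintf("OG%05d", seq_len(n_og))
  og_class <- rep(c("core", "dispensable"),
                  c(cfg$n_core_orthogroups, cfg$n_dispensable_orthogroups))

  p_presence <- rep(1, n_og)
  if (cfg$n_dispensable_orthogroups > 0) {
    p_presence[og_class == "dispensable"] <-
      .draw_spectrum(cfg$dispensable_freq_spectrum, cfg$n_dispensable_orthogroups)
  }
  n_nlr <- round(cfg$nlr_fraction * n_og)
  is_nlr <- rep(FALSE, n_og)
  if (n_nlr > 0) is_nlr[sample.int(n_og, n_nlr)] <- TRUE

  presence <- matrix(rbinom(n_og * n_acc, 1, rep(p_presence, n_acc)) == 1,
                     nrow = n_og, dimnames = list(og, acc))
  presence[og_class == "core", ] <- TRUE

  # shared chromosome assignment and gene order (collinear across accessions)
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  og_chrom <- sample(chrom_names, n_og, replace = TRUE)
  order_by_chrom <- lapply(chrom_names, function(ch) {
    idx <- which(og_chrom == ch)
    .order_with_nlr_bias(idx, is_nlr[idx], cfg$nlr_cluster_bias)
  })
  names(order_by_chrom) <- chrom_names

  genes <- vector("list", n_acc)
  for (a in seq_len(n_acc)) {
    per_chrom <- vector("list", length(chrom_names))
    for (ci in seq_along(chrom_names)) {
      ch <- chrom_names[ci]
      idx <- order_by_chrom[[ch]]
      idx <- idx[presence[idx, a]]
      ng <- length(idx)
      if (ng == 0) next
      len <- round(runif(ng, 1000, 4000))
      gap <- round(runif(ng, 500, 2000))
      start <- cumsum(gap) + cumsum(c(0, len[-ng])) + 1
      end <- start + len - 1
      if (end[ng] > cfg$chrom_length_bp) {
        abort(sprintf(
          "chromosome %s of accession %s is too short: %d genes need %.0f bp but only %.0f bp available (deficit %.0f bp)",
          ch, acc[a], ng, end[ng], cfg$chrom_length_bp,
          end[ng] - cfg$chrom_length_bp))
      }
      per_chrom[[ci]] <- tibble(
        accession_id = acc[a], chrom = ch,
        start = start, end = end,
        strand = sample(c("+", "-"), ng, replace = TRUE),
        orthogroup_id = og[idx], is_nlr = is_nlr[idx])
    }
    genes[[a]] <- bind_rows(per_chrom)
  }
  genes <- bind_rows(genes) |>
    group_by(.data$accession_id) |>
    arrange(.data$chrom, .data$start, .by_group = TRUE) |>
    mutate(gene_id = sprintf("%s_g%04d", .data$accession_id, row_number())) |>
    ungroup() |>
    select("gene_id", "accession_id", "chrom", "start", "end", "strand",
           "orthogroup_id", "is_nlr")

  # wide orthogroup membership table (OrthoFinder layout)
  member <- matrix("", nrow = n_og, ncol = n_acc, dimnames = list(og, acc))
  cell <- genes |>
    group_by(.data$orthogroup_id, .data$accession_id) |>
    summarise(ids = paste(.data$gene_id, collapse = ","), .groups = "drop")
  member[cbind(match(cell$orthogroup_id, og), match(cell$accession_id, acc))] <-
    cell$ids
  orthogroups <- bind_cols(tibble(orthogroup_id = og),
                           as_tibble(member, .name_repair = "minimal"))

  structure(
    list(genes = genes,
         orthogroups = orthogroups,
         truth = list(
           orthogroup = tibble(orthogroup_id = og, class = og_class,
                               presence_prob = p_presence, is_nlr = is_nlr,
                               chrom = og_chrom),
           accessions = tibble(accession_id = acc, subpop = subpops),
           presence = presence)),
    class = "pan_sim")
}

# Order orthogroup indices on one chromosome. Non-NLRs are shuffled first;
# NLRs are then inserted one by one, adjacent to a random already-placed NLR
# with probability `bias` (keeping NLR runs contiguous at bias = 1), otherwise
# at a uniform random slot.
.order_with_nlr_bias <- function(idx, nlr, bias) {
  shuf <- function(x) x[sample.int(length(x))]  # length-1 safe
  ord <- shuf(idx[!nlr])
  for (g in shuf(idx[nlr])) {
    placed_nlr <- which(ord %in% idx[nlr])
    if (length(placed_nlr) > 0 && runif(1) < bias) {
      at <- placed_nlr[sample.int(length(placed_nlr), 1)]  # right after an NLR
    } else {
      at <- sample.int(length(ord) + 1L, 1) - 1L  # uniform slot (0 = front)
    }
    ord <- append(ord, g, after = at)
  }
  ord
}
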