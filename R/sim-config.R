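#' Configuration for the synthetic pan-genome generator
#'
#' Defines the study conditions emulated by [simulate_pangenome()]: a panel of
#' inbred accessions split into subpopulations, a set of core orthogroups
#' present in every accession, and a set of dispensable orthogroups whose
#' per-accession presence is Bernoulli with an orthogroup-specific frequency
#' drawn from `dispensable_freq_spectrum`. A configurable fraction of
#' orthogroups is flagged as NLR (nucleotide-binding leucine-rich repeat
#' immune genes), and `nlr_cluster_bias` controls how strongly NLRs are placed
#' next to other NLRs in gene order, mimicking the clustered organisation of
#' resistance genes in plant genomes.
#'
#' @param n_accessions_per_subpop Named integer vector, accessions per
#'   subpopulation (e.g. `c(Osi = 10, Or = 5)`).
#' @param n_core_orthogroups Number of core orthogroups (present everywhere).
#' @param n_dispensable_orthogroups Number of dispensable orthogroups.
#' @param dispensable_freq_spectrum List naming the presence-probability
#'   distribution. Default `list(name = "beta", shape1 = 0.5, shape2 = 1.5)`,
#'   a rare-skewed spectrum with many low-frequency genes. A constant spectrum
#'   is available as `list(name = "constant", p = 0.5)`.
#' @param n_chromosomes Chromosomes per accession.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param nlr_fraction Fraction of orthogroups flagged as NLR, in `[0, 1]`.
#' @param nlr_cluster_bias Probability that an NLR orthogroup is placed
#'   adjacent to an already-placed NLR on its chromosome, in `[0, 1]`.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A `pangenome_sim_config` list.
#' @export
#' @examples
#' cfg <- pangenome_sim_config(c(Osi = 4, Or = 3), 50, 100, seed = 1)
pangenome_sim_config <- function(n_accessions_per_subpop,
                                 n_core_orthogroups,
                                 n_dispensable_orthogroups,
                                 dispensable_freq_spectrum =
                                   list(name = "beta", shape1 = 0.5, shape2 = 1.5),
                                 n_chromosomes = 2L,
                                 chrom_length_bp = 5e6,
                                 nlr_fraction = 0.05,
                                 nlr_cluster_bias = 0.7,
                                 seed = 1L) {
  if (is.null(names(n_accessions_per_subpop)) ||
      any(names(n_accessions_per_subpop) == "")) {
    abort("`n_accessions_per_subpop` must be a named vector (subpop -> count)")
  }
  counts <- c(n_accessions_per_subpop, n_core_orthogroups,
              n_dispensable_orthogroups, n_chromosomes, chrom_length_bp)
  if (any(counts < 0)) abort("all counts must be >= 0")
  if (nlr_fraction < 0 || nlr_fraction > 1) abort("`nlr_fraction` must be in [0, 1]")
  if (nlr_cluster_bias < 0 || nlr_cluster_bias > 1) {
    abort("`nlr_cluster_bias` must be in [0, 1]")
  }
  spec <- dispensable_freq_spectrum
  if (!is.list(spec) || is.null(spec$name)) {
    abort("`dispensable_freq_spectrum` must be a list with a `name` element")
  }
  if (identical(spec$name, "constant") &&
      (spec$p <= 0 || spec$p >= 1)) {
    abort("constant presence probability must be in (0, 1)")
  }
  structure(
    list(n_accessions_per_subpop = n_accessions_per_subpop,
         n_core_orthogroups = as.integer(n_core_orthogroups),
         n_dispensable_orthogroups = as.integer(n_dispensable_orthogroups),
         dispensable_freq_spectrum = spec,
         n_chromosomes = as.integer(n_chromosomes),
         chrom_length_bp = as.numeric(chrom_length_bp),
         nlr_fraction = nlr_fraction,
         nlr_cluster_bias = nlr_cluster_bias,
         seed = .check_seed(seed)),
    class = "pangenome_sim_config")
}

#' Configuration for the synthetic structural-variant generator
#'
#' Defines the SV call set emulated by [simulate_svs()]: positions uniform on
#' the reference (optionally enriched inside injected hotspot regions), a
#' lognormal length mixture truncated to the callable range, SV types drawn by
#' weight, and haploid presence/absence genotypes over an accession panel with
#' per-variant carrier frequencies from `maf_spectrum`.
#'
#' @param n_svs Number of SVs to simulate.
#' @param length_mixture List of components `list(weight, meanlog, sdlog)`
#'   (bp, lognormal). Weights must sum to 1. The default mixture places the
#'   majority of SVs below 1 kb, the size structure typical of long-read rice
#'   SV call sets.
#' @param type_weights Named weights over SVTYPEs (`DEL`, `INS`, `INV`, `DUP`,
#'   `TRA`); must sum to 1.
#' @param maf_spectrum Allele-frequency distribution for carriers; default
#'   `list(name = "beta", shape1 = 0.3, shape2 = 3)`, a rare-dominated
#'   spectrum. `list(name = "constant", p = …)` is also accepted.
#' @param hotspot_regions Optional tibble `chrom, start, end, multiplier`
#'   (1-based closed) of injected hotspots; SV density inside is multiplied
#'   by `multiplier`.
#' @param n_accessions Size of the genotyped accession panel.
#' @param length_range Hard truncation of simulated lengths, default
#'   `c(50, 1e6)` (the callable range); set wider only to exercise filters.
#' @param seed Integer seed.
#'
#' @return An `sv_sim_config` list.
#' @export
sv_sim_config <- function(n_svs,
                          length_mixture = list(
                            list(weight = 0.75, meanlog = log(300), sdlog = 0.9),
                            list(weight = 0.25, meanlog = log(5000), sdlog = 1.1)),
                          type_weights = c(DEL = 0.45, INS = 0.40, INV = 0.05,
                                           DUP = 0.08, TRA = 0.02),
                          maf_spectrum = list(name = "beta", shape1 = 0.3, shape2 = 3),
                          hotspot_regions = NULL,
                          n_accessions = 25L,
                          length_range = c(50, 1e6),
                          seed = 1L) {
  if (n_svs < 0) abort("`n_svs` must be >= 0")
  w <- vapply(length_mixture, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) abort("length_mixture weights must sum to 1")
  if (abs(sum(type_weights) - 1) > 1e-8) abort("type_weights must sum to 1")
  if (!is.null(hotspot_regions)) {
    .assert_cols(hotspot_regions, c("chrom", "start", "end", "multiplier"),
                 "hotspot_regions")
    if (any(hotspot_regions$multiplier < 0)) abort("hotspot multipliers must be >= 0")
  }
  structure(
    list(n_svs = as.integer(n_svs), length_mixture = length_mixture,
         type_weights = type_weights, maf_spectrum = maf_spectrum,
         hotspot_regions = hotspot_regions,
         n_accessions = as.integer(n_accessions),
         length_range = length_range, seed = .check_seed(seed)),
    class = "sv_sim_config")
}

#' Configuration for the synthetic two-population haplotype generator
#'
#' Defines the biallelic haplotype panel emulated by [simulate_haplotypes()]:
#' two populations of haploid genotypes at `n_sites` distinct positions in a
#' region, with per-site allele frequencies following `divergence_profile`.
#'
#' @param n_hap_per_pop Integer (shared) or length-2 vector of haplotype
#'   counts for the two populations.
#' @param n_sites Number of biallelic sites; must not exceed
#'   `region_length_bp`.
#' @param region_length_bp Region length in bp.
#' @param divergence_profile Either `list(name = "constant", p1 =, p2 =)` for
#'   a flat schedule, `list(name = "block", p1 =, p2 =, block_start =,
#'   block_end =, block_p1 =, block_p2 =)` for a step-change of divergence
#'   inside a coordinate block, or a tibble with per-site columns `p1, p2`
#'   (recycled/truncated to `n_sites` in position order).
#' @param seed Integer seed.
#'
#' @return A `popgen_sim_config` list.
#' @export
popgen_sim_config <- function(n_hap_per_pop,
                              n_sites,
                              region_length_bp,
                              divergence_profile =
                                list(name = "constant", p1 = 0.5, p2 = 0.5),
                              seed = 1L) {
  if (length(n_hap_per_pop) == 1) n_hap_per_pop <- rep(n_hap_per_pop, 2)
  if (length(n_hap_per_pop) != 2 || any(n_hap_per_pop < 0)) {
    abort("`n_hap_per_pop` must be one or two non-negative counts")
  }
  if (n_sites > region_length_bp) {
    abort(sprintf("cannot place %d sites in %d bp: %d too many",
                  n_sites, region_length_bp, n_sites - region_length_bp))
  }
  structure(
    list(n_hap_per_pop = as.integer(n_hap_per_pop),
         n_sites = as.integer(n_sites),
         region_length_bp = as.numeric(region_length_bp),
         divergence_profile = divergence_profile,
         seed = .check_seed(seed)),
    class = "popgen_sim_config")
}

# draw n values from a spectrum spec in (0, 1)
.draw_spectrum <- function(spec, n) {
  switch(spec$name,
         beta = rbeta(n, spec$shape1, spec$shape2),
         constant = rep(spec$p, n),
         abort(sprintf("unknown spectrum '%s'", spec$name)))
}
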