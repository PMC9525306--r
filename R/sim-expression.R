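#' Simulate an expression matrix with planted SV effects
#'
#' Builds per-accession expression values as
#' `baseline(gene) + effect x genotype dosage + Gaussian noise` for every
#' planted (SV, gene) pair in `effect_plan`; genes not named in the plan are
#' pure baseline plus noise and serve as nulls. The planted truth is returned
#' so recovery can be scored after eQTL mapping.
#'
#' @param genotypes An `sv_set` or a 0/1 dosage matrix (SV x accession).
#' @param effect_plan Tibble `sv_id, gene_id, effect`; duplicate (sv, gene)
#'   pairs are a configuration error.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param seed Integer seed.
#' @param gene_ids Optional full gene panel; defaults to the plan's genes.
#'   Extra ids become unassociated null genes.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#'
#' @return List with `expression` (tibble, `gene_id` + one column per
#'   accession) and `truth` (the effect plan joined with per-gene baselines).
#' @export
simulate_expression <- function(genotypes, effect_plan, noise_sd, seed,
                                gene_ids = NULL,
                                baseline_mean = 8, baseline_sd = 2) {
  if (inherits(genotypes, "sv_set")) genotypes <- genotypes$genotypes
  .assert_cols(effect_plan, c("sv_id", "gene_id", "effect"), "effect_plan")
  if (anyDuplicated(effect_plan[c("sv_id", "gene_id")])) {
    abort("effect_plan contains duplicate (sv_id, gene_id) entries")
  }
  missing_sv <- setdiff(effect_plan$sv_id, rownames(genotypes))
  if (length(missing_sv) > 0) {
    abort(sprintf("planted SV(s) not in genotype matrix: %s",
                  paste(missing_sv, collapse = ", ")))
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  set.seed(.substream(.check_seed(seed), 4L))

  gene_ids <- gene_ids %||% unique(effect_plan$gene_id)
  if (!all(effect_plan$gene_id %in% gene_ids)) {
    abort("every planted gene_id must be in `gene_ids`")
  }
  acc <- colnames(genotypes)
  n_g <- length(gene_ids)
  baseline <- rnorm(n_g, baseline_mean, baseline_sd)
  names(baseline) <- gene_ids

  E <- matrix(rep(baseline, length(acc)), nrow = n_g,
              dimnames = list(gene_ids, acc))
  for (i in seq_len(nrow(effect_plan))) {
    g <- effect_plan$gene_id[i]
    dose <- genotypes[effect_plan$sv_id[i], ]
    dose[is.na(dose)] <- 0
    E[g, ] <- E[g, ] + effect_plan$effect[i] * dose
  }
  if (noise_sd > 0) E <- E + rnorm(length(E), 0, noise_sd)

  list(expression = bind_cols(tibble(gene_id = gene_ids),
                              as_tibble(E, .name_repair = "minimal")),
       truth = effect_plan |>
         mutate(baseline = baseline[.data$gene_id]))
}
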