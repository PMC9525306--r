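#' Simulate biallelic haplotypes for two populations
#'
#' Draws haploid 0/1 genotypes at `n_sites` distinct positions in a region for
#' two populations, with per-site population allele frequencies following the
#' configured divergence profile. The output feeds the divergence-scan module
#' ([fst_per_site()], [windowed_fst()], [windowed_dxy()]).
#'
#' @param cfg A [popgen_sim_config()].
#'
#' @return A `hap_set`: list with `haplotypes` (0/1 matrix, haplotype x site),
#'   `positions` (sorted bp), `pop` (population label per haplotype row),
#'   `chrom` and `region_length`, plus a `truth` tibble of the per-site
#'   frequencies used.
#' @export
#' @examples
#' hs <- simulate_haplotypes(popgen_sim_config(20, 100, 1e5, seed = 2))
#' dim(hs$haplotypes)
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "popgen_sim_config"))
  set.seed(.substream(cfg$seed, 3L))
  n1 <- cfg$n_hap_per_pop[1]; n2 <- cfg$n_hap_per_pop[2]
  positions <- sort(sample.int(cfg$region_length_bp, cfg$n_sites))
  prof <- .site_frequencies(cfg$divergence_profile, positions)

  draw <- function(n, p) {
    matrix(rbinom(n * length(p), 1, rep(p, each = n)), nrow = n)
  }
  H <- rbind(draw(n1, prof$p1), draw(n2, prof$p2))
  if (cfg$n_sites == 0) H <- matrix(integer(), nrow = n1 + n2, ncol = 0)
  rownames(H) <- c(sprintf("pop1_h%03d", seq_len(n1)),
                   sprintf("pop2_h%03d", seq_len(n2)))
  structure(
    list(haplotypes = H, positions = positions,
         pop = rep(c("pop1", "pop2"), c(n1, n2)),
         chrom = "chr1", region_length = cfg$region_length_bp,
         truth = tibble(pos = positions, p1 = prof$p1, p2 = prof$p2)),
    class = "hap_set")
}

.site_frequencies <- function(profile, positions) {
  n <- length(positions)
  if (is.data.frame(profile)) {
    .assert_cols(profile, c("p1", "p2"), "divergence_profile")
    idx <- rep_len(seq_len(nrow(profile)), n)
    return(list(p1 = profile$p1[idx], p2 = profile$p2[idx]))
  }
  switch(profile$name,
    constant = list(p1 = rep(profile$p1, n), p2 = rep(profile$p2, n)),
    block = {
      p1 <- rep(profile$p1, n); p2 <- rep(profile$p2, n)
      inside <- positions >= profile$block_start & positions <= profile$block_end
      p1[inside] <- profile$block_p1; p2[inside] <- profile$block_p2
      list(p1 = p1, p2 = p2)
    },
    abort(sprintf("unknown divergence profile '%s'", profile$name)))
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> %d haplotypes (%s) x %d sites on %s (%g bp)\n",
              nrow(x$haplotypes),
              paste(table(x$pop), collapse = " + "),
              ncol(x$haplotypes), x$chrom, x$region_length))
  invisible(x)
}
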