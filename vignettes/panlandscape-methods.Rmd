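---
title: "Methods: pan-genome PAV, SV and divergence landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome PAV, SV and divergence landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panlandscape)
library(dplyr)
```

panlandscape implements the downstream analysis layer of a multi-accession
plant pan-genome study: gene presence/absence variation (PAV) over
orthogroups, NLR arrangement classification, structural-variant (SV)
landscapes and hotspot testing, collinear-locus inference over pan-genome
graph bubbles, windowed population divergence, and SV-based eQTL mapping.
This vignette records the models, the parameter choices that matter, and the
design decisions taken where the underlying procedures were open to
interpretation.

## The synthetic study system

Every stage is exercisable without external data through the
`simulate_*()` generators, which emulate an inbred rice-like panel:

* **Pan-genome** (`simulate_pangenome()`): a configurable number of
  accessions per subpopulation; core orthogroups present everywhere;
  each dispensable orthogroup draws a presence probability from a
  Beta(0.5, 1.5) spectrum and is then present independently per accession.
  The Beta default is a stand-in giving the qualitative pattern observed in
  real pan-genomes — many rare genes, few intermediate-frequency ones — and
  is configurable; no empirical frequency spectrum is claimed. Orthogroups
  have a fixed home chromosome and rank order shared by all accessions, so
  gene order is collinear across the panel; an `nlr_cluster_bias` parameter
  controls the probability that an NLR orthogroup is inserted adjacent to an
  already-placed NLR (at bias 1 each chromosome's NLRs form one contiguous
  run). Each present orthogroup contributes exactly one gene model per
  accession: tandem paralogs, nested genes and TE-derived models are *not*
  simulated, so tests passing on this generator say nothing about those
  features of real annotations.
* **SVs** (`simulate_svs()`): positions uniform per bp, multiplied by an
  enrichment factor inside injected hotspot regions; lengths from a
  two-component lognormal mixture (defaults placing roughly two thirds of
  SVs below 1 kb, the size structure typical of long-read rice call sets)
  truncated to the callable 50 bp–1 Mb range; haploid presence/absence
  genotypes with carrier frequencies from a rare-dominated Beta(0.3, 3)
  spectrum. Genotypes are haploid because rice accessions are inbred; a
  diploid mode writes homozygous VCF genotypes.
* **Haplotypes** (`simulate_haplotypes()`): biallelic haploid 0/1 calls at
  distinct positions, with per-site population allele frequencies following
  a constant, per-site, or block (step-change) divergence profile.
* **Expression** (`simulate_expression()`): baseline per gene plus
  `effect × dosage` for planted (SV, gene) pairs plus Gaussian noise, with
  the planted truth returned for recovery scoring.

All generators derive their randomness from one seed through fixed
per-generator substreams and are bit-reproducible.

## PAV: core/dispensable, rarefaction, divergence, taxon levels

An orthogroup is **core** iff `n_present / n_accessions >= threshold`
(default 0.95), evaluated as an exact fraction with no integer pre-rounding:
for a 251-accession panel the boundary is 239 present (95.2%, core) versus
238 (94.8%, dispensable). Core and dispensable always partition the matrix.

**Rarefaction** randomizes the accession order (default 500 orderings,
matching standard practice for gene-accumulation curves) and reports, per
step, the union (pan) and intersection (core) sizes with mean/sd/min/max
summaries — the underlying per-ordering curves are retained so monotonicity
is checkable. The `nonprivate` mode restricts to orthogroups present in at
least two accessions; this restriction is computed **once on the full input
panel**, not per subsample, because non-private status is a property of the
population being rarefied.

**Pairwise PAV divergence** counts the symmetric difference of two
accessions' presence sets. The published quantity divides by an "average
gene number between them", which is ambiguous; we divide by the **union** of
the two presence sets so the ratio is bounded by 1 and equals 1 exactly for
disjoint gene content. Both the counts and the ratio are reported per pair,
so the alternative normalization can be recomputed from the output.

**Taxon levels** classify orthogroups by subpopulation sharing in a fixed
order (each level excluding the previous ones): I = Or and Ob; II = Or and
Os (Osi or Osj); III = Og and Ob; IV = Osi and Osj; everything else —
e.g. a gene only in Osi and Og, a pattern expected under admixture — is
`undetermined`.

## NLR arrangement

Two NLRs "approach" when at most one non-NLR gene lies between them in
**gene-rank order** on the same chromosome. Rank order (not bp distance) is
used because the rule counts genes; only annotated genes enter the ranking,
and the importer accepts a gene-type filter for annotations that include
TE-derived models. Groups are connected components of the approaching
relation; because the gap between any two NLRs bounds the gaps of the
consecutive NLRs between them, chaining consecutive NLRs yields exactly the
same components, which is what the implementation does (the test suite
checks it against an explicit pairwise matrix + BFS oracle on 1,000 random
chromosomes). Component sizes map to singleton / pair / cluster (>= 3).

Pair orientation is determined after sorting by start: same strand = T-H
(tail-to-head); `-` then `+` = H-H, chosen so the two promoters (5' ends)
face each other, which is the stated property of the H-H configuration;
`+` then `-` = T-T. Clusters record a strand pattern string but no H-H/T-T
typing, which is defined only for pairs. Homogeneity is "all members share
one orthogroup"; any mismatch makes the group heterogeneous.

Domain enrichment uses a two-sided Wilcoxon rank-sum test of one
subpopulation's per-accession domain counts against all remaining
accessions, Benjamini–Hochberg adjusted across all (domain, subpopulation)
tests; when the test statistic has no variation at all (identical constant
counts) the p-value is reported as 1 rather than NA.

## SV landscape

`filter_svs()` applies the five standard long-read filters (length outside
50 bp–1 Mb; in a reference assembly gap; no carrier / `0/0` genotype;
imprecise; support depth below 30). Records missing a depth or precision
field are rejected under the corresponding rule and counted separately;
rejection counts are per rule with multi-rule records counted in each.

Breakpoint windows are 200 kb with a 100 kb step (half-open internally,
trailing partial windows included). Insertions and translocations contribute
one breakpoint (`pos`), deletions/inversions/duplications two (`pos`,
`end`) — Sniffles semantics. Hotspots are the top 10% of windows by count
with **strict-rank tie handling**: exactly `floor(top_frac × W)` windows are
flagged and ties at the cutoff are resolved by genomic order, for
determinism. Contiguous flagged windows merge into regions.

The null model re-places the observed SVs — identical length and type
multiset — uniformly at random, per-chromosome probability proportional to
length, avoiding declared gap intervals, 100 replicates by default.
Significance is a two-sided Wilcoxon **rank-sum** of observed per-window
counts against the pooled simulated counts. The published test is named only
"Wilcoxon"; rank-sum over pooled replicates was chosen because replicates
are exchangeable and a paired test would discard the between-replicate
variance, and the choice is isolated in `hotspot_significance()` so a paired
variant can be substituted.

SV–gene annotation: `contains-gene` requires the SV to cover both gene
endpoints; `overlaps-gene` is any other body intersection; `within-flank`
intersects only the ±2 kb extension; otherwise `intergenic`.

## Collinear loci over graph bubbles

Features are intersected with bubble paths on the accession's own contig
coordinates; each feature is projected to the pan backbone as the hull of
its overlapping bubbles' pan intervals (the reference path of the graph).
Bubbles uncalled by the aligner are linearly interpolated between the
nearest collinear flanking bubbles on the same contig and dropped when no
such flanks exist. Loci are single-linkage clusters of projected intervals.
Two same-accession **singletons** in one bubble trigger the 1 bp tie-break:
the lexicographically smaller feature id keeps the bubble locus (the
published rule does not say which is kept; lexicographic order makes it
deterministic) and each additional singleton becomes a point locus exactly
1 bp beyond the bubble's pan end, so displaced singletons from different
accessions still co-locate. Chaining uses **strict** interval overlap rather
than bookended merging — a bookended merge would immediately re-absorb the
displaced 1 bp locus. Single-member loci are excluded from the locus table
and listed separately, and every input feature ends up in exactly one of:
a multi-member locus, the excluded list, or the unplaced list.

## Windowed divergence

Per-site FST is the Weir–Cockerham (1984) estimator in its haploid one-way
ANOVA form (inbred accessions carry no heterozygosity term; a diploid
extension would add it to the within component). Negative estimates are
retained, matching standard tooling. Windowed FST uses the **ratio of sums**
of variance components, the recommended aggregation for this estimator; a
mean-of-ratios mode is provided for comparison with tools that report it.
Monomorphic sites get zero components: undefined as ratios, harmless in
sums. Dxy is `Σ p1(1−p2) + p2(1−p1)` over sites divided by window length in
bp. Windows default to non-overlapping 20 kb tiles; the published scan says
"20 kb sliding windows" without a step, so the step defaults to the window
size and is configurable. Top divergent regions take the top 5% of defined
windows (floor quota, genomic-order tie-break) and merge adjacent selections.

## eQTL

Expression is filtered to genes with mean FPKM > 0.1 and rank-normalized per
gene with the Blom offset `qnorm((r − 3/8)/(n + 1/4))`, averaged ranks for
ties. Association is OLS of expression on genotype dosage plus covariates
(supplied as a precomputed matrix — e.g. PEER factors and genotype PCs;
hidden-factor estimation itself is out of scope), computed by residualizing
both sides on the covariates once and scanning all pairs in matrix form,
which is algebraically identical to the per-pair fit (verified against
`lm()` to 1e-8 in the tests). SVs enter at allele frequency >= 0.05 and
missing rate <= 0.1; residual missing dosages are mean-imputed. Multiple
testing is Benjamini–Hochberg at α = 0.05; a fixed genome-wide threshold is
deliberately not hard-coded because the published one (1.29e-5) is
data-derived.

LD pruning walks each gene's hits in ascending p-value order (ties by SV id)
and retains a hit only if its r² with every already-retained hit is at or
below the background level (default 0.11, the LD-decay plateau reported for
deletions and insertions). Greedy-by-p was chosen over pairwise-sequential
pruning for determinism and order-invariance. r² is the squared Pearson
correlation of dosages over pairwise-complete accessions. A hit is **cis**
iff its SV intersects the gene body or sits strictly within 2 kb of either
gene end; the rule is applied to both ends per the published definition, so
it is strand-symmetric.

## Numerical choices and problem sizes

Tie-breaks are deterministic everywhere (documented per function); window
tilings are half-open with trailing partials; all counts use exact integer
arithmetic. The test-suite problem sizes — 1,000 random chromosomes of 200
genes for the NLR oracle, 5,000 SVs over 10 Mb with a 50× 200 kb injected
hotspot, 10,000 panmixia sites, 100-seed eQTL recovery at 200 accessions
with 5×noise effects, 20 replicates per calibration trial — were chosen as
the smallest scales at which the Monte-Carlo checks have stable power; the
acceptance script uses the same conditions with 20 eQTL seeds.

## Known limitations

The generator's collinear gene order cannot produce genuine rearrangement
polymorphism, so collinear-locus inference is tested on planted bubble
tables rather than on simulated rearrangements. Homogeneous NLR clusters
(same orthogroup repeated in tandem) do not arise from the generator and are
covered by constructed fixtures. The Wilcoxon hotspot test inherits the
spatial autocorrelation of overlapping windows (adjacent windows share half
their span); the published procedure has the same property. FST/Dxy assume
biallelic haploid sites; multi-allelic sites must be split upstream.
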