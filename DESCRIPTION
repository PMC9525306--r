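Package: panlandscape
Title: Pan-Genome Presence/Absence, Structural-Variant and Divergence Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-accession plant pan-genomes built from
    whole-genome assemblies. Builds gene presence/absence-variation (PAV)
    matrices from orthogroup tables and classifies core versus dispensable
    genes; computes gene-accumulation (rarefaction) curves and pairwise PAV
    divergence; classifies nucleotide-binding leucine-rich repeat (NLR) immune
    genes into singletons, pairs and clusters with pair orientation and
    homogeneity typing; filters Sniffles-style structural-variant (SV) calls,
    summarizes SV size and frequency spectra, and detects SV hotspots against
    a matched-size simulated null; infers collinear loci across accessions
    from pan-genome graph bubble tables; runs windowed Weir-Cockerham FST and
    Dxy divergence scans; and maps SV expression quantitative trait loci with
    covariate-adjusted linear models, LD-based pruning and cis/trans
    classification. A built-in synthetic pan-genome generator provides
    statistically controlled inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
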