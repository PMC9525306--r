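#' Read and write the pipeline's standard file formats
#'
#' Thin wrappers around rtracklayer, vcfR and readr that move between the
#' package's tibble-based records and the field's plain-text formats: GFF3
#' gene annotations (1-based closed), Sniffles-dialect SV VCF 4.2 (INFO keys
#' `SVTYPE`, `SVLEN`, `END`, `RE` and a `PRECISE`/`IMPRECISE` flag, haploid or
#' homozygous-diploid `GT`), OrthoFinder-style orthogroup TSV, chromosome
#' length TSV (two columns, no header), expression TSV and subpopulation TSV.
#'
#' @param genes,path,sv_set,chrom_lengths,orthogroups,expression,subpops
#'   Records to serialize and file paths.
#' @param diploid Write diploid homozygous genotypes (`1/1`, `0/0`) instead of
#'   haploid `1`/`0`.
#' @name panlandscape-io
NULL

#' @rdname panlandscape-io
#' @export
write_pangenome_gff3 <- function(genes, path) {
  .assert_cols(genes, c("gene_id", "accession_id", "chrom", "start", "end",
                        "strand", "orthogroup_id", "is_nlr"), "genes")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = .iranges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "panlandscape", type = "gene",
    ID = genes$gene_id, accession_id = genes$accession_id,
    orthogroup_id = genes$orthogroup_id,
    is_nlr = ifelse(genes$is_nlr, "true", "false"))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname panlandscape-io
#' @export
read_pangenome_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    gene_id = gr$ID,
    accession_id = gr$accession_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    orthogroup_id = gr$orthogroup_id,
    is_nlr = gr$is_nlr == "true")
}

#' @rdname panlandscape-io
#' @export
write_sv_vcf <- function(sv_set, path, chrom_lengths = NULL, diploid = FALSE) {
  v <- sv_set$variants
  gt <- sv_set$genotypes
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panlandscape",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>",
              chrom_lengths$chrom, as.integer(chrom_lengths$length))
    },
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise structural variant\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise structural variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the SV\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the SV\">",
    "##INFO=<ID=RE,Number=1,Type=Integer,Description=\"Number of supporting reads\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"))
  body <- character(0)
  if (nrow(v) > 0) {
    info <- sprintf("%s;SVTYPE=%s;SVLEN=%d;END=%d;RE=%d",
                    ifelse(v$precise, "PRECISE", "IMPRECISE"),
                    v$svtype,
                    as.integer(ifelse(v$svtype == "DEL", -v$svlen, v$svlen)),
                    as.integer(v$end), as.integer(v$support_depth))
    code <- function(x) {
      if (diploid) ifelse(is.na(x), "./.", ifelse(x > 0, "1/1", "0/0"))
      else ifelse(is.na(x), ".", as.character(as.integer(x > 0)))
    }
    gt_chr <- apply(gt, 2, code)
    if (is.null(dim(gt_chr))) gt_chr <- matrix(gt_chr, nrow = nrow(v))
    body <- paste(v$chrom, v$pos, v$sv_id, "N",
                  sprintf("<%s>", v$svtype), ".", "PASS", info, "GT",
                  apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
    if (ncol(gt) == 0) {  # no samples: drop the trailing empty field
      body <- paste(v$chrom, v$pos, v$sv_id, "N", sprintf("<%s>", v$svtype),
                    ".", "PASS", info, "GT", sep = "\t")
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname panlandscape-io
#' @export
read_sv_vcf <- function(path) {
  lines <- readLines(path)
  header_line <- grep("^#CHROM", lines, value = TRUE)
  if (length(header_line) != 1) abort(sprintf("%s: no #CHROM header line", path))
  cols <- strsplit(header_line, "\t")[[1]]
  acc <- if (length(cols) > 9) cols[-(1:9)] else character(0)
  if (sum(!startsWith(lines, "#")) == 0) {
    return(structure(
      list(variants = tibble(sv_id = character(), chrom = character(),
                             pos = integer(), end = integer(),
                             svtype = character(), svlen = integer(),
                             support_depth = integer(), precise = logical()),
           genotypes = matrix(integer(), 0, length(acc),
                              dimnames = list(NULL, acc))),
      class = "sv_set"))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  int_info <- function(key) {
    suppressWarnings(as.integer(vcfR::extract.info(vcf, key)))
  }
  variants <- tibble(
    sv_id = fix[, "ID"],
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    end = int_info("END"),
    svtype = vcfR::extract.info(vcf, "SVTYPE"),
    svlen = abs(int_info("SVLEN")),
    support_depth = int_info("RE"),
    precise = !grepl("(^|;)IMPRECISE(;|$)", info))
  gt <- matrix(integer(), nrow(variants), length(acc),
               dimnames = list(variants$sv_id, acc))
  if (length(acc) > 0) {
    raw <- vcfR::extract.gt(vcf)
    first <- substr(raw, 1, 1)
    gt[] <- ifelse(is.na(raw) | first == ".", NA_integer_,
                   as.integer(first != "0"))
  }
  structure(list(variants = variants, genotypes = gt), class = "sv_set")
}

#' @rdname panlandscape-io
#' @export
write_orthogroup_tsv <- function(orthogroups, path) {
  readr::write_tsv(orthogroups, path)
  invisible(path)
}

#' @rdname panlandscape-io
#' @export
read_orthogroup_tsv <- function(path) {
  out <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    na = character()),
    error = function(e) abort(sprintf("malformed orthogroup TSV %s: %s",
                                      path, conditionMessage(e))))
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed orthogroup TSV %s: parse failure at line %d (%s)",
                  path, prob$row[1], prob$expected[1]))
  }
  out
}

#' @rdname panlandscape-io
#' @export
write_chrom_lengths_tsv <- function(chrom_lengths, path) {
  readr::write_tsv(chrom_lengths[c("chrom", "length")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname panlandscape-io
#' @export
read_chrom_lengths_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = "cd")
}

#' @rdname panlandscape-io
#' @export
write_expression_tsv <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' @rdname panlandscape-io
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(gene_id = "c", .default = "d"))
}

#' @rdname panlandscape-io
#' @export
write_subpop_tsv <- function(subpops, path) {
  readr::write_tsv(subpops[c("accession_id", "subpop")], path)
  invisible(path)
}

#' @rdname panlandscape-io
#' @export
read_subpop_tsv <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' Read a gaps BED file
#'
#' Returns assembly-gap intervals in BED convention (0-based half-open), the
#' representation [filter_svs()] expects.
#'
#' @param path BED file path.
#' @return Tibble `chrom, start, end` (0-based half-open).
#' @export
read_gaps_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr)) |>
    arrange(.data$chrom, .data$start)
}
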