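#' Write a variant table as VCF 4.2
#'
#' Minimal single-sample VCF with `GENE` and `CSQ` INFO tags carrying the
#' gene and consequence annotations, and a `GT` FORMAT field encoding the
#' genotype class (`0/1` het, `1/1` hom-alt, `0/0` hom-ref, `./.` missing).
#'
#' @param variants A [variant_table()].
#' @param path Output path.
#' @param build A [genome_build()] used for the contig header lines.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, build, sample_name = "FOCAL") {
  stopifnot(inherits(build, "genome_build"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  gt <- ifelse(is.na(variants$gt), "./.", gt_code[variants$gt])
  info <- ifelse(is.na(variants$consequence), ".",
                 paste0("CSQ=", variants$consequence))
  info <- ifelse(is.na(variants$gene), info,
                 paste0(info, ";GENE=", variants$gene))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", build$chrom, build$length),
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene name\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  body <- paste(variants$chrom, format(variants$pos, scientific = FALSE,
                                       trim = TRUE),
                ".", variants$ref, variants$alt, ".", "PASS", info, "GT", gt,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parses genotype classes from the first sample's `GT` field and the
#' `GENE`/`CSQ` INFO tags if present.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) {
    return(variant_table(character(0), numeric(0)))
  }
  gtmat <- vcfR::extract.gt(v, element = "GT")
  raw_gt <- if (is.null(gtmat)) rep(NA_character_, n) else gtmat[, 1]
  gt <- rep(NA_character_, n)
  gt[raw_gt %in% c("0/0", "0|0")] <- "hom_ref"
  gt[raw_gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  gt[raw_gt %in% c("1/1", "1|1")] <- "hom_alt"
  csq <- suppressWarnings(vcfR::extract.info(v, element = "CSQ"))
  gene <- suppressWarnings(vcfR::extract.info(v, element = "GENE"))
  variant_table(fix$CHROM, as.numeric(fix$POS), fix$REF, fix$ALT,
                gt = gt,
                consequence = if (is.null(csq)) NA_character_ else csq,
                gene = if (is.null(gene)) NA_character_ else gene)
}

#' Read / write interval sets as BED
#'
#' Intervals are 0-based half-open in memory and on disk (BED convention).
#'
#' @param df A data.frame with `chrom`, `start`, `end` and optionally a name
#'   column.
#' @param path File path.
#' @param name_col Optional column written as the BED name field.
#' @return `read_bed` returns a data.frame (`chrom`, `start`, `end`, and
#'   `name` when present); `write_bed` returns `path` invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL) {
  gr <- intervals_to_granges(df)
  if (!is.null(name_col)) names(gr) <- as.character(df[[name_col]])
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write / read the heterozygosity window track as TSV
#'
#' @param windows A window track from [het_windows()] or [count_het()].
#' @param path File path.
#' @param header_lines Optional comment lines (prefixed `#`) written before
#'   the column header, e.g. a config hash.
#' @return `read_windows_tsv` returns the window data.frame;
#'   `write_windows_tsv` returns `path` invisibly.
#' @export
write_windows_tsv <- function(windows, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(windows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
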