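#' Construct an annotated variant table
#'
#' The in-memory representation of a VCF used throughout the package: one row
#' per site with a genotype class and a functional-consequence annotation.
#' Consequence annotation is consumed, not computed — variant effect
#' prediction is upstream of this package.
#'
#' @param chrom,pos Chromosome and 1-based position.
#' @param ref,alt Reference and alternate alleles.
#' @param gt Genotype class: `"hom_ref"`, `"het"`, `"hom_alt"`, or `NA`.
#' @param consequence `"synonymous"`, `"non_synonymous"`, `"other"`, or `NA`.
#' @param gene Gene name or `NA`.
#' @return A data.frame with the seven columns above.
#' @export
variant_table <- function(chrom, pos, ref = "N", alt = "N", gt = "het",
                          consequence = NA_character_,
                          gene = NA_character_) {
  n <- length(chrom)
  bad_gt <- !is.na(gt) & !gt %in% c("hom_ref", "het", "hom_alt")
  if (any(bad_gt)) stop("invalid genotype class")
  data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
             ref = rep_len(as.character(ref), n),
             alt = rep_len(as.character(alt), n),
             gt = rep_len(as.character(gt), n),
             consequence = rep_len(as.character(consequence), n),
             gene = rep_len(as.character(gene), n),
             stringsAsFactors = FALSE)
}

# 0-based half-open interval data.frame -> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# variant positions (1-based) -> width-1 GRanges
variants_to_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1))
}

# Annotate each variant with the name of the containing gene interval
# (half-open: a variant at pos p is inside [start, end) iff start < p <= end).
annotate_gene_membership <- function(variants, genes) {
  if (nrow(variants) == 0) {
    variants$gene <- character(0)
    return(variants)
  }
  hits <- GenomicRanges::findOverlaps(variants_to_granges(variants),
                                      intervals_to_granges(genes),
                                      select = "first")
  variants$gene <- ifelse(is.na(hits), NA_character_, genes$gene[hits])
  variants
}
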