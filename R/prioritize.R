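#' Keep homozygous-alt non-synonymous variants
#'
#' Records with a missing genotype or consequence annotation are skipped and
#' their number reported with a message (they cannot satisfy the filter).
#'
#' @param variants A [variant_table()].
#' @return The filtered table.
#' @export
filter_hom_nonsyn <- function(variants) {
  missing_ann <- is.na(variants$gt) | is.na(variants$consequence)
  if (any(missing_ann)) {
    message(sprintf("%d record(s) without genotype/consequence annotation skipped",
                    sum(missing_ann)))
  }
  keep <- !missing_ann & variants$gt == "hom_alt" &
    variants$consequence == "non_synonymous"
  variants[keep, , drop = FALSE]
}

#' Restrict variants to candidate-gene intervals
#'
#' Intervals are half-open: a variant at 1-based position `p` is inside
#' `[start, end)` iff `start < p <= end`; a variant exactly at the interval
#' start coordinate (0-based) is included, one at the end coordinate is not.
#' The `gene` column is (re)annotated with the containing gene's name.
#'
#' @param variants A [variant_table()].
#' @param genes A data.frame `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return The filtered, gene-annotated table.
#' @export
restrict_to_genes <- function(variants, genes) {
  variants <- annotate_gene_membership(variants, genes)
  variants[!is.na(variants$gene), , drop = FALSE]
}

#' Keep variants private with respect to a comparison panel
#'
#' A variant is private when no panel individual carries its alt allele at
#' that position (genotype `het` or `hom_alt` on a record with the same
#' `chrom`, `pos`, `alt`). A panel record at the site with a missing
#' genotype counts as absence of the allele, but such variants are flagged
#' in `panel_missing` so the ambiguity is visible rather than hidden.
#'
#' @param variants The focal [variant_table()].
#' @param panel A list of panel variant tables (may be empty: everything
#'   passes).
#' @return The private subset, with a logical `panel_missing` column.
#' @export
private_against_panel <- function(variants, panel) {
  if (nrow(variants) == 0 || length(panel) == 0) {
    variants$panel_missing <- rep(FALSE, nrow(variants))
    return(variants)
  }
  key <- function(v) paste(v$chrom, v$pos, v$alt, sep = ":")
  vkey <- key(variants)
  carried <- rep(FALSE, nrow(variants))
  missing_at_site <- rep(FALSE, nrow(variants))
  for (tab in panel) {
    carrier <- !is.na(tab$gt) & tab$gt %in% c("het", "hom_alt")
    carried <- carried | vkey %in% key(tab[carrier, , drop = FALSE])
    missing_at_site <- missing_at_site |
      vkey %in% key(tab[is.na(tab$gt), , drop = FALSE])
  }
  out <- variants[!carried, , drop = FALSE]
  out$panel_missing <- missing_at_site[!carried]
  out
}

#' Annotate variants with their ROH context
#'
#' Flags each variant with whether it falls inside a called run of
#' homozygosity and, if so, the containing segment's length (half-open
#' boundary rule: a variant at a segment's end coordinate is outside).
#'
#' @param variants A [variant_table()].
#' @param callset A [compute_f_roh()] result (post-processed segments).
#' @return The table with `in_roh` (logical) and `roh_length` (bp or `NA`).
#' @export
annotate_roh_context <- function(variants, callset) {
  seg <- if (inherits(callset, "roh_callset")) callset$segments else callset
  if (nrow(variants) == 0 || nrow(seg) == 0) {
    variants$in_roh <- rep(FALSE, nrow(variants))
    variants$roh_length <- rep(NA_real_, nrow(variants))
    return(variants)
  }
  hits <- GenomicRanges::findOverlaps(variants_to_granges(variants),
                                      intervals_to_granges(seg),
                                      select = "first")
  variants$in_roh <- !is.na(hits)
  variants$roh_length <- ifelse(is.na(hits), NA_real_,
                                (seg$end - seg$start)[hits])
  variants
}

#' Run the full candidate-variant prioritization funnel
#'
#' Homozygous non-synonymous, then candidate-gene overlap, then privacy
#' against the panel, then ROH-context annotation. Each filter is an
#' intersection, so the surviving set does not depend on filter order; the
#' per-stage counts (the filtering funnel) are returned for auditability.
#'
#' @param variants The focal [variant_table()].
#' @param genes Candidate-gene intervals.
#' @param panel List of panel variant tables.
#' @param callset Optional [compute_f_roh()] result for ROH annotation.
#' @return A list: `result` (surviving variants, ROH-annotated) and
#'   `funnel` (data.frame of stage names and record counts, non-increasing).
#' @export
prioritize_variants <- function(variants, genes, panel, callset = NULL) {
  v1 <- filter_hom_nonsyn(variants)
  v2 <- restrict_to_genes(v1, genes)
  v3 <- private_against_panel(v2, panel)
  if (!is.null(callset)) v3 <- annotate_roh_context(v3, callset)
  list(result = v3,
       funnel = data.frame(
         stage = c("input", "hom_non_synonymous", "in_candidate_gene",
                   "private"),
         n = c(nrow(variants), nrow(v1), nrow(v2), nrow(v3)),
         stringsAsFactors = FALSE))
}
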