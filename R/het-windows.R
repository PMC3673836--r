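#' Tile a genome into non-overlapping windows
#'
#' Windows tile each chromosome exactly and in order; the last window of a
#' chromosome may be shorter than `window_size` and is flagged `short` when
#' it is below half the nominal size (short windows are excluded from ROH
#' calling, see [call_roh()]).
#'
#' @param build A [genome_build()].
#' @param window_size Window size in bp (default 1 Mbp).
#' @return A window track: data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `nominal_size`, `short`, `masked_out`,
#'   `effective_bases`, `het_count`, `het_per_kbp`.
#' @export
tile_windows <- function(build, window_size = 1e6) {
  stopifnot(inherits(build, "genome_build"))
  if (!is.numeric(window_size) || window_size <= 0) {
    stop("'window_size' must be > 0")
  }
  per_chrom <- lapply(seq_len(nrow(build)), function(i) {
    L <- build$length[i]
    starts <- seq(0, L - 1, by = window_size)
    data.frame(chrom = build$chrom[i], start = starts,
               end = pmin(starts + window_size, L),
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, per_chrom)
  w$nominal_size <- window_size
  w$short <- (w$end - w$start) < window_size / 2
  w$masked_out <- FALSE
  w$effective_bases <- w$end - w$start
  w$het_count <- NA_real_
  w$het_per_kbp <- NA_real_
  rownames(w) <- NULL
  w
}

#' Apply a duplication mask to a window track
#'
#' A window is dropped (`masked_out`) when its overlap with the mask exceeds
#' `max_overlap` of the window length — strictly: a window with exactly 40%
#' overlap is retained. Surviving windows get `effective_bases` = window
#' length minus masked overlap, the denominator used by [count_het()].
#'
#' @param windows A window track from [tile_windows()].
#' @param dup_mask A data.frame `chrom`, `start`, `end` (0-based half-open);
#'   overlapping intervals are merged first.
#' @param max_overlap Maximum tolerated overlap fraction (default 0.40).
#' @return The window track with `masked_out` and `effective_bases` set; the
#'   merged mask is attached as `attr(, "dup_mask")` so [count_het()] can
#'   exclude in-mask sites.
#' @export
mask_windows <- function(windows, dup_mask, max_overlap = 0.40) {
  if (max_overlap < 0 || max_overlap >= 1) {
    stop("'max_overlap' must be in [0, 1)")
  }
  if (is.null(dup_mask) || nrow(dup_mask) == 0) {
    attr(windows, "dup_mask") <- NULL
    return(windows)
  }
  if (any(dup_mask$end <= dup_mask$start)) {
    stop("malformed mask interval: end <= start")
  }
  dup_mask <- merge_intervals(dup_mask)
  wgr <- intervals_to_granges(windows)
  mgr <- intervals_to_granges(dup_mask)
  hits <- GenomicRanges::findOverlaps(wgr, mgr)
  ov <- GenomicRanges::pintersect(wgr[S4Vectors::queryHits(hits)],
                                  mgr[S4Vectors::subjectHits(hits)])
  ov_bp <- rep(0, nrow(windows))
  if (length(hits) > 0) {
    agg <- rowsum(GenomicRanges::width(ov), S4Vectors::queryHits(hits))
    ov_bp[as.integer(rownames(agg))] <- agg[, 1]
  }
  wlen <- windows$end - windows$start
  windows$masked_out <- ov_bp / wlen > max_overlap
  windows$effective_bases <- wlen - ov_bp
  windows$het_count <- NA_real_
  windows$het_per_kbp <- NA_real_
  attr(windows, "dup_mask") <- dup_mask
  windows
}

#' Count heterozygous sites per window and compute densities
#'
#' Only genotype-heterozygous records are counted. Sites falling inside the
#' duplication mask are excluded even in retained windows, consistent with
#' the effective-base denominator: both numerator and denominator refer to
#' unmasked sequence. `het_per_kbp = 1000 * het_count / effective_bases`;
#' masked-out windows carry no density.
#'
#' @param windows A window track (after [mask_windows()], or unmasked).
#' @param variants A [variant_table()]; records on chromosomes absent from
#'   the track are skipped with a warning.
#' @param dup_mask Mask intervals; defaults to the mask attached by
#'   [mask_windows()].
#' @return The window track with `het_count` and `het_per_kbp` filled in.
#' @export
count_het <- function(windows, variants, dup_mask = attr(windows,
                                                         "dup_mask")) {
  het <- variants[!is.na(variants$gt) & variants$gt == "het", , drop = FALSE]
  known <- het$chrom %in% unique(windows$chrom)
  if (any(!known)) {
    warning(sprintf("%d heterozygous site(s) on chromosomes absent from the window track; skipped",
                    sum(!known)))
    het <- het[known, , drop = FALSE]
  }
  counts <- rep(0, nrow(windows))
  if (nrow(het) > 0) {
    vgr <- variants_to_granges(het)
    if (!is.null(dup_mask) && nrow(dup_mask) > 0) {
      in_mask <- IRanges::overlapsAny(vgr, intervals_to_granges(dup_mask))
      vgr <- vgr[!in_mask]
    }
    hits <- GenomicRanges::findOverlaps(vgr, intervals_to_granges(windows),
                                        select = "first")
    tab <- table(hits)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  windows$het_count <- counts
  dens <- ifelse(windows$effective_bases > 0,
                 1000 * counts / windows$effective_bases, NA_real_)
  dens[windows$masked_out] <- NA_real_
  windows$het_per_kbp <- dens
  windows
}

#' Windowed heterozygosity in one call
#'
#' Convenience wrapper: [tile_windows()] then [mask_windows()] then
#' [count_het()].
#'
#' @inheritParams tile_windows
#' @inheritParams mask_windows
#' @inheritParams count_het
#' @return A completed window track.
#' @export
het_windows <- function(build, variants, dup_mask = NULL,
                        window_size = 1e6, max_overlap = 0.40) {
  w <- tile_windows(build, window_size)
  w <- mask_windows(w, dup_mask, max_overlap)
  count_het(w, variants)
}
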