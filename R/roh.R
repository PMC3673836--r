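#' Call runs of homozygosity from a window track
#'
#' A ROH is a maximal run of at least `min_windows` consecutive eligible
#' windows whose heterozygosity density falls strictly below
#' `het_threshold`. Masked-out windows (and trailing short windows) do not
#' contribute, but a single such window does not break a run; two or more in
#' a row do. The called segment spans from the start of the first qualifying
#' window to the end of the last.
#'
#' The density cut is not an absolute constant by default: it is
#' `threshold_factor` times the genome-wide median density of eligible
#' windows, a scale-free choice that tracks the individual's overall
#' diversity. Pass `het_threshold` to override with an absolute density.
#'
#' @param windows A completed window track from [count_het()].
#' @param het_threshold Absolute density cut in het sites/kbp, or `NULL` to
#'   derive it from the track.
#' @param threshold_factor Multiplier on the genome-wide median density used
#'   when `het_threshold` is `NULL` (default 0.25).
#' @param min_windows Minimum number of qualifying windows per run
#'   (default 2).
#' @return A data.frame of segments: `chrom`, `start`, `end`, `length`,
#'   `n_windows`, `mean_het_per_kbp`, sorted and non-overlapping. The
#'   threshold used is attached as `attr(, "het_threshold")`.
#' @export
call_roh <- function(windows, het_threshold = NULL, threshold_factor = 0.25,
                     min_windows = 2L) {
  eligible <- !windows$masked_out & !windows$short &
    !is.na(windows$het_per_kbp)
  if (is.null(het_threshold)) {
    med <- stats::median(windows$het_per_kbp[eligible])
    het_threshold <- threshold_factor * med
  }
  if (!is.finite(het_threshold) || het_threshold <= 0) {
    stop("'het_threshold' must be > 0 (is the window track empty?)")
  }
  state <- ifelse(!eligible, "skip",
                  ifelse(windows$het_per_kbp < het_threshold, "low", "high"))

  segs <- list()
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    low_run <- integer(0) # indices of qualifying windows in current run
    pending_skip <- 0L
    close_run <- function(run) {
      if (length(run) >= min_windows) {
        segs[[length(segs) + 1]] <<- data.frame(
          chrom = ch,
          start = windows$start[run[1]],
          end = windows$end[run[length(run)]],
          n_windows = length(run),
          mean_het_per_kbp = mean(windows$het_per_kbp[run]),
          stringsAsFactors = FALSE)
      }
    }
    for (i in idx) {
      s <- state[i]
      if (s == "low") {
        if (pending_skip >= 2L) {
          close_run(low_run)
          low_run <- integer(0)
        }
        low_run <- c(low_run, i)
        pending_skip <- 0L
      } else if (s == "skip") {
        pending_skip <- pending_skip + 1L
      } else { # high
        close_run(low_run)
        low_run <- integer(0)
        pending_skip <- 0L
      }
    }
    close_run(low_run)
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_windows = integer(0), mean_het_per_kbp = numeric(0),
               stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out <- out[, c("chrom", "start", "end", "length", "n_windows",
                 "mean_het_per_kbp")]
  rownames(out) <- NULL
  attr(out, "het_threshold") <- het_threshold
  out
}

#' Post-process ROH segments: merge small gaps, then drop short segments
#'
#' Adjacent same-chromosome segments separated by a gap strictly smaller
#' than `max_gap` are merged (the merged span includes the gap); segments
#' shorter than `min_length` are then removed. Merging precedes filtering so
#' that clusters of sub-threshold segments can survive as one long segment.
#'
#' @param segments A segment data.frame (`chrom`, `start`, `end`, optionally
#'   `rep` for pooled simulator output; other columns are dropped).
#' @param min_length Minimum retained segment length in bp (default 2 Mbp).
#' @param max_gap Gaps strictly below this are merged (default 500 kbp).
#' @param order `"merge_first"` (default) or `"filter_first"`: whether the
#'   gap merge runs before or after the length filter. Merge-first lets
#'   clusters of short sub-threshold segments survive; filter-first is
#'   stricter.
#' @return A data.frame `chrom`, `start`, `end`, `length` (plus `rep` if
#'   present), sorted and non-overlapping within each group.
#' @export
postprocess_segments <- function(segments, min_length = 2e6,
                                 max_gap = 5e5,
                                 order = c("merge_first", "filter_first")) {
  order <- match.arg(order)
  if (order == "filter_first") {
    seg <- as.data.frame(segments)
    seg <- seg[(seg$end - seg$start) >= min_length, , drop = FALSE]
    return(postprocess_segments(seg, min_length = min_length,
                                max_gap = max_gap, order = "merge_first"))
  }
  has_rep <- "rep" %in% names(segments)
  cols <- c(if (has_rep) "rep", "chrom", "start", "end")
  seg <- as.data.frame(segments)[, cols, drop = FALSE]
  if (nrow(seg) == 0) {
    seg$length <- numeric(0)
    return(seg)
  }
  o <- if (has_rep) order(seg$rep, seg$chrom, seg$start) else
    order(seg$chrom, seg$start)
  seg <- seg[o, , drop = FALSE]
  new_grp <- if (nrow(seg) == 1) TRUE else c(TRUE,
    (if (has_rep) seg$rep[-1] != seg$rep[-nrow(seg)] else FALSE) |
      seg$chrom[-1] != seg$chrom[-nrow(seg)] |
      (seg$start[-1] - seg$end[-nrow(seg)]) >= max_gap)
  gid <- cumsum(new_grp)
  first <- !duplicated(gid)
  last <- !duplicated(gid, fromLast = TRUE)
  out <- seg[first, , drop = FALSE]
  out$end <- seg$end[last]
  out$length <- out$end - out$start
  out <- out[out$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute the F_ROH inbreeding coefficient
#'
#' `F_ROH` is the fraction of the effective genome covered by (post-
#' processed) runs of homozygosity: `total_roh / effective_genome`.
#'
#' @param segments Post-processed segments (`chrom`, `start`, `end`).
#' @param effective_genome Effective genome size in bp (> 0) — typically the
#'   unmasked autosomal length the window track retained.
#' @return An object of class `roh_callset`: list with `segments`,
#'   `total_roh`, `effective_genome`, `f_roh`.
#' @examples
#' seg <- data.frame(chrom = "chr1", start = 0, end = 306e6)
#' compute_f_roh(seg, 2587e6)$f_roh # 0.118
#' @export
compute_f_roh <- function(segments, effective_genome) {
  if (!is.numeric(effective_genome) || effective_genome <= 0) {
    stop("'effective_genome' must be > 0")
  }
  seg <- as.data.frame(segments)
  if (nrow(seg) > 0) {
    seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
    same <- seg$chrom[-1] == seg$chrom[-nrow(seg)]
    if (nrow(seg) > 1 && any(same & seg$start[-1] < seg$end[-nrow(seg)])) {
      stop("internal error: overlapping segments; post-process first")
    }
  }
  seg$length <- seg$end - seg$start
  total <- sum(seg$length)
  f <- total / effective_genome
  if (f > 1) stop("total ROH exceeds the effective genome")
  structure(list(segments = seg, total_roh = total,
                 effective_genome = effective_genome, f_roh = f),
            class = "roh_callset")
}

#' @export
print.roh_callset <- function(x, ...) {
  cat(sprintf("<roh_callset> %d segments, %.1f Mbp / %.1f Mbp, F_ROH = %.3f\n",
              nrow(x$segments), x$total_roh / 1e6,
              x$effective_genome / 1e6, x$f_roh))
  invisible(x)
}

#' Summarize a ROH callset
#'
#' @param callset A [compute_f_roh()] result.
#' @param large_threshold Length above which a segment counts as "large"
#'   (default 2 Mbp).
#' @return A list: `n_segments`, `n_large`, `largest`, `total_roh`, `f_roh`,
#'   and `per_chrom` (data.frame of per-chromosome totals).
#' @export
summarize_callset <- function(callset, large_threshold = 2e6) {
  stopifnot(inherits(callset, "roh_callset"))
  seg <- callset$segments
  if (nrow(seg) == 0) {
    return(list(n_segments = 0L, n_large = 0L, largest = 0,
                total_roh = 0, f_roh = 0,
                per_chrom = data.frame(chrom = character(0),
                                       total_roh = numeric(0),
                                       n_segments = integer(0))))
  }
  per <- stats::aggregate(seg$length, by = list(chrom = seg$chrom),
                          FUN = sum)
  names(per)[2] <- "total_roh"
  per$n_segments <- as.integer(table(seg$chrom)[per$chrom])
  list(n_segments = nrow(seg),
       n_large = sum(seg$length > large_threshold),
       largest = max(seg$length),
       total_roh = callset$total_roh,
       f_roh = callset$f_roh,
       per_chrom = per)
}
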