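#' Define a segment-length binning
#'
#' Segments are classified by length into consecutive bins of `bin_width`
#' starting at the post-processing minimum length (no shorter segment can
#' exist), left-closed right-open, with an open-ended top bin. Defaults:
#' 5-Mbp bins from 2 Mbp, i.e. [2, 7), [7, 12), ... Mbp.
#'
#' @param min_length Lower edge of the first bin in bp.
#' @param bin_width Bin width in bp.
#' @param n_bins Number of bins including the open-ended top bin.
#' @return A list of class `length_binning` with `breaks` (lower edges) and
#'   the parameters.
#' @export
length_binning <- function(min_length = 2e6, bin_width = 5e6, n_bins = 16) {
  stopifnot(bin_width > 0, n_bins >= 1, min_length >= 0)
  structure(list(min_length = min_length, bin_width = bin_width,
                 n_bins = as.integer(n_bins),
                 breaks = min_length + bin_width * (seq_len(n_bins) - 1)),
            class = "length_binning")
}

# smallest n_bins covering all lengths in `lens` at the given binning params
binning_for <- function(lens, min_length = 2e6, bin_width = 5e6) {
  top <- if (length(lens) == 0) 1 else
    floor((max(lens) - min_length) / bin_width) + 1
  length_binning(min_length, bin_width, max(1, top))
}

#' Bin segment lengths into counts
#'
#' @param segments A post-processed segment data.frame (all lengths must be
#'   `>= min_length` of the binning) or a numeric vector of lengths.
#' @param binning A [length_binning()].
#' @return An integer vector of length `n_bins`; sums to the number of
#'   segments.
#' @export
bin_counts <- function(segments, binning) {
  stopifnot(inherits(binning, "length_binning"))
  lens <- if (is.data.frame(segments)) segments$end - segments$start else
    as.numeric(segments)
  if (any(lens < binning$min_length)) {
    stop("segment shorter than the binning minimum; post-process first")
  }
  idx <- pmin(floor((lens - binning$min_length) / binning$bin_width) + 1,
              binning$n_bins)
  tabulate(idx, nbins = binning$n_bins)
}

#' Estimate multinomial bin probabilities from simulated counts
#'
#' `p_i = (c_i + pseudocount) / sum(c_j + pseudocount)`. The pseudocount
#' (default 0.5 per bin) keeps every bin probability positive so that
#' observed counts in bins the simulation never produced score finitely
#' rather than at -Inf.
#'
#' @param counts Non-negative count vector (pooled over replicates).
#' @param pseudocount Added to every bin (>= 0).
#' @return A probability vector summing to 1.
#' @export
fit_model_probs <- function(counts, pseudocount = 0.5) {
  if (any(counts < 0)) stop("counts must be >= 0")
  tot <- sum(counts + pseudocount)
  if (tot <= 0) stop("all-zero counts with zero pseudocount")
  (counts + pseudocount) / tot
}

#' Multinomial log-likelihood of observed bin counts
#'
#' `log P(c | p) = log(n!) - sum(log(c_i!)) + sum(c_i log p_i)` with
#' `n = sum(c)`. Returns `-Inf` only when some `c_i > 0` has `p_i = 0`
#' (prevented upstream by the pseudocount).
#'
#' @param observed Non-negative integer count vector.
#' @param probs Probability vector of the same length, summing to 1.
#' @return The log-likelihood (a scalar).
#' @export
multinomial_loglik <- function(observed, probs) {
  if (length(observed) != length(probs)) {
    stop("'observed' and 'probs' must have equal length")
  }
  if (any(observed < 0) || sum(observed) == 0) {
    stop("'observed' must be non-negative with at least one segment")
  }
  n <- sum(observed)
  term <- ifelse(observed > 0, observed * log(probs), 0)
  lgamma(n + 1) - sum(lgamma(observed + 1)) + sum(term)
}

#' Rank pedigree models by multinomial likelihood of an observed callset
#'
#' Bins the observed post-processed ROH segment lengths, fits per-model bin
#' probabilities from each model's pooled simulated segments, and scores the
#' observed counts under each model. A common binning wide enough for the
#' longest segment (observed or simulated) is used for all models.
#'
#' @param observed_segments Observed post-processed segments (data.frame
#'   with `start`, `end`), e.g. `compute_f_roh(...)$segments`.
#' @param model_runs A list of [run_model()] results, one per candidate
#'   model, simulated under identical build/rates/post-processing.
#' @param pseudocount Passed to [fit_model_probs()].
#' @param binning A [length_binning()], or `NULL` to derive one.
#' @return A data.frame sorted by decreasing `log_likelihood`:
#'   `model_id`, `class`, `log_likelihood`, `delta_loglik`, `rank` (ties
#'   share the smallest rank and are reported, never broken), and per-model
#'   diagnostics `mean_n_segments`, `mean_autozygous_fraction`,
#'   `n_sim_segments`. The binning is attached as `attr(, "binning")`.
#' @export
rank_models <- function(observed_segments, model_runs, pseudocount = 0.5,
                        binning = NULL) {
  obs_lens <- observed_segments$end - observed_segments$start
  if (length(obs_lens) == 0) {
    stop("observed callset has no ROH segments: nothing to rank ",
         "(no ROH implies no detectable inbreeding signal)")
  }
  stopifnot(length(model_runs) >= 1)
  if (is.null(binning)) {
    sim_lens <- unlist(lapply(model_runs, function(r) r$segments$length))
    binning <- binning_for(c(obs_lens, sim_lens))
  }
  obs_counts <- bin_counts(obs_lens, binning)
  rows <- lapply(model_runs, function(r) {
    probs <- fit_model_probs(bin_counts(r$segments$length, binning),
                             pseudocount)
    data.frame(model_id = r$model_id, class = r$class,
               log_likelihood = multinomial_loglik(obs_counts, probs),
               mean_n_segments = mean(r$n_segments),
               mean_autozygous_fraction = mean(r$postfilter_fraction),
               n_sim_segments = nrow(r$segments),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$log_likelihood), , drop = FALSE]
  out$delta_loglik <- max(out$log_likelihood) - out$log_likelihood
  out$rank <- rank(-out$log_likelihood, ties.method = "min")
  rownames(out) <- NULL
  attr(out, "binning") <- binning
  attr(out, "observed_counts") <- obs_counts
  out
}
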