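# Independent oracles used by the tests. These deliberately re-derive
# results by enumeration / per-base comparison, not by calling the package's
# own code paths.

# Exhaustive ROH scan: enumerate all window-index pairs (i, j) that qualify
# as a run (low endpoints, no high window inside, >= min_windows low
# windows, no two consecutive non-eligible windows) and keep the maximal
# ones. Qualification is interval-closed, so a pair is maximal iff it has
# the minimal qualifying start for its end and the maximal qualifying end
# for its start.
oracle_roh_scan <- function(windows, het_threshold, min_windows = 2) {
  state <- ifelse(windows$masked_out | windows$short |
                    is.na(windows$het_per_kbp), "skip",
                  ifelse(windows$het_per_kbp < het_threshold, "low", "high"))
  out <- list()
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    s <- state[idx]
    n <- length(s)
    low <- s == "low"
    chigh <- cumsum(s == "high")
    clow <- cumsum(low)
    dbl <- c(FALSE, s[-1] == "skip" & s[-n] == "skip")
    cdbl <- cumsum(dbl)
    li <- which(low)
    if (length(li) == 0) next
    I <- rep(li, each = length(li))
    J <- rep(li, times = length(li))
    keep <- J >= I
    I <- I[keep]; J <- J[keep]
    qual <- (chigh[J] - chigh[I]) == 0 &
      (clow[J] - clow[I] + 1) >= min_windows &
      (cdbl[J] - cdbl[I]) == 0
    I <- I[qual]; J <- J[qual]
    if (length(I) == 0) next
    min_i <- tapply(I, J, min)
    max_j <- tapply(J, I, max)
    maximal <- I == min_i[as.character(J)] & J == max_j[as.character(I)]
    out[[ch]] <- data.frame(
      chrom = ch,
      start = windows$start[idx[I[maximal]]],
      end = windows$end[idx[J[maximal]]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Naive merge-then-filter, one segment at a time.
oracle_postprocess <- function(seg, min_length = 2e6, max_gap = 5e5) {
  if (nrow(seg) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  seg <- seg[order(seg$chrom, seg$start), c("chrom", "start", "end")]
  out <- list()
  cur <- seg[1, ]
  for (k in seq_len(nrow(seg))[-1]) {
    row <- seg[k, ]
    if (row$chrom == cur$chrom && (row$start - cur$end) < max_gap) {
      cur$end <- max(cur$end, row$end)
    } else {
      out[[length(out) + 1]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1]] <- cur
  res <- do.call(rbind, out)
  res <- res[(res$end - res$start) >= min_length, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# All outcome vectors of a multinomial with n trials over k bins.
oracle_compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  do.call(rbind, lapply(0:n, function(i) {
    cbind(i, oracle_compositions(n - i, k - 1))
  }))
}

# Direct multinomial pmf from factorials.
oracle_multinom_pmf <- function(counts, p) {
  factorial(sum(counts)) / prod(factorial(counts)) * prod(p^counts)
}

# Haplotype label at a set of positions (per-base lookup).
oracle_label_at <- function(hap, pos) {
  hap$lab[findInterval(pos, hap$brk)]
}

# Random window track: 1-Mbp windows with mixed low/high densities, some
# masked and some short, on a handful of chromosomes.
random_track <- function(n_windows, p_low = 0.3, p_skip = 0.1,
                         n_chrom = 2) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_windows,
                       replace = TRUE))
  starts <- unlist(lapply(table(chrom), function(k) (seq_len(k) - 1) * 1e6))
  dens <- ifelse(runif(n_windows) < p_low, runif(n_windows, 0, 0.4),
                 runif(n_windows, 0.6, 1.5))
  w <- data.frame(chrom = chrom, start = starts, end = starts + 1e6,
                  nominal_size = 1e6, short = FALSE,
                  masked_out = runif(n_windows) < p_skip,
                  effective_bases = 1e6, het_count = NA_real_,
                  het_per_kbp = dens, stringsAsFactors = FALSE)
  w$het_per_kbp[w$masked_out] <- NA_real_
  w
}

# Tiny two-chromosome build used across unit tests.
toy_build <- function() genome_build(c("chrA", "chrB"), c(10e6, 6e6))
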