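make_track <- function(dens, chrom = "chr1", masked = FALSE) {
  n <- length(dens)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * 1e6,
             end = seq_len(n) * 1e6, nominal_size = 1e6, short = FALSE,
             masked_out = rep_len(masked, n), effective_bases = 1e6,
             het_count = dens * 1000,
             het_per_kbp = ifelse(rep_len(masked, n), NA_real_, dens),
             stringsAsFactors = FALSE)
}

test_that("call_roh requires at least two consecutive low windows", {
  expect_equal(nrow(call_roh(make_track(rep(1, 10)), het_threshold = 0.25)),
               0L)
  # single low window flanked by high ones is not called
  expect_equal(nrow(call_roh(make_track(c(1, 1, 0.1, 1, 1)),
                             het_threshold = 0.25)), 0L)
  seg <- call_roh(make_track(c(1, 0.1, 0.1, 1)), het_threshold = 0.25)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 1e6)
  expect_equal(seg$end, 3e6)
  expect_equal(seg$n_windows, 2L)
  expect_error(call_roh(make_track(rep(1, 4)), het_threshold = -1), "> 0")
})

test_that("a single masked window does not break a run but two do", {
  d <- c(0.1, 0.1, NA, 0.1, 0.1)
  w <- make_track(ifelse(is.na(d), 0, d))
  w$masked_out[3] <- TRUE
  w$het_per_kbp[3] <- NA_real_
  seg <- call_roh(w, het_threshold = 0.25)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(0, 5e6))
  expect_equal(seg$n_windows, 4L) # masked window contributes no length

  w2 <- make_track(rep(0.1, 6))
  w2$masked_out[3:4] <- TRUE
  w2$het_per_kbp[3:4] <- NA_real_
  seg2 <- call_roh(w2, het_threshold = 0.25)
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$end - seg2$start, c(2e6, 2e6))
})

test_that("call_roh matches the exhaustive scan on random tracks", {
  set.seed(99)
  for (i in 1:60) {
    w <- random_track(sample(5:200, 1))
    got <- call_roh(w, het_threshold = 0.5)
    want <- oracle_roh_scan(w, 0.5)
    expect_equal(got[, c("chrom", "start", "end")], want)
  }
})

test_that("postprocess_segments merges strictly-small gaps before filtering", {
  seg <- data.frame(chrom = "chr1", start = c(0, 3.4e6), end = c(3e6, 6e6))
  out <- postprocess_segments(seg)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(0, 6e6))

  # gap exactly 500 kbp is NOT merged (strict inequality)
  seg2 <- data.frame(chrom = "chr1", start = c(0, 3.5e6), end = c(3e6, 6e6))
  expect_equal(nrow(postprocess_segments(seg2)), 2L)

  # merge-then-filter: two 1.2 Mbp segments 100 kbp apart survive as one
  seg3 <- data.frame(chrom = "chr1", start = c(0, 1.3e6),
                     end = c(1.2e6, 2.5e6))
  out3 <- postprocess_segments(seg3)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$length, 2.5e6)

  # filter-first would have dropped both; also check sub-min removal
  expect_equal(nrow(postprocess_segments(
    data.frame(chrom = "chr1", start = 0, end = 1.9e6))), 0L)

  # segments on different chromosomes never merge
  seg4 <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 1e5),
                     end = c(3e6, 3.1e6))
  expect_equal(nrow(postprocess_segments(seg4)), 2L)

  # the stricter filter-first order drops sub-threshold neighbours instead
  seg3 <- data.frame(chrom = "chr1", start = c(0, 1.3e6),
                     end = c(1.2e6, 2.5e6))
  expect_equal(nrow(postprocess_segments(seg3, order = "filter_first")), 0L)
})

test_that("raising the threshold never shrinks total called ROH", {
  set.seed(7)
  w <- random_track(150)
  thresholds <- c(0.1, 0.3, 0.5, 0.8, 1.2)
  totals <- vapply(thresholds, function(t) {
    seg <- call_roh(w, het_threshold = t)
    sum(seg$end - seg$start)
  }, 0)
  expect_true(all(diff(totals) >= 0))
})

test_that("compute_f_roh computes the callset arithmetic", {
  # empty callset
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  expect_equal(compute_f_roh(empty, 1e9)$f_roh, 0)

  # whole single-chromosome genome in one segment
  whole <- data.frame(chrom = "chr1", start = 0, end = 5e7)
  expect_equal(compute_f_roh(whole, 5e7)$f_roh, 1)

  expect_error(compute_f_roh(whole, 0), "> 0")
  overlapping <- data.frame(chrom = "chr1", start = c(0, 1e6),
                            end = c(2e6, 3e6))
  expect_error(compute_f_roh(overlapping, 1e9), "overlap")
})

test_that("summarize_callset counts large segments and per-chromosome totals", {
  seg <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(0, 5e6, 0), end = c(1e6, 7.5e6, 68e6))
  s <- summarize_callset(compute_f_roh(seg, 2.587e9))
  expect_equal(s$n_segments, 3L)
  expect_equal(s$n_large, 2L)
  expect_equal(s$largest, 68e6)
  expect_equal(s$per_chrom$total_roh[s$per_chrom$chrom == "chr1"], 3.5e6)

  s0 <- summarize_callset(compute_f_roh(
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0)),
    1e9))
  expect_equal(s0$n_segments, 0L)
  expect_equal(s0$largest, 0)
})

test_that("planted ROH are recovered to window resolution on synthetic data", {
  b <- genome_build(c("chr1", "chr2"), c(80e6, 60e6))
  planted <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(10e6, 50e6, 20e6),
                        end = c(14e6, 58e6, 23e6))
  tr <- synthetic_truth(planted_roh = planted, seed = 21)
  w <- count_het(tile_windows(b), gen_het_sites(b, tr))
  seg <- postprocess_segments(call_roh(w))
  expect_equal(nrow(seg), 3L)
  o <- order(seg$chrom, seg$start)
  expect_true(all(abs(seg$start[o] - planted$start) <= 1e6))
  expect_true(all(abs(seg$end[o] - planted$end) <= 1e6))

  # F_ROH of truth and callset agree within 2 window sizes per segment
  f_truth <- sum(planted$end - planted$start) / total_length(b)
  f_call <- compute_f_roh(seg, total_length(b))$f_roh
  expect_lt(abs(f_call - f_truth), 2e6 * nrow(seg) / total_length(b))
})
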