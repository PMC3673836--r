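test_that("gen_build conserves total length and is seed-deterministic", {
  b1 <- gen_build(1, 10e6, seed = 7)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$length, 10e6)

  b22 <- gen_build(22, 2.875e9, seed = 1)
  expect_equal(sum(b22$length), 2.875e9)
  expect_equal(nrow(b22), 22L)
  expect_true(all(b22$length > 0))

  expect_identical(gen_build(3, 300e6, seed = 5), gen_build(3, 300e6, seed = 5))
  expect_false(identical(gen_build(3, 300e6, seed = 5)$length,
                         gen_build(3, 300e6, seed = 6)$length))

  expect_error(gen_build(0, 1e6, seed = 1), "positive")
  expect_error(gen_build(5, 3, seed = 1), ">=")
})

test_that("gen_het_sites draws a Poisson process at the configured rates", {
  b <- genome_build("chr1", 10e6)

  # rate 1/kbp on 10 Mbp: count within 4 SD of 10,000
  tr <- synthetic_truth(background_het_rate = 1.0, roh_het_rate = 0.01,
                        seed = 42)
  v <- gen_het_sites(b, tr)
  expect_true(abs(nrow(v) - 10000) < 4 * sqrt(10000))
  expect_true(all(v$gt == "het"))
  expect_false(is.unsorted(v$pos))
  expect_true(all(v$pos >= 1 & v$pos <= 10e6))

  # zero-rate interval: no sites inside the planted ROH
  roh <- data.frame(chrom = "chr1", start = 2e6, end = 5e6)
  tr0 <- synthetic_truth(planted_roh = roh, background_het_rate = 1,
                         roh_het_rate = 0, seed = 9)
  v0 <- gen_het_sites(b, tr0)
  expect_equal(sum(v0$pos > 2e6 & v0$pos <= 5e6), 0)
  expect_gt(nrow(v0), 0)

  # determinism
  expect_identical(gen_het_sites(b, tr), gen_het_sites(b, tr))

  expect_error(synthetic_truth(background_het_rate = -1), ">= 0")
  expect_error(synthetic_truth(background_het_rate = 1, roh_het_rate = 1),
               "strictly below")
})

test_that("window densities recover the generating rates", {
  b <- genome_build("chr1", 60e6)
  roh <- data.frame(chrom = "chr1", start = 20e6, end = 40e6)
  tr <- synthetic_truth(planted_roh = roh, seed = 4)
  v <- gen_het_sites(b, tr)
  w <- count_het(tile_windows(b), v)
  inside <- w$start >= 20e6 & w$end <= 40e6
  expect_equal(mean(w$het_per_kbp[!inside]), tr$background_het_rate,
               tolerance = 0.02)
  expect_equal(mean(w$het_per_kbp[inside]), tr$roh_het_rate,
               tolerance = 0.2)
})

test_that("gen_dup_mask covers the requested fraction without overlap", {
  b <- genome_build("chr1", 100e6)
  expect_equal(nrow(gen_dup_mask(b, 0, seed = 1)), 0L)

  m <- gen_dup_mask(b, 0.05, seed = 3)
  covered <- sum(m$end - m$start)
  expect_lt(abs(covered - 5e6) / 5e6, 0.10)
  expect_true(all(m$start[-1] >= m$end[-nrow(m)])) # non-overlapping
  expect_true(all(m$start >= 0 & m$end <= 100e6))

  b2 <- toy_build()
  m2 <- gen_dup_mask(b2, 0.1, seed = 5)
  for (i in seq_len(nrow(b2))) {
    on_chr <- m2[m2$chrom == b2$chrom[i], ]
    expect_true(all(on_chr$end <= b2$length[i])) # never crosses a boundary
  }
  expect_error(gen_dup_mask(b, 1.2, seed = 1), "0, 1")
})

test_that("candidate-variant generator plants exactly one private causal", {
  b <- toy_build()
  genes <- data.frame(gene = c("G1", "G2"), chrom = c("chrA", "chrB"),
                      start = c(1e6, 2e6), end = c(1.2e6, 2.2e6))
  causal <- list(chrom = "chrA", pos = 1.1e6, ref = "C", alt = "G")

  fx <- gen_candidate_variants(b, genes, causal, panel_size = 2, seed = 8,
                               n_shared_in_gene = 10, n_background = 300)
  res <- prioritize_variants(fx$focal, genes, fx$panel)$result
  expect_equal(nrow(res), 1L)
  expect_equal(res$pos, causal$pos)

  # planting the causal allele in a panel genome empties the funnel
  fx2 <- gen_candidate_variants(b, genes, causal, panel_size = 2, seed = 8,
                                n_shared_in_gene = 10, n_background = 300,
                                leak_causal_to_panel = TRUE)
  expect_equal(nrow(prioritize_variants(fx2$focal, genes, fx2$panel)$result),
               0L)

  # empty panel: privacy filter degenerates, all in-gene hom non-syn pass
  fx0 <- gen_candidate_variants(b, genes, causal, panel_size = 0, seed = 8,
                                n_shared_in_gene = 10, n_background = 300)
  expect_equal(nrow(prioritize_variants(fx0$focal, genes, list())$result),
               11L)

  expect_error(
    gen_candidate_variants(b, genes, list(chrom = "chrA", pos = 5e6,
                                          ref = "C", alt = "G")),
    "inside a candidate-gene")
})
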