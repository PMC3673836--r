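test_that("bin_counts classifies lengths into left-closed 5-Mbp bins", {
  bn <- length_binning(min_length = 2e6, bin_width = 5e6, n_bins = 8)
  counts <- bin_counts(c(2.1e6, 4.9e6, 7.2e6, 40e6), bn)
  expect_equal(sum(counts), 4)
  expect_equal(counts[1], 2L)
  expect_equal(counts[2], 1L)
  expect_equal(counts[8], 1L) # 40 Mbp lands in the open-ended top bin

  # boundary exactly at a bin edge goes right (left-closed, right-open)
  expect_equal(bin_counts(7e6, bn), c(0L, 1L, rep(0L, 6)))

  expect_equal(bin_counts(numeric(0), bn), rep(0L, 8))
  expect_error(bin_counts(1e6, bn), "post-process")
})

test_that("fit_model_probs applies pseudocount smoothing", {
  expect_equal(fit_model_probs(c(10, 10), pseudocount = 0), c(0.5, 0.5))
  expect_equal(fit_model_probs(c(0, 10), pseudocount = 0.5),
               c(0.5 / 11, 10.5 / 11))
  expect_equal(sum(fit_model_probs(c(3, 0, 7, 1))), 1)
  expect_error(fit_model_probs(c(0, 0), pseudocount = 0), "all-zero")
  expect_error(fit_model_probs(c(-1, 2)), ">= 0")
})

test_that("multinomial log-likelihood matches hand computation and dmultinom", {
  expect_equal(multinomial_loglik(5, 1), 0) # degenerate single bin
  expect_equal(multinomial_loglik(c(1, 1), c(0.5, 0.5)), log(0.5))
  for (i in 1:10) {
    set.seed(i)
    p <- fit_model_probs(rpois(4, 5))
    x <- rmultinom(1, 7, p)[, 1]
    expect_equal(multinomial_loglik(x, p),
                 dmultinom(x, prob = p, log = TRUE))
  }
  expect_error(multinomial_loglik(c(1, 2), c(1)), "equal length")
  expect_error(multinomial_loglik(c(0, 0), c(0.5, 0.5)), "at least one")
})

test_that("multinomial pmf sums to 1 over all outcomes (enumeration oracle)", {
  for (n in 1:5) {
    for (k in 1:3) {
      p <- fit_model_probs(seq_len(k))
      outcomes <- oracle_compositions(n, k)
      pm <- apply(outcomes, 1, function(x)
        exp(multinomial_loglik(x, p)))
      expect_equal(sum(pm), 1, tolerance = 1e-10)
      direct <- apply(outcomes, 1, oracle_multinom_pmf, p = p)
      expect_equal(pm, direct, tolerance = 1e-12)
    }
  }
})

test_that("binning and scores are invariant to segment input order", {
  set.seed(12)
  lens <- runif(40, 2e6, 30e6)
  bn <- length_binning(n_bins = 6)
  expect_equal(bin_counts(lens, bn), bin_counts(rev(lens), bn))
  expect_equal(bin_counts(lens, bn), bin_counts(sample(lens), bn))
})

test_that("rank_models prefers the generating model and reports ties", {
  b <- gen_build(8, 1.2e9, seed = 3, jitter = 0)
  runs <- list(
    run_model("uncle_niece_pat", b, n_reps = 400, seed = 1),
    run_model("grandfather_granddaughter_pat", b, n_reps = 400, seed = 2)
  )
  # observed = pooled expectation of model 1: model 1 attains the max
  bn <- length_binning(n_bins = 10)
  pooled <- bin_counts(runs[[1]]$segments$length, bn)
  obs_lens <- rep(bn$breaks + 1e5, pooled) # one segment per counted bin slot
  obs <- data.frame(start = 0, end = obs_lens)
  rk <- rank_models(obs, runs, binning = bn)
  expect_equal(rk$model_id[1], "uncle_niece_pat")
  expect_equal(rk$rank[1], 1L)
  expect_true(all(diff(rk$log_likelihood) <= 0))

  # identical runs tie and the tie is reported
  rk2 <- rank_models(obs, list(runs[[1]], runs[[1]]), binning = bn)
  expect_equal(rk2$rank, c(1L, 1L))

  empty <- data.frame(start = numeric(0), end = numeric(0))
  expect_error(rank_models(empty, runs), "no ROH")
})

test_that("the generating model attains the highest expected log-likelihood", {
  b <- gen_build(8, 1.2e9, seed = 3, jitter = 0)
  models <- c("half_sib_pat", "uncle_niece_pat",
              "grandfather_granddaughter_mat")
  runs <- lapply(seq_along(models), function(i)
    run_model(models[i], b, n_reps = 800, seed = 40 + i))
  names(runs) <- models
  # score held-out replicates of each generating model under all three:
  # the generating model should have the highest mean log-likelihood
  for (g in models) {
    test_run <- run_model(g, b, n_reps = 60, seed = 900 + match(g, models))
    ll <- sapply(split(test_run$segments, test_run$segments$rep),
                 function(seg) {
                   rk <- rank_models(seg, runs)
                   stats::setNames(rk$log_likelihood, rk$model_id)[models]
                 })
    mean_ll <- rowMeans(ll)
    expect_equal(names(which.max(mean_ll)), g)
  }
})
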