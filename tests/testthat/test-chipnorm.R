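test_that("stage 1 removes background and biased bins", {
  # library means: count_a ~2 except one strong bin; inputs flat except bin 5
  bins <- tibble::tibble(
    count_a = c(0, 2, 30, 2, 2, 2, 2, 2, 2, 2),
    count_b = c(0, 2, 2, 2, 2, 2, 2, 2, 2, 2),
    input_a = c(2, 2, 2, 2, 40, 2, 2, 2, 2, 2),
    input_b = c(2, 2, 2, 2, 40, 2, 2, 2, 2, 2)
  )
  out <- stage1_filter(bins, stage1_alpha = 0.01, c_bias = 5)
  expect_false(out$retained[1]) # both zero: background by definition
  expect_true(out$retained[3]) # 30 vs mean ~4.6: p << 0.01
  expect_false(out$retained[5]) # biased and weak in both IPs
  # make bin 5 strong in IP too: the bias rule still removes it
  bins2 <- bins
  bins2$count_a[5] <- 30
  out2 <- stage1_filter(bins2, stage1_alpha = 0.01, c_bias = 5)
  expect_false(out2$retained[5])
  # without the bias filter it would be retained
  out3 <- stage1_filter(bins2, stage1_alpha = 0.01, bias_filter = FALSE)
  expect_true(out3$retained[5])
})

test_that("quantile normalization maps rank-wise to the mean order statistics", {
  qn <- quantile_normalize(c(1, 2, 3), c(2, 4, 6))
  expect_equal(qn$a, c(1.5, 3, 4.5))
  expect_equal(qn$b, c(1.5, 3, 4.5))

  same <- quantile_normalize(c(4, 1, 9), c(4, 1, 9))
  expect_equal(same$a, c(4, 1, 9))
  expect_equal(same$b, c(4, 1, 9))

  expect_error(quantile_normalize(1:3, 1:4), "equal length")

  # permutation equivariance
  set.seed(5)
  a <- runif(50); b <- runif(50)
  perm <- sample(50)
  qn1 <- quantile_normalize(a, b)
  qn2 <- quantile_normalize(a[perm], b[perm])
  expect_equal(qn2$a, qn1$a[perm])
  expect_equal(qn2$b, qn1$b[perm])

  # identical empirical distributions after normalization (tie-free input)
  expect_identical(sort(qn1$a), sort(qn1$b))

  # ties receive the mean reference value over the tied ranks
  qt <- quantile_normalize(c(1, 1), c(2, 3))
  expect_equal(qt$a, c(1.75, 1.75)) # mean of ref = (1.5, 2)
  expect_equal(qt$b, c(1.5, 2))
})

test_that("quantile normalization agrees with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  a <- rpois(200, 20) + runif(200) # tie-free
  b <- rpois(200, 35) + runif(200)
  qn <- quantile_normalize(a, b)
  ref <- limma::normalizeQuantiles(cbind(a, b))
  expect_equal(qn$a, unname(ref[, 1]), tolerance = 1e-12)
  expect_equal(qn$b, unname(ref[, 2]), tolerance = 1e-12)
})

test_that("differential bin labels follow the pseudocounted fold rule", {
  bins <- tibble::tibble(norm_a = c(10, 5, 4), norm_b = c(4, 5, 10))
  out <- call_differential_bins(bins, tau = 2, pseudocount = 1)
  expect_equal(out$direction, c("higher_in_A", NA, "higher_in_B"))
  expect_equal(out$log2_fold[1], log2(11 / 5))

  # swapping the columns flips every label
  swapped <- call_differential_bins(
    tibble::tibble(norm_a = bins$norm_b, norm_b = bins$norm_a),
    tau = 2, pseudocount = 1
  )
  flip <- c(higher_in_A = "higher_in_B", higher_in_B = "higher_in_A")
  expect_equal(swapped$direction, unname(flip[out$direction]))

  expect_error(call_differential_bins(bins, tau = 0.5), "tau")
  expect_error(call_differential_bins(bins, pseudocount = 0), "pseudocount")
})

test_that("directional merging respects direction boundaries and gaps", {
  mk <- function(dirs) {
    tibble::tibble(
      chrom = "c1", start = seq_along(dirs) * 200L - 200L,
      end = seq_along(dirs) * 200L, direction = dirs,
      log2_fold = ifelse(is.na(dirs), NA,
                         ifelse(dirs == "higher_in_A", 1.5, -1.5))
    )
  }
  r1 <- merge_directional(mk(c(NA, "higher_in_A", "higher_in_A",
                               "higher_in_A", NA)), width = 200)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_bins, 3L)
  expect_equal(r1$mean_log2_fold, 1.5)

  r2 <- merge_directional(mk(c("higher_in_A", "higher_in_B")), width = 200)
  expect_equal(nrow(r2), 2L) # opposite directions never merge

  r3 <- merge_directional(mk(c("higher_in_A", NA, "higher_in_A")),
                          width = 200, merge_gap = 1)
  expect_equal(nrow(r3), 1L)

  r0 <- merge_directional(mk(c(NA, NA)), width = 200)
  expect_equal(nrow(r0), 0L)
})

test_that("differential bins at tau = 2.5 are a subset of those at tau = 2.0", {
  sim <- simulate_chipseq(sim_config(seed = 31, n_genes = 60,
                                     chrom_length = 5e5))
  fit <- chipnorm(sim$reads$ip_k4_a, sim$reads$input_a,
                  sim$reads$ip_k4_b, sim$reads$input_b, sim$genome)
  kept <- fit$bins[fit$bins$retained, ]
  at2 <- call_differential_bins(kept, tau = 2.0)
  at25 <- call_differential_bins(kept, tau = 2.5)
  lab2 <- which(!is.na(at2$direction))
  lab25 <- which(!is.na(at25$direction))
  expect_true(all(lab25 %in% lab2))
  expect_equal(at25$direction[lab25], at2$direction[lab25])
})

test_that("swapping the two conditions flips every region direction exactly", {
  sim <- simulate_chipseq(sim_config(seed = 32, n_genes = 80,
                                     chrom_length = 1e6))
  fwd <- chipnorm(sim$reads$ip_k4_a, sim$reads$input_a,
                  sim$reads$ip_k4_b, sim$reads$input_b, sim$genome)
  rev <- chipnorm(sim$reads$ip_k4_b, sim$reads$input_b,
                  sim$reads$ip_k4_a, sim$reads$input_a, sim$genome)
  f <- tidy(fwd); r <- tidy(rev)
  expect_equal(nrow(f), nrow(r))
  expect_equal(f[, c("chrom", "start", "end", "n_bins")],
               r[, c("chrom", "start", "end", "n_bins")])
  flip <- c(higher_in_A = "higher_in_B", higher_in_B = "higher_in_A")
  expect_equal(r$direction, unname(flip[f$direction]))
  expect_equal(r$mean_log2_fold, -f$mean_log2_fold, tolerance = 1e-12)
})

test_that("null libraries produce few differential bins", {
  # no planted asymmetry: both conditions share one generative model. The
  # fold-change rule's false rate depends on depth: ~20-count bins cross
  # 2-fold by noise a few percent of the time, so at the default scaled-down
  # depth we bound loosely; at 4x depth (nearer the real-library regime) the
  # rate is below 1% of retained bins.
  null_props <- c(both = 0.6, none = 0.4, a_only = 0, b_only = 0)
  deep <- simulate_chipseq(sim_config(seed = 33, k4_props = null_props,
                                      background_rate = 0.028))
  fit_deep <- chipnorm(deep$reads$ip_k4_a, deep$reads$input_a,
                       deep$reads$ip_k4_b, deep$reads$input_b, deep$genome)
  g_deep <- glance(fit_deep)
  expect_lt(g_deep$n_differential_bins / g_deep$n_retained, 0.01)

  shallow <- simulate_chipseq(sim_config(seed = 33, k4_props = null_props))
  fit_sh <- chipnorm(shallow$reads$ip_k4_a, shallow$reads$input_a,
                     shallow$reads$ip_k4_b, shallow$reads$input_b,
                     shallow$genome)
  g_sh <- glance(fit_sh)
  expect_lt(g_sh$n_differential_bins / g_sh$n_retained, 0.10)
})
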