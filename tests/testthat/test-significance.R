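test_that("minimal null enumerates correctly and hits quantile 1", {
  # bulk_size 1, depth 1 per pool: each pool frequency is dosage/2 in
  # {0, .5, 1} w.p. (1/4, 1/2, 1/4); a single read is HHZ w.p. f, so the
  # observed index is Bernoulli(f) and |delta| = 1 exactly when the two
  # single reads disagree: P = 2 * E[f](1 - E[f]) = 0.5. The 99.9% quantile
  # is therefore 1 (as it also is under the pre-read enumeration, P = 0.25).
  d <- null_delta_distribution(1, 1, 1, n_reps = 4000, seed = 3)
  expect_setequal(unique(d), c(0, 1))
  p1 <- mean(d == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 4000))
  expect_equal(unname(quantile(d, 0.999)), 1)
})

test_that("deep sequencing leaves only bulk-sampling noise in the null", {
  # depth >> bulk: |delta| ~ |f_T - f_S| with f ~ Binom(100, .5)/100,
  # so SD(delta) = sqrt(2 * 0.25/100) ~ 0.0707 and q_.999 ~ 3.3 * SD < 0.35
  d <- null_delta_distribution(10000, 10000, 50, n_reps = 20000, seed = 5)
  expect_lt(unname(quantile(d, 0.999)), 0.35)
  expect_lt(abs(sd(d - mean(d))), 0.09)
})

test_that("window thresholds are deterministic, depth- and snp-monotone", {
  w <- data.frame(chrom = "chr1",
                  start = c(1, 5001, 10001, 15001),
                  end = c(5e5, 505000, 510000, 515000),
                  n_snps = c(10, 10, 50, 5),
                  mean_index_t = 0.5, mean_index_s = 0.5, mean_delta = 0,
                  med_depth_t = c(57, 57, 57, 57),
                  med_depth_s = c(57, 57, 57, 57),
                  usable = TRUE)
  cfg <- null_config(n_reps = 4000, seed = 7)
  expect_warning(t1 <- threshold_for_windows(w, cfg), "noisy")
  t2 <- suppressWarnings(threshold_for_windows(w, cfg))
  # identical windows share identical thresholds under the same seed
  expect_identical(t1$thr_0.999, t2$thr_0.999)
  expect_equal(t1$thr_0.999[1], t1$thr_0.999[2])
  # monotone in confidence level
  expect_true(all(t1$thr_0.95 <= t1$thr_0.99 & t1$thr_0.99 <= t1$thr_0.999))
  # more SNPs at equal depth -> strictly smaller threshold
  expect_lt(t1$thr_0.999[3], t1$thr_0.999[4])
  # doubling depth everywhere does not raise thresholds (read noise shrinks)
  w2 <- w; w2$med_depth_t <- 114; w2$med_depth_s <- 114
  t3 <- suppressWarnings(threshold_for_windows(w2, cfg))
  expect_true(all(t3$thr_0.999 <= t1$thr_0.999 + 0.02))
  # unusable windows stay inert
  w$usable[4] <- FALSE
  t4 <- suppressWarnings(threshold_for_windows(w, cfg))
  expect_true(is.na(t4$thr_0.999[4]))
})

test_that("region calling enforces all three criteria and merges gaps", {
  step <- 5e3; W <- 5e5
  starts <- seq(1, 3e6, by = step)
  w <- data.frame(chrom = "chr1", start = starts,
                  end = pmin(starts + W - 1, 3e6),
                  n_snps = 10, mean_index_t = 0.5, mean_index_s = 0.5,
                  mean_delta = 0, med_depth_t = 57, med_depth_s = 57,
                  usable = TRUE, thr_0.999 = 0.3)
  attr(w, "scan_config") <- list(window = W, step = step, min_snps = 3,
                                 chrom_lengths = c(chr1 = 3e6))
  # nothing significant -> empty frame
  expect_equal(nrow(call_regions(w)), 0)
  # a block passing all criteria
  hot <- w$start >= 1e6 & w$start <= 1.2e6
  w$mean_delta[hot] <- 0.6
  w$mean_index_t[hot] <- 0.85
  w$mean_index_s[hot] <- 0.25
  r <- call_regions(w)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, min(w$start[hot]))
  expect_equal(r$end, max(w$start[hot]) + W - 1)
  expect_equal(r$size_mb, (r$end - r$start) / 1e6)
  expect_equal(r$peak_delta, 0.6)
  # high delta alone is not enough without the pool-index criteria
  w2 <- w; w2$mean_index_t[hot] <- 0.65
  expect_equal(nrow(call_regions(w2)), 0)
  expect_equal(nrow(call_regions(w2, index_t_min = NULL)), 1)
  # two significant windows separated by less than a window width merge
  pair <- w$start %in% c(1000001, 1400001)
  w3 <- w
  w3$mean_delta[pair] <- 0.6
  w3$mean_index_t[pair] <- 0.85
  w3$mean_index_s[pair] <- 0.25
  r3 <- call_regions(w3)
  expect_equal(nrow(r3), 1)
  # far-apart windows stay separate regions, ordered and idempotent
  sig2 <- w$start %in% c(1000001, 2500001)
  w4 <- w
  w4$mean_delta[sig2] <- 0.6
  w4$mean_index_t[sig2] <- 0.85
  w4$mean_index_s[sig2] <- 0.25
  r4 <- call_regions(w4)
  expect_equal(nrow(r4), 2)
  expect_true(all(diff(r4$start) > 0))
  # order invariance: shuffling window rows changes nothing
  w5 <- w4[sample(nrow(w4)), ]
  attr(w5, "scan_config") <- attr(w4, "scan_config")
  expect_equal(call_regions(w5), r4)
})

test_that("the mapped-interval arithmetic reproduces the 0.965 Mb size", {
  r <- candidate_region("chr08", 3555000, 4520000)
  expect_identical(r$size_mb, 0.965)
  expect_error(candidate_region("chr08", 10, 10), "start < end")
})
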