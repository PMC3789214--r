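test_that("channel-wise t-test matches the hand-computed statistic", {
  a <- c(2.1, 2.5, 1.9, 2.4, 2.2)
  b <- c(3.0, 2.8, 3.3, 2.7)
  # direct pooled-variance formula as an independent oracle
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_oracle <- 2 * pt(-abs(tstat), length(a) + length(b) - 2)
  expect_equal(channelwise_ttest(a, b), p_oracle, tolerance = 1e-12)

  expect_equal(channelwise_ttest(c(1, 2, 3), c(3, 2, 1)), 1)
  big <- channelwise_ttest(rnorm(17), rnorm(17) + 10)
  expect_lt(big, 1e-10)
  expect_true(is.na(channelwise_ttest(c(1), c(1, 2, 3))))
})

test_that("binomial channel correction applies the k >= 3 rule", {
  p21 <- rep(0.5, 21)
  p21[1:3] <- 0.01
  r3 <- binomial_channel_correction(p21)
  expect_true(r3$corrected_significant)
  expect_equal(r3$n_significant, 3)
  expect_equal(r3$binomial_tail_p, pbinom(2, 21, 0.05, lower.tail = FALSE))
  p21[3] <- 0.5
  expect_false(binomial_channel_correction(p21)$corrected_significant)
  expect_equal(binomial_channel_correction(rep(0.5, 21))$binomial_tail_p, 1,
               tolerance = 1e-12)
  expect_error(binomial_channel_correction(rep(NA_real_, 3)), "valid channel")
})

test_that("binomial correction keeps its nominal type-I error on null tensors", {
  # 60 null biomarkers x 21 channels, 17 subjects per group
  set.seed(31)
  mk <- function(group, sid) {
    v <- matrix(rnorm(60 * 21), 60, 21,
                dimnames = list(paste0("bm", 1:60), montage_1020(21)))
    structure(list(values = v, subject_id = sid, visit = 2L, group = group),
              class = "biomarker_tensor")
  }
  tensors <- c(lapply(1:17, function(i) mk("MCI-stable", paste0("m", i))),
               lapply(1:17, function(i) mk("AD-converter", paste0("a", i))))
  dm <- difference_map(tensors)
  fp_rate <- mean(dm$corrected_significant)
  # binomial tail P(X >= 3 | 21, 0.05) ~ 0.085 under independence
  expect_lte(fp_rate, pbinom(2, 21, 0.05, lower.tail = FALSE) + 0.08)
})

test_that("feature reduction freezes training channel sets and uses medians", {
  mk <- function(group, sid, visit, bump = 0) {
    v <- matrix(0, 2, 3, dimnames = list(c("bm1", "bm2"),
                                         c("C3", "Cz", "C4")))
    v["bm1", ] <- c(1, 2, 9) + bump
    v["bm2", ] <- 5
    structure(list(values = v, subject_id = sid, visit = visit,
                   group = group), class = "biomarker_tensor")
  }
  dmap <- list(corrected_significant = c(bm1 = TRUE, bm2 = FALSE),
               significant_channels = list(bm1 = c("C3", "Cz", "C4"),
                                           bm2 = character(0)))
  class(dmap) <- "difference_map"
  tensors <- list(mk("MCI-stable", "s1", 1), mk("AD-converter", "s2", 1, 1))
  ft <- reduce_to_features(tensors, dmap)
  expect_equal(names(ft), c("subject_id", "group", "visit", "bm1"))
  expect_equal(ft$bm1, c(2, 3))   # median of {1,2,9} and {2,3,10}
  # single significant channel: feature equals that channel's value
  dmap1 <- dmap; dmap1$significant_channels$bm1 <- "Cz"
  expect_equal(reduce_to_features(tensors, dmap1)$bm1, c(2, 3))
  # a missing value on one channel: median of the rest
  t3 <- mk("MCI-stable", "s3", 1)
  t3$values["bm1", "C4"] <- NA
  expect_equal(reduce_to_features(list(t3), dmap)$bm1, 1.5)
})

test_that("difference-map channel sets are a pure function of training data", {
  set.seed(8)
  spec <- fast_cohort_spec(n_per_group = 6, frac_missing = 0)
  out <- generate_cohort(spec)
  reg <- fast_registry()
  tensors <- lapply(out$recordings, extract_battery, registry = reg)
  v2 <- tensors[vapply(tensors, function(t) t$visit, integer(1)) == 2L]
  dm1 <- difference_map(v2, k_min = 1)
  dm2 <- difference_map(v2, k_min = 1)
  expect_identical(dm1$significant_channels, dm2$significant_channels)
  # test-visit tensors never enter the map: reducing shuffled visit-1 data
  # with the same map leaves the channel sets untouched
  v1 <- tensors[vapply(tensors, function(t) t$visit, integer(1)) == 1L]
  v1_shuffled <- v1[sample(length(v1))]
  f1 <- reduce_to_features(v1, dm1)
  f2 <- reduce_to_features(v1_shuffled, dm1)
  expect_identical(dm1$significant_channels, dm2$significant_channels)
  expect_equal(sort(f1$subject_id), sort(f2$subject_id))
  m1 <- f1[order(f1$subject_id), -(1:3), drop = FALSE]
  m2 <- f2[order(f2$subject_id), -(1:3), drop = FALSE]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("permutation test matches exhaustive enumeration at n = 4 + 4", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(6.3, 7.1, 5.9, 8.2)
  got <- permutation_test_median(a, b)
  expect_true(got$exact)
  # independent exhaustive oracle over all choose(8, 4) = 70 splits
  pooled <- c(a, b)
  splits <- combn(8, 4)
  obs <- median(a) - median(b)
  d <- apply(splits, 2, function(idx)
    median(pooled[idx]) - median(pooled[-idx]))
  expect_equal(got$p_value, mean(abs(d) >= abs(obs)))

  expect_equal(permutation_test_median(1:5, 1:5)$p_value, 1)
  sep <- permutation_test_median(1:10, 101:110, n_perm = 999, seed = 2)
  expect_false(sep$exact)
  expect_equal(sep$p_value, 1 / 1000)   # smallest achievable at n_perm=999
  expect_equal(permutation_test_median(rep(2, 4), rep(2, 5))$p_value, 1)
})

test_that("sampled permutation p-values are uniform under the null", {
  set.seed(17)
  ps <- replicate(200, {
    x <- rnorm(12); y <- rnorm(12)
    permutation_test_median(x, y, n_perm = 400,
                            seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BCa intervals cover and degrade gracefully", {
  expect_equal(bca_bootstrap_ci(rep(3, 10)), c(3, 3))
  # symmetric sample: BCa close to the percentile interval
  set.seed(4)
  x <- rnorm(60)
  bca <- bca_bootstrap_ci(x, n_boot = 3000, seed = 5)
  bt <- apply(matrix(sample(x, 3000 * 60, replace = TRUE), 3000), 1, median)
  perc <- unname(quantile(bt, c(0.025, 0.975)))
  expect_lt(max(abs(bca - perc)), 0.15)
  expect_error(bca_bootstrap_ci(rnorm(5)), "at least 8")
})

test_that("BCa coverage is near nominal for the Gaussian median", {
  cover <- mean(vapply(1:500, function(i) {
    set.seed(i)
    x <- rnorm(30)
    ci <- bca_bootstrap_ci(x, n_boot = 1000, seed = i + 1000)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1)))
  expect_lt(abs(cover - 0.95), 0.03)
})

test_that("Barnard's exact test matches the frozen independent oracles", {
  # APOE-like table: 15/39 carriers vs 16/25. The mirrored table (24, 9)
  # has exactly the same |score| as the observed one; with the tied table
  # included (ties are "at least as extreme") the exhaustively enumerated
  # sup over the nuisance grid is 0.051256, while an oracle that drops the
  # tie by floating-point accident reports 0.049420. We follow the
  # tie-inclusive convention and check against the enumeration oracle.
  r <- barnard_exact_test(matrix(c(15, 16, 24, 9), 2))
  expect_lt(abs(r$p_value - 0.051256), 0.002)
  expect_lt(r$p_value, 0.052)
  expect_lt(abs(r$statistic - (-1.99457)), 1e-4)
  expect_equal(barnard_exact_test(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # complete association, no boundary ties: scipy oracle 1.9073e-06
  strong <- barnard_exact_test(matrix(c(10, 0, 0, 10), 2))
  expect_lt(strong$p_value, 0.001)
  expect_lt(abs(strong$p_value - 1.9073e-06) / 1.9073e-06, 0.05)
  expect_error(barnard_exact_test(matrix(c(0, 0, 3, 4), 2)), "margins")
})
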